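Package: sigcensus
Title: Rule-Based Census of Bacterial Signal Transduction Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial proteins into signal transduction systems
    (chemosensory, two-component, c-di-GMP, ECF sigma factor, cAMP, and
    Ser/Thr/Tyr kinase systems) from protein domain architectures and gene
    neighborhoods, and assembles per-genome and per-ecotype census tables.
    Includes diguanylate cyclase active-site (A-site) and inhibitory-site
    (I-site) motif calling from protein sequence, configurable chemosensory
    class assignment from gene-order signatures, and a deterministic
    synthetic-genome generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    yaml,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Biostrings,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
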