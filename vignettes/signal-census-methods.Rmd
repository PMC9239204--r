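---
title: "Methods: rule-based census of bacterial signal transduction systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based census of bacterial signal transduction systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcensus)
```

`sigcensus` classifies bacterial proteins into signal-transduction systems
from two kinds of evidence: the protein's **domain architecture** (an ordered
set of domain hits, e.g. from an HMM search) and its **gene neighborhood**
(which signaling genes sit nearby on the same replicon). This vignette spells
out every classification rule, the default parameters and why they were
chosen, and what the bundled synthetic-genome generator does and does not
model.

## Inputs and the domain vocabulary

Three tables drive the census:

* a **gene table** (`read_gene_table()`, GFF3 or TSV) with one row per gene:
  replicon, coordinates, strand, and the encoded protein id. Genes are
  assigned a 0-based **ordinal** per replicon in coordinate order; every
  record, coding or not, occupies an ordinal.
* a **domain table** (`read_domain_table()`, hmmscan `--domtblout` or TSV)
  with per-domain hits (envelope coordinates, e-value, bitscore).
* optional **protein sequences** (`read_protein_fasta()`), needed only for
  active-site motif calling on GGDEF-domain proteins.

Domain names are mapped to functional roles through a YAML **vocabulary**
(`default_vocabulary()`, overridable per run). A role such as `REC` or
`HATPase` can be matched by several model names (e.g. `Response_reg`,
`HATPase_c`, `HATPase_c_2`), so the rules below are stated in role terms.
Before any classification, overlapping hits on the same protein are resolved
(`resolve_architectures()`): hits above the e-value threshold (default
`1e-5`) are dropped, and when two kept hits overlap by more than half of the
shorter one, the better-scoring hit wins. The survivors, sorted by envelope
start, are the protein's architecture.

## Two-component systems

`classify_tcs()` assigns each protein one of five roles:

* **HK** — at least one HisKA and one HATPase domain, no REC domain.
* **HHK** (hybrid histidine kinase) — HisKA + HATPase with a REC domain
  C-terminal of the kinase core (REC midpoint past the last HATPase end).
* **HRR** (hybrid response regulator) — REC N-terminal of the kinase core
  (REC midpoint before the first HisKA start).
* **RR** — REC present without the HisKA+HATPase pair. This deliberately
  includes REC-carrying chemosensory proteins (CheV, REC-fused CheA or CheB):
  a receiver domain is a receiver domain, and the chemosensory census counts
  those proteins separately.
* **none** — everything else. A protein with HATPase but no HisKA is *not*
  an HK; it is a candidate STAS-kinase (see auxiliary systems).

A kinase whose REC domains sit on both sides of the core, or strictly inside
it, does not fit the rule set; it is classified HHK with a warning rather
than silently.

**Gene distance** is the number of genes *between* two genes on the same
replicon (`|ordinal difference| − 1`; adjacent genes are at distance 0;
different replicons are infinitely far). `link_hk_rr()` pairs kinase and RR
genes within a window of 4 intervening genes: adjacent pairs are
`adjacent_pair`; a non-adjacent pair where each partner sees exactly one
counterpart in the window is `one_to_one_within_window`; anything else is
`multi_within_window`. `flag_solo()` marks a kinase **solo** when its nearest
RR is strictly more than 4 genes away — so a nearest RR at distance 4 is
linked-eligible and at distance 5 the gene is solo. The window of 4 reflects
typical operon spans: cognate pairs are overwhelmingly encoded in the same
operon or an immediately adjacent one.

`classify_rr_output()` bins each RR/HRR by its non-REC output domains:
`cdgmp_enzyme` (GGDEF, EAL or HD-GYP present; takes precedence),
`dna_binding` (any helix-turn-helix family from the vocabulary), else
`other_unknown`.

`detect_atypical_clusters()` chains signaling genes of any system separated
by at most 2 non-signaling genes and reports chains containing at least 2
hybrid (HHK/HRR) genes — the genomic signature of multistep phosphorelay
neighborhoods.

## c-di-GMP turnover enzymes

`identify_cdgmp()` flags proteins with GGDEF (cyclase), EAL or HD-GYP
(phosphodiesterase) domains. `categorize_cdgmp()` splits them into six
architecture categories: DGC or PDE fused to a partner sensory domain,
stand-alone single-domain DGC or PDE, bifunctional (GGDEF together with
EAL/HD-GYP), and REC-coupled enzymes. Bifunctional proteins are excluded
from the partner categories so the categories partition the enzyme set.

When sequences are available, the GGDEF **A-site** (active site) is called
from the residues at the catalytic position: `GGDEF`, `GGEEF`, `SGDEF` and
`AGDEF` are **active**; otherwise two relaxed anchor patterns
(`xG[D/E][E/Q]F`, then `xx[D/E]EF`) locate a **degenerate** site; failing
both, the site is **absent**. The **I-site** (allosteric inhibitory site) is
an `RxxD` motif within the 15 residues upstream of the A-site. `active_dgc`
in the census counts GGDEF proteins whose A-site is active — degenerate
cyclases are frequent and often repurposed as receptors, so the active count
is the biologically meaningful one.

## Chemosensory systems

`identify_che_components()` maps architectures to components with explicit
precedence: a protein with Hpt + HATPase is **CheA** (even with a fused
REC); CheW-domain + REC is **CheV**; a single STAS domain is a component
(STAS proteins travel with chemosensory clusters in some classes); MCPsignal
marks a chemoreceptor (**MCP**); CheB, CheR, CheC, CheD, CheX, CheZ by their
own domains. **CheY** cannot be recognized from architecture alone (it is
just a single REC domain), so CheY calling is positional: after clusters are
found, any single-REC protein with no other domains within one gene of a
cluster is labeled CheY and the clusters are re-chained — a two-pass design
that keeps the CheY definition from circularly creating clusters.

`find_che_clusters()` chains chemosensory genes separated by at most 2
non-chemosensory genes. A "cluster" consisting of one lone MCP is dropped;
orphan receptors are counted separately (`count_chemoreceptors()` counts all
MCPs genome-wide).

**Class assignment** (`assign_f_class()`) compares the cluster's ordered
component tokens against gene-order **signatures**
(`default_f_signatures()`; YAML-overridable). Each signature has a core
token order (wildcard positions allowed), a set of required components,
optional auxiliary rules, and an insertion allowance. The **order score** is
the largest fraction of core tokens that occurs, in order, within a cluster
window containing at most the allowed number of extra genes — evaluated in
both orientations, since gene clusters are read off either strand. A
signature is eligible at score ≥ 0.4. Among eligible signatures the winner
maximizes, in order: order score; **number of matched tokens** (so a longer
signature matched in full beats a shorter signature that is merely a
subsequence of it — nested signatures make this tie-break necessary);
fraction of required components and auxiliary rules satisfied; and a fixed
priority. Auxiliary rules (e.g. "CheA carries a REC domain", "a CheB without
REC exists elsewhere in the genome") contribute to ranking only.

**Status** reflects in-cluster completeness of the winning signature's
required components: `full` (all present), `half` (40–80%), `partial`
(anything else above zero), `none`. Completeness is computed from the
cluster's own genes, not the whole genome — a genome-wide tally would let an
unrelated distant homolog mask a genuinely half-complete cluster, and
"half" status is precisely meant to flag reduced clusters.

## Auxiliary systems

`classify_aux()` assigns at most one system per protein, in precedence
order:

1. **ECF** sigma factor — *exactly* the two domains sigma70 region 2 +
   region 4.2 and nothing else; any third domain disqualifies. The strictness
   is the point: ECFs are minimal sigma factors, and group-1/2 sigma factors
   carry additional regions.
2. **AC** — adenylate cyclase domain.
3. **bifunctional_PP2C_Pkinase** — PP2C phosphatase fused to a Ser/Thr
   kinase domain.
4. **eSTYK** — Pkinase domain (eukaryotic-type Ser/Thr/Tyr kinase).
5. **stas_STYK** — HATPase without HisKA or Hpt: a kinase-family catalytic
   domain outside a two-component context, the anti-sigma-factor-antagonist
   kinase architecture.
6. **PP2C** — stand-alone phosphatase (not part of an HK).
7. **STAS** — single STAS domain (also a chemosensory component; counted in
   both tables deliberately).
8. **CRP_like** — cyclic-nucleotide receptor domain; the census also reports
   whether CRP-like regulators occur without any cyclase in the genome.

Neighborhood modules: `detect_ecf242()` finds the iron-uptake-style
ECF + anti-sigma pairs (an ECF gene with FecR within 4 intervening genes;
TonB nearby is supporting evidence). `detect_camp_clusters()` finds an AC
gene with at least two of {cAMP phosphodiesterase, FecR, TPR} within 6
genes. `detect_combined_pathways()` screens three fixed cross-system
neighborhood rules (e.g. PP2C + STYK + STAS + c-di-GMP enzyme around a PP2C
anchor) within a window of 6, reporting confidence `high` only when a member
protein is membrane-anchored. `qs_screen()` reports a quorum-sensing pathway
present only when a synthase *and* its cognate receptor identifier co-occur.

## The census and reproducible outputs

`classify_genome()` runs everything on one genome and returns a
`sigcensus_result`; `tidy()` gives one row per classified protein,
`glance()`/`build_census()` one row per genome, and `aggregate_by_ecotype()`
per-ecotype summaries. `run_census()` drives the whole pipeline from a YAML
config and writes TSV/JSON outputs that are byte-identical across repeated
runs on the same input — no step consumes random numbers.

## The synthetic-genome generator

`synth_generate()` builds genomes with implanted signaling systems and
exact, hand-derived ground truth, for end-to-end validation
(`synth_implant()` describes one implant; `synth_archetype()` bundles three
contrasting ecotype profiles; `synth_cohort()` builds a mixed cohort).
Implanted blocks are separated by at least 8 background genes — more than
every neighborhood window in the package — so implants can never interact
and the per-implant truth stays exact; the generator refuses
("unrealizable spec") rather than crowd implants. Background genes draw
from decoy domains that belong to no signaling vocabulary. Sequences are
generated only for GGDEF proteins, with controlled A-site/I-site motifs in
otherwise motif-free sequence. `synth_perturb()` adds measurement noise
(domain dropout, extra decoy hits) for robustness studies;
`synth_protein_cohort()` generates role-labeled protein sets with the
minimal domain count each role needs, so dropout recall has a closed-form
binomial expectation.

The generator's scope is deliberately narrow: it emits domain tables
directly rather than simulating sequence evolution plus an HMM search, gene
lengths and intergenic spacing are stylized, and truth is defined by
construction rather than by homology. It validates the *classification
logic*, not upstream homology search.

## Limitations

* All rules are architecture- and neighborhood-based; a protein whose
  domains fall below the e-value threshold, or a vocabulary missing a local
  model naming convention, silently becomes `none`.
* Class signatures are a configurable starting set, not an exhaustive
  catalog; clusters scoring below 0.4 against every signature are
  `unassigned` rather than forced into a class.
* CheY identification is positional and will miss orphan CheYs far from any
  cluster (they are still counted as RRs).
* Distances are gene-count based; ordinal distance ignores physical base-pair
  spacing.
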