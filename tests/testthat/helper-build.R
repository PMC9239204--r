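# Small constructors for hand-built fixtures used across the module tests.

mk_hits <- function(protein_id, domain, start, end,
                    evalue = 1e-20, bitscore = 100, accession = NA_character_) {
  tibble::tibble(protein_id = protein_id, domain = domain,
                 accession = accession, env_start = as.integer(start),
                 env_end = as.integer(end), evalue = evalue,
                 bitscore = bitscore)
}

# one protein whose domains are laid out left to right without overlap
mk_arch <- function(protein_id, domains) {
  n <- length(domains)
  start <- seq(10L, by = 200L, length.out = n)
  mk_hits(rep(protein_id, n), domains, start, start + 150L)
}

# a linear gene table; protein ids given per gene (NA = non-coding)
mk_genes <- function(protein_id, replicon = "chr1", strand = "+") {
  n <- length(protein_id)
  start <- seq(1L, by = 1000L, length.out = n)
  g <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                      replicon = rep_len(replicon, n),
                      start = start, end = start + 899L,
                      strand = rep_len(strand, n),
                      protein_id = protein_id)
  sigcensus:::assign_ordinals(g)
}
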