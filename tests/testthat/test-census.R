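small_genome <- function(seed = 5) {
  synth_generate(
    seed = seed, n_genes = 160,
    implants = list(
      synth_implant("che_cluster", class = "F3"),
      synth_implant("tcs_pair"),
      synth_implant("tcs_pair", output = "other_unknown"),
      synth_implant("hhk", rr_distance = 2),
      synth_implant("solo_hk", distance = 5),
      synth_implant("dgc"),
      synth_implant("pde", kind = "EAL"),
      synth_implant("crp"),
      synth_implant("orphan_mcp", n = 2)
    ),
    genome_id = paste0("mini", seed), ecotype = "generalist"
  )
}

classify_synth <- function(g, ...) {
  classify_genome(g$genes, g$domains, g$sequences, genome_id = g$genome_id,
                  ecotype = g$ecotype, ...)
}

test_that("a classified genome reproduces its implanted census exactly", {
  g <- small_genome()
  res <- classify_synth(g)
  exp <- g$truth$expected
  for (cl in intersect(names(exp), names(res$census))) {
    expect_equal(res$census[[cl]], exp[[cl]], info = cl)
  }
})

test_that("census bookkeeping identities hold", {
  res <- classify_synth(small_genome())
  cen <- res$census
  expect_equal(cen$n_hk + cen$n_hhk + cen$n_hrr, cen$n_hk_total)
  expect_lte(cen$active_dgc, cen$total_dgc)
  expect_equal(cen$rr_prop_dna + cen$rr_prop_cdgmp + cen$rr_prop_other, 1)
  expect_equal(cen$n_rr_dna + cen$n_rr_cdgmp + cen$n_rr_other, cen$n_rr)
})

test_that("the census is invariant to replicon reversal", {
  g <- small_genome(6)
  res_f <- classify_synth(g)
  g_rev <- g
  g_rev$genes <- reverse_genome(g$genes)
  res_r <- classify_genome(g_rev$genes, g$domains, g$sequences,
                           genome_id = g$genome_id, ecotype = g$ecotype)
  expect_equal(res_r$census, res_f$census)
  expect_equal(res_r$tcs[order(res_r$tcs$protein_id), ],
               res_f$tcs[order(res_f$tcs$protein_id), ])
  expect_equal(sort(paste(res_r$chemo$assignments$class,
                          res_r$chemo$assignments$status)),
               sort(paste(res_f$chemo$assignments$class,
                          res_f$chemo$assignments$status)))
})

test_that("building the census combines and orders genome rows", {
  g1 <- small_genome(7)
  g2 <- small_genome(8)
  g2$genome_id <- "aaa_first"
  r1 <- classify_synth(g1)
  r2 <- classify_genome(g2$genes, g2$domains, g2$sequences,
                        genome_id = "aaa_first", ecotype = "generalist")
  cen <- build_census(list(r1, r2))
  expect_equal(nrow(cen), 2)
  expect_equal(cen$genome_id[1], "aaa_first")
})

test_that("ecotype aggregation pools regulator counts, not per-genome means", {
  cen <- tibble::tibble(
    genome_id = c("a", "b"), ecotype = "generalist",
    n_rr = c(10L, 90L), n_rr_dna = c(10L, 0L), n_rr_cdgmp = c(0L, 45L),
    n_rr_other = c(0L, 45L),
    n_hk_total = c(5L, 5L), n_enzymes = c(3L, 3L),
    n_chemoreceptors = c(2L, 2L)
  )
  agg <- aggregate_by_ecotype(cen)
  # pooled: 10 of 100 regulators bind DNA, not mean(100%, 0%) = 50%
  expect_equal(agg$rr_prop_dna[agg$ecotype == "generalist"], 0.1)
})

test_that("tidied results map classified proteins back to gene coordinates", {
  g <- small_genome(9)
  res <- classify_synth(g)
  td <- tidy(res)
  expect_true(all(c("protein_id", "gene_id", "system", "role", "replicon",
                    "start") %in% names(td)))
  hk_rows <- td[td$role %in% "HK", ]
  expect_gt(nrow(hk_rows), 0)
  expect_true(all(hk_rows$gene_id %in% g$genes$gene_id))
  expect_equal(glance(res), res$census)
  expect_output(print(res), res$genome_id, fixed = TRUE)
})

test_that("census files are written deterministically", {
  g <- small_genome(10)
  res <- classify_synth(g)
  cen <- build_census(list(res))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_census(cen, d1)
  write_census(cen, d2)
  for (f in c("census.tsv", "census.json", "ecotype_summary.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("run_census drives the pipeline from files and a config", {
  g <- small_genome(11)
  src <- withr::local_tempdir()
  paths <- write_synth(g, src)
  out <- file.path(src, "results")
  cfg <- list(
    output_dir = out,
    genomes = list(list(genome_id = g$genome_id, ecotype = "generalist",
                        genes = paths$genes, domains = paths$domains,
                        sequences = paths$sequences))
  )
  r <- run_census(cfg, quiet = TRUE)
  expect_true(file.exists(file.path(out, "census.tsv")))
  expect_true(file.exists(file.path(out, "census.json")))
  expect_true(file.exists(file.path(out, paste0(g$genome_id, "_proteins.tsv"))))
  expect_equal(r$census$genome_id, g$genome_id)
  # the file round-trip changes nothing relative to in-memory classification
  direct <- classify_synth(g)
  expect_equal(r$census$n_hk_total, direct$census$n_hk_total)
  expect_equal(r$census$total_dgc, direct$census$total_dgc)
})

test_that("plots build without evaluation errors", {
  g <- small_genome(12)
  res <- classify_synth(g)
  cen <- build_census(list(res))
  p1 <- plot_census(cen)
  p2 <- plot_genome_map(res)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  b1 <- ggplot2::ggplot_build(p1)
  b2 <- ggplot2::ggplot_build(p2)
  expect_gt(nrow(b2$data[[1]]), 0)
})
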