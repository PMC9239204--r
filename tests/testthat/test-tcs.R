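roles_of <- function(hits) {
  r <- classify_tcs(annotate_roles(resolve_architectures(hits)))
  stats::setNames(r$role, r$protein_id)
}

test_that("transmitter-only proteins are classical histidine kinases", {
  expect_equal(unname(roles_of(mk_arch("p1", c("HisKA", "HATPase_c")))["p1"]),
               "HK")
})

test_that("a C-terminal receiver makes a hybrid kinase", {
  r <- roles_of(mk_arch("p1", c("HisKA", "HATPase_c", "Response_reg")))
  expect_equal(unname(r["p1"]), "HHK")
})

test_that("an N-terminal receiver ahead of the transmitter makes a hybrid response regulator", {
  r <- roles_of(mk_arch("p1", c("Response_reg", "HisKA", "HATPase_c")))
  expect_equal(unname(r["p1"]), "HRR")
})

test_that("an interior receiver falls back to hybrid kinase with a warning", {
  h <- mk_arch("p1", c("HisKA", "Response_reg", "HATPase_c"))
  expect_warning(r <- classify_tcs(annotate_roles(resolve_architectures(h))),
                 "interior|ambiguous|position")
  expect_equal(r$role, "HHK")
})

test_that("receivers without the paired transmitter are response regulators", {
  expect_equal(unname(roles_of(mk_arch("p1", "Response_reg"))["p1"]), "RR")
  # HATPase without HisKA (CheA-like) does not form the transmitter pair
  r <- roles_of(mk_arch("p1", c("Hpt", "HATPase_c", "Response_reg")))
  expect_equal(unname(r["p1"]), "RR")
  # HisKA alone is not a kinase
  r2 <- classify_tcs(annotate_roles(resolve_architectures(mk_arch("p1", "HisKA"))))
  expect_equal(r2$role, "none")
})

test_that("solo status flips exactly between receiver distances four and five", {
  for (d in c(4L, 5L)) {
    pids <- c("hk", rep(NA_character_, d), "rr")
    g <- mk_genes(pids)
    h <- dplyr::bind_rows(mk_arch("hk", c("HisKA", "HATPase_c")),
                          mk_arch("rr", "Response_reg"))
    tcs <- classify_tcs(annotate_roles(resolve_architectures(h)))
    s <- flag_solo(g, tcs)
    expect_equal(s$solo[s$protein_id == "hk"], d > 4,
                 info = paste("distance", d))
  }
})

test_that("kinases with no receiver anywhere are solo", {
  g <- mk_genes("hk")
  tcs <- classify_tcs(annotate_roles(resolve_architectures(
    mk_arch("hk", c("HisKA", "HATPase_c")))))
  s <- flag_solo(g, tcs)
  expect_true(s$solo)
  expect_equal(s$nearest_rr_distance, Inf)
})

test_that("widening the solo window never creates new solo kinases", {
  g <- mk_genes(c("hk", NA, NA, "rr"))
  h <- dplyr::bind_rows(mk_arch("hk", c("HisKA", "HATPase_c")),
                        mk_arch("rr", "Response_reg"))
  tcs <- classify_tcs(annotate_roles(resolve_architectures(h)))
  for (w in 1:8) {
    s_narrow <- flag_solo(g, tcs, window = w)
    s_wide <- flag_solo(g, tcs, window = w + 1)
    # solo under the wider window implies solo under the narrower one
    expect_true(all(!s_wide$solo | s_narrow$solo))
  }
})

test_that("kinase-regulator links are typed by distance and multiplicity", {
  g <- mk_genes(c("hk1", "rr1", NA, NA, "hk2", NA, "rr2", "rr3"))
  h <- dplyr::bind_rows(
    mk_arch("hk1", c("HisKA", "HATPase_c")),
    mk_arch("hk2", c("HisKA", "HATPase_c")),
    mk_arch("rr1", "Response_reg"),
    mk_arch("rr2", "Response_reg"),
    mk_arch("rr3", "Response_reg")
  )
  tcs <- classify_tcs(annotate_roles(resolve_architectures(h)))
  l <- link_hk_rr(g, tcs)
  t1 <- l$link_type[l$hk_gene_id == "g001" & l$rr_gene_id == "g002"]
  expect_equal(t1, "adjacent_pair")
  # the second kinase (g005) sees rr2 (1 intervening) and rr3 (2 intervening)
  expect_true(all(l$link_type[l$hk_gene_id == "g005"] == "multi_within_window"))
})

test_that("a uniquely paired kinase at a distance links one-to-one", {
  g <- mk_genes(c("hk1", NA, NA, "rr1"))
  h <- dplyr::bind_rows(mk_arch("hk1", c("HisKA", "HATPase_c")),
                        mk_arch("rr1", "Response_reg"))
  tcs <- classify_tcs(annotate_roles(resolve_architectures(h)))
  l <- link_hk_rr(g, tcs)
  expect_equal(l$link_type, "one_to_one_within_window")
})

test_that("regulator output classes follow enzyme > DNA-binding > other precedence", {
  h <- dplyr::bind_rows(
    mk_arch("rr_dna", c("Response_reg", "Trans_reg_C")),
    mk_arch("rr_enz", c("Response_reg", "GGDEF")),
    mk_arch("rr_both", c("Response_reg", "Trans_reg_C", "GGDEF")),
    mk_arch("rr_other", c("Response_reg", "PAS")),
    mk_arch("rr_bare", "Response_reg")
  )
  res <- annotate_roles(resolve_architectures(h))
  tcs <- classify_tcs(res)
  out <- classify_rr_output(res, tcs)
  cat_of <- stats::setNames(out$category, out$protein_id)
  expect_equal(unname(cat_of["rr_dna"]), "dna_binding")
  expect_equal(unname(cat_of["rr_enz"]), "cdgmp_enzyme")
  expect_equal(unname(cat_of["rr_both"]), "cdgmp_enzyme")
  expect_equal(unname(cat_of["rr_other"]), "other_unknown")
  expect_equal(unname(cat_of["rr_bare"]), "other_unknown")
})

test_that("runs of hybrid kinases form reported atypical clusters", {
  pids <- c("h1", "r1", "h2", "r2", "h3", "r3", NA, NA, NA, "hk9")
  g <- mk_genes(pids)
  h <- dplyr::bind_rows(
    mk_arch("h1", c("HisKA", "HATPase_c", "Response_reg")),
    mk_arch("h2", c("HisKA", "HATPase_c", "Response_reg")),
    mk_arch("h3", c("Response_reg", "HisKA", "HATPase_c")),
    mk_arch("r1", "Response_reg"), mk_arch("r2", "Response_reg"),
    mk_arch("r3", "Response_reg"),
    mk_arch("hk9", c("HisKA", "HATPase_c"))
  )
  res <- annotate_roles(resolve_architectures(h))
  tcs <- classify_tcs(res)
  sig_genes <- g$gene_id[!is.na(g$protein_id)]
  cl <- detect_atypical_clusters(g, tcs, sig_genes)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_atypical_hks, 3L)
  expect_equal(cl$n_signaling_genes, 6L)
})
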