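aux_of <- function(hits) {
  a <- classify_aux(annotate_roles(resolve_architectures(hits)))
  stats::setNames(a$system, a$protein_id)
}

test_that("an ECF sigma factor is exactly region-2 plus region-4.2", {
  expect_equal(unname(aux_of(mk_arch("p", c("Sigma70_r2", "Sigma70_r4_2")))["p"]),
               "ECF")
})

test_that("any deviation from the exact two-domain set breaks the ECF call", {
  # add a third domain of any kind
  for (extra in c("PAS", "Response_reg", "Sigma70_r2")) {
    h <- mk_arch("p", c("Sigma70_r2", "Sigma70_r4_2", extra))
    a <- classify_aux(annotate_roles(resolve_architectures(h)))
    expect_false(any(a$system[a$protein_id == "p"] %in% "ECF"), info = extra)
  }
  # remove either half
  for (only in c("Sigma70_r2", "Sigma70_r4_2")) {
    e <- classify_ecf(annotate_roles(resolve_architectures(mk_arch("p", only))))
    expect_false(e$is_ecf, info = only)
  }
})

test_that("kinase and phosphatase systems follow their architecture rules", {
  h <- dplyr::bind_rows(
    mk_arch("estyk", "Pkinase"),
    mk_arch("bif", c("Pkinase", "PP2C")),
    mk_arch("sstyk", "HATPase_c_3"),
    mk_arch("pp2c", c("Cache_1", "PP2C")),
    mk_arch("stas", "STAS"),
    mk_arch("crp", "Crp"),
    mk_arch("ac", c("CHASE2", "Adenylate_cycl")),
    mk_arch("chea", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("hk", c("HisKA", "HATPase_c"))
  )
  a <- aux_of(h)
  expect_equal(unname(a["estyk"]), "eSTYK")
  expect_equal(unname(a["bif"]), "bifunctional_PP2C_Pkinase")
  expect_equal(unname(a["sstyk"]), "stas_STYK")
  expect_equal(unname(a["pp2c"]), "PP2C")
  expect_equal(unname(a["stas"]), "STAS")
  expect_equal(unname(a["crp"]), "CRP_like")
  expect_equal(unname(a["ac"]), "AC")
  # CheA (Hpt blocks stas_STYK) and classical HKs match no alternative system
  expect_false("chea" %in% names(a))
  expect_false("hk" %in% names(a))
})

test_that("sigma/anti-sigma clusters require FecR within the window", {
  build <- function(gap) {
    pids <- c("ecf", "tonb", rep(NA_character_, gap - 1), "fecr")
    g <- mk_genes(pids)
    h <- dplyr::bind_rows(
      mk_arch("ecf", c("Sigma70_r2", "Sigma70_r4_2")),
      mk_arch("fecr", "FecR"),
      mk_arch("tonb", "TonB_dep_Rec")
    )
    res <- annotate_roles(resolve_architectures(h))
    detect_ecf242(g, res, classify_aux(res))
  }
  near <- build(4)   # FecR at exactly four intervening genes
  expect_equal(nrow(near), 1)
  expect_equal(near$ecf_gene_id, "g001")
  expect_true("g002" %in% near$tonb_gene_ids[[1]])
  far <- build(5)    # one gene farther: no candidate
  expect_equal(nrow(far), 0)
})

test_that("cAMP clusters need a cyclase with two of three partners", {
  mk <- function(partners) {
    pids <- c("ac", partners)
    g <- mk_genes(pids)
    archs <- list(ac = c("CHASE2", "Adenylate_cycl"), pde = "PDEase_I",
                  fecr = "FecR", tpr = "TPR_1")
    h <- dplyr::bind_rows(lapply(pids, function(p) mk_arch(p, archs[[p]])))
    res <- annotate_roles(resolve_architectures(h))
    detect_camp_clusters(g, res, classify_aux(res))
  }
  full <- mk(c("pde", "fecr", "tpr"))
  expect_true(full$cyclases$cluster)
  two <- mk(c("pde", "tpr"))
  expect_true(two$cyclases$cluster)
  one <- mk("pde")
  expect_false(one$cyclases$cluster)
})

test_that("CRP homologs without any cyclase are flagged", {
  g <- mk_genes("crp")
  res <- annotate_roles(resolve_architectures(mk_arch("crp", "Crp")))
  d <- detect_camp_clusters(g, res, classify_aux(res))
  expect_true(d$crp_without_cyclase)
  expect_equal(d$n_crp, 1L)
  # with a cyclase elsewhere the flag clears
  g2 <- mk_genes(c("crp", rep(NA_character_, 8), "ac"))
  h2 <- dplyr::bind_rows(mk_arch("crp", "Crp"),
                         mk_arch("ac", c("CHASE2", "Adenylate_cycl")))
  res2 <- annotate_roles(resolve_architectures(h2))
  d2 <- detect_camp_clusters(g2, res2, classify_aux(res2))
  expect_false(d2$crp_without_cyclase)
})

test_that("quorum-sensing pathways need synthase and receptor together", {
  both <- mk_hits(c("s", "r"), c("Autoind_synth", "Autoind_bind"),
                  c(10, 10), c(200, 200))
  q <- qs_screen(both)
  expect_equal(q$status[q$pathway == "AHL"], "present")
  syn_only <- mk_hits("s", "LuxS", 10, 150)
  q2 <- qs_screen(syn_only)
  expect_equal(q2$status[q2$pathway == "AI2"], "partial")
  expect_false(any(q2$present))
  q3 <- qs_screen(mk_hits("x", "ABC_tran", 10, 150))
  expect_true(all(q3$status == "absent"))
})

test_that("combined-pathway neighborhoods require every partner in the window", {
  pids <- c("pp2c", "sstyk", "stas", "dgc")
  g <- mk_genes(pids)
  archs <- list(pp2c = c("Cache_1", "PP2C"), sstyk = "HATPase_c_3",
                stas = "STAS", dgc = c("PAS", "GGDEF"))
  h <- dplyr::bind_rows(lapply(pids, function(p) mk_arch(p, archs[[p]])))
  res <- annotate_roles(resolve_architectures(h))
  aux <- classify_aux(res)
  cd <- identify_cdgmp(res)
  d <- detect_combined_pathways(g, res, aux, cd)
  expect_true("pp2c_styk_stas_cdgmp" %in% d$rule)
  expect_equal(d$confidence[d$rule == "pp2c_styk_stas_cdgmp"], "unverified")
  # drop the enzyme: the rule no longer fires
  keep <- pids[pids != "dgc"]
  g2 <- mk_genes(keep)
  h2 <- dplyr::bind_rows(lapply(keep, function(p) mk_arch(p, archs[[p]])))
  res2 <- annotate_roles(resolve_architectures(h2))
  d2 <- detect_combined_pathways(g2, res2, classify_aux(res2),
                                 identify_cdgmp(res2))
  expect_false("pp2c_styk_stas_cdgmp" %in% d2$rule)
})

test_that("a partial sigma gene with a nearby cyclase is a merged-pathway candidate", {
  g <- mk_genes(c("sig", "ac"))
  h <- dplyr::bind_rows(mk_arch("sig", "Sigma70_r2"),
                        mk_arch("ac", c("CHASE2", "Adenylate_cycl")))
  res <- annotate_roles(resolve_architectures(h))
  d <- detect_combined_pathways(g, res, classify_aux(res),
                                identify_cdgmp(res))
  expect_true("ecf_partial_plus_cyclase" %in% d$rule)
  # transmembrane evidence upgrades confidence
  d2 <- detect_combined_pathways(g, res, classify_aux(res),
                                 identify_cdgmp(res), tm_proteins = "ac")
  expect_equal(d2$confidence[d2$rule == "ecf_partial_plus_cyclase"], "high")
})

test_that("receiver-fused kinase-phosphatase proteins anchor the receptor rule", {
  pids <- c("bifrec", "stas", "mcp")
  g <- mk_genes(pids)
  archs <- list(bifrec = c("Response_reg", "Pkinase", "PP2C"), stas = "STAS",
                mcp = "MCPsignal")
  h <- dplyr::bind_rows(lapply(pids, function(p) mk_arch(p, archs[[p]])))
  res <- annotate_roles(resolve_architectures(h))
  d <- detect_combined_pathways(g, res, classify_aux(res),
                                identify_cdgmp(res))
  expect_true("rec_pp2c_styk_mcp" %in% d$rule)
})
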