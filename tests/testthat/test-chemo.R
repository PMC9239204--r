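comp_of <- function(hits) {
  c <- identify_che_components(annotate_roles(resolve_architectures(hits)))
  stats::setNames(c$component, c$protein_id)
}

test_that("chemosensory components are recognized from their architectures", {
  h <- dplyr::bind_rows(
    mk_arch("mcp", "MCPsignal"),
    mk_arch("cheA", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("cheV", c("CheW", "Response_reg")),
    mk_arch("cheW", "CheW"),
    mk_arch("cheB", c("Response_reg", "CheB_methylest")),
    mk_arch("cheR", "CheR"),
    mk_arch("cheD", "CheD"),
    mk_arch("stas", "STAS")
  )
  cmp <- comp_of(h)
  expect_equal(unname(cmp[c("mcp", "cheA", "cheV", "cheW", "cheB", "cheR",
                            "cheD", "stas")]),
               c("MCP", "CheA", "CheV", "CheW", "CheB", "CheR", "CheD",
                 "STAS"))
})

test_that("a receiver fused to CheW is CheV, not CheW", {
  cmp <- comp_of(mk_arch("p", c("CheW", "Response_reg")))
  expect_equal(unname(cmp["p"]), "CheV")
})

test_that("clusters chain component genes across gaps of at most two", {
  pids <- c("cheV", "cheA", NA, NA, "cheW", rep(NA, 4), "mcp1", "mcp2")
  g <- mk_genes(pids)
  h <- dplyr::bind_rows(
    mk_arch("cheV", c("CheW", "Response_reg")),
    mk_arch("cheA", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("cheW", "CheW"),
    mk_arch("mcp1", "MCPsignal"), mk_arch("mcp2", "MCPsignal")
  )
  comps <- identify_che_components(annotate_roles(resolve_architectures(h)))
  cl <- find_che_clusters(g, comps)
  expect_equal(nrow(cl), 2)
  sizes <- sort(vapply(cl$gene_ids, length, integer(1)))
  expect_equal(sizes, c(2L, 3L))
})

test_that("a lone chemoreceptor gene is not a cluster but still a receptor", {
  g <- mk_genes(c("mcp", NA, NA, NA, "other"))
  h <- mk_arch("mcp", "MCPsignal")
  comps <- identify_che_components(annotate_roles(resolve_architectures(h)))
  cl <- find_che_clusters(g, comps)
  expect_equal(nrow(cl), 0)
  expect_equal(count_chemoreceptors(comps), 1L)
})

test_that("cluster token strings mark components, kinases and other genes", {
  pids <- c("cheV", "cheA", "hk", "x", "cheW")
  g <- mk_genes(pids)
  h <- dplyr::bind_rows(
    mk_arch("cheV", c("CheW", "Response_reg")),
    mk_arch("cheA", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("hk", c("HisKA", "HATPase_c")),
    mk_arch("cheW", "CheW")
  )
  res <- annotate_roles(resolve_architectures(h))
  comps <- identify_che_components(res)
  tcs <- classify_tcs(res)
  tok <- tokenize_cluster(g, comps, "chr1", 0L, 4L, tcs)
  expect_equal(tok, c("V", "A", "K", ".", "W"))
})

test_that("signature order scoring equals the exhaustive alignment oracle", {
  set.seed(11)
  sigs <- default_f_signatures()
  for (i in 1:200) {
    rc <- oracle_random_cluster(12)
    for (sig in sigs) {
      got <- sigcensus:::signature_order_score(sig, rc$tokens)$score
      want <- oracle_order_score(sig, rc$tokens)
      expect_equal(got, want,
                   info = paste(sig$class_name, paste(rc$tokens, collapse = "")))
    }
  }
})

test_that("order scores are invariant to cluster orientation", {
  set.seed(12)
  sigs <- default_f_signatures()
  for (i in 1:50) {
    rc <- oracle_random_cluster(10)
    for (sig in sigs) {
      f <- sigcensus:::signature_order_score(sig, rc$tokens)$score
      r <- sigcensus:::signature_order_score(sig, rev(rc$tokens))$score
      expect_equal(f, r)
    }
  }
})

test_that("a full matching signature in reverse orientation scores 1", {
  sig <- default_f_signatures()[[2]] # A W M B R
  s <- sigcensus:::signature_order_score(sig, rev(c("A", "W", "M", "B", "R")))
  expect_equal(s$score, 1)
  expect_equal(s$orientation, "reverse")
})

test_that("removing required components never increases completeness", {
  sigs <- default_f_signatures()
  f9 <- sigs[[4]]
  toks <- c("M", "W", "A", "B", "R", "Y")
  comp_full <- tibble::tibble(
    protein_id = sprintf("p%d", 1:6),
    component = c("MCP", "CheW", "CheA", "CheB", "CheR", "CheY"),
    has_rec = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  prev <- Inf
  for (k in 6:1) {
    a <- assign_f_class(toks[1:k], comp_full[1:k, ], comp_full[1:k, ], sigs)
    expect_lte(a$completeness, prev)
    prev <- a$completeness
  }
})

test_that("a complete cluster beats a shorter signature nested inside its own", {
  # the F7 order (A W M B R) is a subsequence of F14 (S A W M B R D); a full
  # F14 cluster must be called F14
  comp <- tibble::tibble(
    protein_id = sprintf("p%d", 1:7),
    component = c("STAS", "CheA", "CheW", "MCP", "CheB", "CheR", "CheD"),
    has_rec = FALSE
  )
  a <- assign_f_class(c("S", "A", "W", "M", "B", "R", "D"), comp, comp)
  expect_equal(a$class, "F14")
  expect_equal(a$status, "full")
})

test_that("clusters matching no signature above the floor stay unassigned", {
  comp <- tibble::tibble(protein_id = "p1", component = "CheR",
                         has_rec = FALSE)
  a <- assign_f_class(c("R"), comp, comp)
  expect_equal(a$class, "unassigned")
  expect_equal(a$status, "none")
})

test_that("single receiver proteins beside a cluster are called CheY", {
  pids <- c("cheW2", "cheA", "cheW", "chey", NA, "far_rec")
  g <- mk_genes(pids)
  h <- dplyr::bind_rows(
    mk_arch("cheW2", "CheW"),
    mk_arch("cheA", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("cheW", "CheW"),
    mk_arch("chey", "Response_reg"),
    mk_arch("far_rec", "Response_reg")
  )
  res <- annotate_roles(resolve_architectures(h))
  ch <- chemo_census(g, res)
  comp <- ch$components
  expect_true(any(comp$component == "CheY" & comp$protein_id == "chey"))
  expect_false(any(comp$protein_id == "far_rec"))
})

test_that("the canonical compact cluster with aux components classifies as F3", {
  # cheV-cheA(REC)-cheW cluster plus a genome-wide receiver-less CheB
  pids <- c("cheV", "cheA", "cheW", rep(NA_character_, 9), "cheB")
  g <- mk_genes(pids)
  h <- dplyr::bind_rows(
    mk_arch("cheV", c("CheW", "Response_reg")),
    mk_arch("cheA", c("Hpt", "HATPase_c", "Response_reg")),
    mk_arch("cheW", "CheW"),
    mk_arch("cheB", "CheB_methylest")
  )
  res <- annotate_roles(resolve_architectures(h))
  ch <- chemo_census(g, res)
  main <- ch$assignments[ch$assignments$class != "unassigned", ]
  expect_equal(nrow(main), 1)
  expect_equal(main$class, "F3")
  expect_equal(main$status, "full")
})
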