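pad <- function(n) strrep("A", n)

test_that("each catalytically competent A-site motif is called active", {
  for (m in c("GGDEF", "GGEEF", "SGDEF", "AGDEF")) {
    s <- paste0(pad(30), "LKT", m, "QRS", pad(30))
    a <- call_a_site(s, 10, nchar(s) - 5)
    expect_equal(a$state, "active", info = m)
    expect_equal(a$motif, m)
    expect_equal(substr(s, a$position, a$position + 4), m)
  }
})

test_that("a single-residue A-site mutation flips active to degenerate", {
  good <- paste0(pad(30), "LKTGGDEFQRS", pad(30))
  mut <- sub("GGDEF", "GGDQF", good)
  expect_equal(call_a_site(good, 5, nchar(good))$state, "active")
  a <- call_a_site(mut, 5, nchar(mut))
  expect_equal(a$state, "degenerate")
  expect_equal(a$motif, "GGDQF")
})

test_that("degenerate motifs are anchored by the relaxed two-stage pattern", {
  # stage 1: xG[DE][EQ]F
  s1 <- paste0(pad(20), "TGDQF", pad(20))
  a1 <- call_a_site(s1, 1, nchar(s1))
  expect_equal(a1$state, "degenerate")
  expect_equal(a1$motif, "TGDQF")
  # stage 2 only: xx[DE]EF without G at the second slot
  s2 <- paste0(pad(20), "KTDEF", pad(20))
  a2 <- call_a_site(s2, 1, nchar(s2))
  expect_equal(a2$state, "degenerate")
  expect_equal(a2$motif, "KTDEF")
  # nothing F-like at all: unanchored degenerate
  s3 <- strrep("K", 60)
  a3 <- call_a_site(s3, 1, 60)
  expect_equal(a3$state, "degenerate")
  expect_equal(a3$motif, "")
  expect_true(is.na(a3$position))
})

test_that("sequences shorter than the domain interval give an unknown call", {
  expect_warning(a <- call_a_site("MKV", 1, 100), "cover")
  expect_equal(a$state, "unknown")
})

test_that("the I-site is an RxxD in the 15 residues upstream of the A-site", {
  s <- paste0(pad(20), "RSSD", "LKGGHT", "GGDEF", pad(20))
  a <- call_a_site(s, 1, nchar(s))
  expect_equal(a$state, "active")
  expect_equal(call_i_site(s, a$position), "present")
  # same protein with the arginine removed
  s2 <- sub("RSSD", "ASSD", s)
  a2 <- call_a_site(s2, 1, nchar(s2))
  expect_equal(call_i_site(s2, a2$position), "absent")
  # no anchored A-site means no I-site call
  expect_equal(call_i_site(s, NA_integer_), "unknown")
})

test_that("an RxxD outside the upstream window does not count", {
  s <- paste0("RSSD", pad(40), "GGDEF", pad(10))
  a <- call_a_site(s, 1, nchar(s))
  expect_equal(call_i_site(s, a$position), "absent")
})

test_that("enzyme identification keys on GGDEF, EAL and HD-GYP domains", {
  h <- dplyr::bind_rows(
    mk_arch("dgc", c("PAS", "GGDEF")),
    mk_arch("pde", c("PAS", "EAL")),
    mk_arch("hd", "HD-GYP"),
    mk_arch("bif", c("GGDEF", "EAL")),
    mk_arch("rrdgc", c("Response_reg", "GGDEF")),
    mk_arch("not_enzyme", c("HisKA", "HATPase_c"))
  )
  cd <- identify_cdgmp(annotate_roles(resolve_architectures(h)))
  expect_setequal(cd$protein_id, c("dgc", "pde", "hd", "bif", "rrdgc"))
  expect_true(cd$has_rec[cd$protein_id == "rrdgc"])
  expect_equal(cd$n_partner[cd$protein_id == "dgc"], 1L)
  expect_equal(cd$n_partner[cd$protein_id == "hd"], 0L)
})

test_that("the six census categories are tallied with bifunctionals set apart", {
  cd <- tibble::tibble(
    protein_id = c("a", "b", "c", "d", "e", "f"),
    has_ggdef = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    has_eal = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    has_hdgyp = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    has_rec = FALSE,
    n_partner = c(1L, 0L, 1L, 1L, 0L, 0L),
    partner_domains = list("PAS", character(), "PAS", "PAS", character(),
                           character()),
    n_hits = c(2L, 1L, 2L, 3L, 1L, 1L)
  )
  motifs <- tibble::tibble(protein_id = c("a", "b", "d", "e"),
                           a_site = c("active", "active", "active", "degenerate"),
                           a_site_motif = "GGDEF", i_site = "present")
  k <- categorize_cdgmp(cd, motifs)
  expect_equal(k$total_dgc, 4)        # a, b, d, e (degenerate included)
  expect_equal(k$dgc_with_partner, 1) # a only: d is bifunctional
  expect_equal(k$pde_with_partner, 1) # c
  expect_equal(k$bifunctional, 1)     # d
  expect_equal(k$single_domain, 3)    # b, e, f
  expect_equal(k$active_dgc, 3)       # a, b, d
  expect_equal(k$n_enzymes, 6)
  # flag variants
  k2 <- categorize_cdgmp(cd, motifs, include_degenerate = FALSE)
  expect_equal(k2$total_dgc, 3)
  k3 <- categorize_cdgmp(cd, motifs, bifunctional_in_partner = TRUE)
  expect_equal(k3$dgc_with_partner, 2)
})

test_that("receiver-bearing enzymes are flagged when a kinase gene is near", {
  g <- mk_genes(c("hk", NA, "rrdgc", rep(NA_character_, 6), "fardgc"))
  h <- dplyr::bind_rows(
    mk_arch("hk", c("HisKA", "HATPase_c")),
    mk_arch("rrdgc", c("Response_reg", "GGDEF")),
    mk_arch("fardgc", c("Response_reg", "GGDEF"))
  )
  res <- annotate_roles(resolve_architectures(h))
  tcs <- classify_tcs(res)
  cd <- flag_near_hk(g, identify_cdgmp(res), tcs)
  expect_true(cd$near_hk[cd$protein_id == "rrdgc"])
  expect_false(cd$near_hk[cd$protein_id == "fardgc"])
})

test_that("protein-level motif calls take the best state over multiple domains", {
  s_active <- paste0(pad(10), "GGDEF", pad(40), "GGDAF", pad(10))
  h <- mk_hits(c("p1", "p1"), c("GGDEF", "GGDEF"), c(5, 50), c(25, 70))
  m <- call_motifs(annotate_roles(resolve_architectures(h)),
                   c(p1 = s_active))
  expect_equal(m$a_site, "active")
})
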