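# Independent brute-force oracles, written from the rule definitions rather
# than from the implementations they check.

# Exhaustive signature order score: enumerate every subset of signature
# tokens (kept in order); a subset counts when it occurs as a subsequence of
# the cluster whose span contains at most `allowed` unmatched genes. For a
# fixed start, greedy left-to-right matching gives the minimal span, so
# scanning all starts covers all windows. Returns the per-orientation
# maximum matched count / core length.
.oracle_subset_cache <- new.env(parent = emptyenv())

oracle_subsets <- function(m, k) {
  key <- paste0(m, "_", k)
  if (is.null(.oracle_subset_cache[[key]])) {
    .oracle_subset_cache[[key]] <- utils::combn(m, k, simplify = FALSE)
  }
  .oracle_subset_cache[[key]]
}

oracle_order_score <- function(sig, tokens) {
  core <- sig$gene_order[sig$gene_order != "."]
  allowed <- sig$max_insertions + sum(sig$gene_order == ".")
  m <- length(core)
  if (m == 0) return(0)
  # minimal span of s as a subsequence of tk starting at any position,
  # Inf when s does not occur
  feasible <- function(s, tk) {
    n <- length(tk)
    k <- length(s)
    if (n < k) return(FALSE)
    for (a in seq_len(n - k + 1L)) {
      if (tk[a] != s[1L]) next
      j <- 2L
      e <- a
      while (j <= k && e < n) {
        e <- e + 1L
        if (tk[e] == s[j]) j <- j + 1L
      }
      if (j > k && (e - a + 1L) - k <= allowed) return(TRUE)
    }
    FALSE
  }
  best_for <- function(tk) {
    if (length(tk) == 0) return(0L)
    for (k in m:1) {
      for (ix in oracle_subsets(m, k)) {
        if (feasible(core[ix], tk)) return(k)
      }
    }
    0L
  }
  max(best_for(tokens), best_for(rev(tokens))) / m
}

# Random cluster generator for oracle comparisons: a token string of length
# 1..max_len plus a component table consistent with the tokens.
oracle_random_cluster <- function(max_len = 12) {
  alphabet <- c("A", "B", "C", "D", "K", "M", "R", "S", "V", "W", "X", "Y",
                "Z", ".")
  n <- sample.int(max_len, 1)
  tokens <- sample(alphabet, n, replace = TRUE)
  tok2comp <- c(A = "CheA", B = "CheB", C = "CheC", D = "CheD", M = "MCP",
                R = "CheR", S = "STAS", V = "CheV", W = "CheW", X = "CheX",
                Y = "CheY", Z = "CheZ")
  comp <- tok2comp[tokens[tokens %in% names(tok2comp)]]
  comps <- tibble::tibble(
    protein_id = sprintf("rc_p%03d", seq_along(comp)),
    component = unname(comp),
    has_rec = stats::runif(length(comp)) < 0.5
  )
  list(tokens = tokens, components = comps)
}
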