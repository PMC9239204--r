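#' Identify chemosensory pathway components
#'
#' Maps each protein onto a chemosensory component from its diagnostic
#' domains: CheA (HATPase + Hpt, with or without REC), CheV (CheW-type domain
#' + REC), CheW (CheW-type domain alone), CheB (methylesterase domain, with or
#' without REC), CheR, CheC, CheX, CheD, CheZ, MCP (chemoreceptor signaling
#' domain), and STAS (a single STAS domain). CheY -- a single-REC-domain
#' protein -- is *not* assigned here: it is only called in the context of a
#' chemosensory gene cluster (see [chemo_census()]), so that orphan response
#' regulators are not swallowed.
#'
#' When a protein matches two components the first in the precedence order
#' MCP, CheA, CheV, CheB, CheR, CheC, CheX, CheD, CheZ, CheW, STAS wins, with
#' a warning.
#'
#' @param hits Resolved, role-annotated domain hits.
#' @param vocab Domain vocabulary.
#' @return Tibble `protein_id`, `component`, `has_rec` for matching proteins.
#' @export
identify_che_components <- function(hits, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  s <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    n_hits = dplyr::n(),
    has_rec = any(.data$role %in% "REC"),
    has_hatpase = any(.data$role %in% "HATPase"),
    has_hpt = any(.data$role %in% "Hpt"),
    has_chew = any(.data$role %in% "CheW"),
    has_cheb = any(.data$role %in% "CheB"),
    has_cher = any(.data$role %in% "CheR"),
    has_chec = any(.data$role %in% "CheC"),
    has_chex = any(.data$role %in% "CheX"),
    has_ched = any(.data$role %in% "CheD"),
    has_chez = any(.data$role %in% "CheZ"),
    has_mcp = any(.data$role %in% "MCPsignal"),
    single_stas = dplyr::n() == 1 && all(.data$role %in% "STAS"),
    .groups = "drop"
  )
  cand <- cbind(
    MCP = s$has_mcp,
    CheA = s$has_hatpase & s$has_hpt,
    CheV = s$has_chew & s$has_rec,
    CheB = s$has_cheb,
    CheR = s$has_cher,
    CheC = s$has_chec,
    CheX = s$has_chex,
    CheD = s$has_ched,
    CheZ = s$has_chez,
    CheW = s$has_chew & !s$has_rec,
    STAS = s$single_stas
  )
  nm <- rowSums(cand)
  if (any(nm > 1)) {
    warning(sum(nm > 1), " protein(s) matched multiple chemosensory ",
            "components; precedence order applied")
  }
  keep <- nm > 0
  comp <- apply(cand[keep, , drop = FALSE], 1L,
                function(r) colnames(cand)[which(r)[1]])
  tibble::tibble(protein_id = s$protein_id[keep], component = comp,
                 has_rec = s$has_rec[keep])
}

#' Group chemosensory genes into genomic clusters
#'
#' Chains genes encoding chemosensory components when at most `max_gap`
#' non-chemosensory genes intervene. Clusters consisting of a single
#' chemoreceptor (MCP) gene are dropped: lone receptors are counted
#' separately, not treated as pathway clusters.
#'
#' @param genes Gene tibble.
#' @param components Output of [identify_che_components()] (optionally with
#'   CheY rows added).
#' @param max_gap Maximum intervening non-chemosensory genes (default 2).
#' @return Tibble `cluster_id`, `replicon`, `ordinal_start`, `ordinal_end`,
#'   `gene_ids` (list), `n_genes`.
#' @export
find_che_clusters <- function(genes, components, max_gap = 2) {
  cg <- genes[!is.na(genes$protein_id) &
                genes$protein_id %in% components$protein_id, , drop = FALSE]
  cg <- dplyr::arrange(cg, .data$replicon, .data$ordinal)
  if (nrow(cg) == 0) {
    return(tibble::tibble(cluster_id = integer(), replicon = character(),
                          ordinal_start = integer(), ordinal_end = integer(),
                          gene_ids = list(), n_genes = integer()))
  }
  grp <- chain_across_replicons(cg$replicon, cg$ordinal, max_gap)
  idx <- unname(split(seq_len(nrow(cg)), grp))
  out <- tibble::tibble(
    replicon = vapply(idx, function(j) cg$replicon[j[1]], character(1)),
    ordinal_start = vapply(idx, function(j) as.integer(min(cg$ordinal[j])), integer(1)),
    ordinal_end = vapply(idx, function(j) as.integer(max(cg$ordinal[j])), integer(1)),
    gene_ids = lapply(idx, function(j) cg$gene_id[j]),
    n_genes = lengths(idx)
  )
  if (nrow(out) > 0) {
    singleton_mcp <- vapply(seq_len(nrow(out)), function(i) {
      ids <- out$gene_ids[[i]]
      if (length(ids) != 1) return(FALSE)
      pid <- genes$protein_id[match(ids, genes$gene_id)]
      comp <- components$component[match(pid, components$protein_id)]
      identical(comp, "MCP")
    }, logical(1))
    out <- out[!singleton_mcp, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$replicon, .data$ordinal_start)
  tibble::tibble(cluster_id = seq_len(nrow(out)), out)
}

# single-token abbreviations used in gene-order signatures
che_token_map <- c(CheA = "A", CheB = "B", CheC = "C", CheD = "D", MCP = "M",
                   CheR = "R", STAS = "S", CheV = "V", CheW = "W", CheX = "X",
                   CheY = "Y", CheZ = "Z")

#' Tokenize a cluster's gene neighborhood
#'
#' Converts the genes spanning a cluster's ordinal range into the single-letter
#' token string used by gene-order signatures: A cheA, B cheB, D cheD, K a
#' histidine kinase gene, M chemoreceptor, R cheR, S a lone STAS-domain gene,
#' V cheV, W cheW, Y cheY (plus C/X/Z), and `.` for anything else.
#'
#' @param genes Gene tibble.
#' @param components Chemosensory components (with CheY rows if called).
#' @param replicon,ordinal_start,ordinal_end Cluster location.
#' @param tcs_roles Optional [classify_tcs()] output; histidine kinase genes
#'   then tokenize as `K`.
#' @return Character vector of tokens in gene order.
#' @export
tokenize_cluster <- function(genes, components, replicon, ordinal_start,
                             ordinal_end, tcs_roles = NULL) {
  g <- genes[genes$replicon == replicon & genes$ordinal >= ordinal_start &
               genes$ordinal <= ordinal_end, , drop = FALSE]
  g <- dplyr::arrange(g, .data$ordinal)
  comp <- components$component[match(g$protein_id, components$protein_id)]
  tok <- unname(che_token_map[comp])
  if (!is.null(tcs_roles)) {
    role <- tcs_roles$role[match(g$protein_id, tcs_roles$protein_id)]
    tok[is.na(tok) & role %in% c("HK", "HHK", "HRR")] <- "K"
  }
  tok[is.na(tok)] <- "."
  tok
}

#' Chemosensory class signatures
#'
#' A signature defines one chemosensory class as data: a `gene_order` token
#' string, the set of `required_components`, optional `auxiliary_rules`
#' (currently `cheA_has_rec` -- a cluster CheA carries a REC domain -- and
#' `aux_cheB_without_rec` -- a CheB lacking REC exists anywhere in the
#' genome), and `max_insertions`, the number of unexpected genes tolerated
#' inside the matched gene order. `default_f_signatures()` ships F3 as
#' defined by its text description (cheVAW core operon, REC in CheA,
#' auxiliary REC-less CheB) plus best-effort gene orders for F7/F8/F9/F14
#' transcribed from published cluster diagrams; `read_f_signatures()` loads
#' the same structure from YAML so users can replace them.
#'
#' @param path YAML file with a `signatures` list.
#' @return A list of signature lists, in priority order (ties in assignment
#'   scoring go to the earlier signature).
#' @export
default_f_signatures <- function() {
  list(
    list(class_name = "F3", gene_order = c("V", "A", "W"),
         required_components = c("CheV", "CheA", "CheW"),
         auxiliary_rules = c("cheA_has_rec", "aux_cheB_without_rec"),
         max_insertions = 1L),
    list(class_name = "F7", gene_order = c("A", "W", "M", "B", "R"),
         required_components = c("CheA", "CheW", "MCP", "CheB", "CheR"),
         auxiliary_rules = character(), max_insertions = 2L),
    list(class_name = "F8", gene_order = c("W", "A", "Y", "M", "R", "B"),
         required_components = c("CheW", "CheA", "CheY", "MCP", "CheR", "CheB"),
         auxiliary_rules = character(), max_insertions = 2L),
    list(class_name = "F9", gene_order = c("M", "W", "A", "B", "R", "Y"),
         required_components = c("MCP", "CheW", "CheA", "CheB", "CheR", "CheY"),
         auxiliary_rules = character(), max_insertions = 2L),
    list(class_name = "F14", gene_order = c("S", "A", "W", "M", "B", "R", "D"),
         required_components = c("STAS", "CheA", "CheW", "MCP", "CheB",
                                 "CheR", "CheD"),
         auxiliary_rules = character(), max_insertions = 2L)
  )
}

#' @rdname default_f_signatures
#' @export
read_f_signatures <- function(path) {
  y <- yaml::read_yaml(path)
  sigs <- y$signatures %||% y
  lapply(sigs, function(s) {
    list(class_name = as.character(s$class_name),
         gene_order = as.character(s$gene_order),
         required_components = as.character(s$required_components),
         auxiliary_rules = as.character(s$auxiliary_rules %||% character()),
         max_insertions = as.integer(s$max_insertions %||% 1L))
  })
}

# Best number of signature tokens matchable in order inside the cluster token
# string, allowing up to `allowed` skipped cluster genes between the first and
# last matched token. Window formulation: for every window of the cluster no
# longer than m + allowed, count the longest common subsequence with the
# signature; the window is feasible when its length minus the match count is
# within the allowance.
align_tokens <- function(sig, tokens, allowed) {
  n <- length(tokens)
  m <- length(sig)
  if (n == 0 || m == 0) return(0L)
  best <- 0L
  for (a in seq_len(n)) {
    for (b in a:min(n, a + m + allowed - 1L)) {
      k <- lcs_length(sig, tokens[a:b])
      if ((b - a + 1L) - k <= allowed) best <- max(best, k)
    }
  }
  best
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# order score of one signature against a token string, best orientation.
# Signature "." tokens are expected hypothetical genes: they are removed and
# converted into extra insertion allowance.
signature_order_score <- function(sig, tokens) {
  core <- sig$gene_order[sig$gene_order != "."]
  allowed <- sig$max_insertions + sum(sig$gene_order == ".")
  if (length(core) == 0) return(list(score = 0, orientation = "forward"))
  fwd <- align_tokens(core, tokens, allowed)
  rev_ <- align_tokens(core, rev(tokens), allowed)
  if (rev_ > fwd) list(score = rev_ / length(core), orientation = "reverse")
  else list(score = fwd / length(core), orientation = "forward")
}

aux_rule_ok <- function(rule, cluster_components, genome_components) {
  switch(rule,
    cheA_has_rec = any(cluster_components$component == "CheA" &
                         cluster_components$has_rec),
    aux_cheB_without_rec = any(genome_components$component == "CheB" &
                                 !genome_components$has_rec),
    stop("unknown auxiliary rule: ", rule)
  )
}

#' Assign a chemosensory class to a gene cluster
#'
#' Scores every signature against the cluster. A signature is eligible when
#' its gene order matches the cluster's token string -- in either orientation,
#' tolerating its insertion allowance -- at an order score (matched /
#' signature length) of at least `floor`. Among eligible signatures the
#' winner maximises, in order: order score, then the fraction of required
#' components present in the cluster together with satisfied auxiliary rules,
#' then signature priority. Completeness is the fraction of required
#' components present in the cluster; status is `full` at completeness 1,
#' `half` inside `half_band`, `none` at 0 and `partial` otherwise.
#'
#' @param tokens Token string of the cluster (see [tokenize_cluster()]).
#' @param cluster_components Components of the cluster's genes (rows of the
#'   component table).
#' @param genome_components Component table for the whole genome (auxiliary
#'   rules may look outside the cluster).
#' @param signatures Signature list (see [default_f_signatures()]).
#' @param floor Minimum order score for eligibility (default 0.4).
#' @param half_band Completeness band reported as `half` (default
#'   `c(0.4, 0.8)`, lower inclusive, upper exclusive).
#' @return One-row tibble: `class`, `status`, `completeness`, `order_score`,
#'   `orientation`.
#' @export
assign_f_class <- function(tokens, cluster_components, genome_components,
                           signatures = default_f_signatures(),
                           floor = 0.4, half_band = c(0.4, 0.8)) {
  unassigned <- tibble::tibble(class = "unassigned", status = "none",
                               completeness = 0, order_score = 0,
                               orientation = NA_character_)
  if (length(tokens) == 0 || length(signatures) == 0) return(unassigned)
  rows <- purrr::imap(signatures, function(sig, i) {
    os <- signature_order_score(sig, tokens)
    req <- sig$required_components
    present <- sum(req %in% cluster_components$component)
    aux <- sig$auxiliary_rules
    aux_ok <- vapply(aux, aux_rule_ok, logical(1),
                     cluster_components = cluster_components,
                     genome_components = genome_components)
    core_len <- sum(sig$gene_order != ".")
    tibble::tibble(
      class = sig$class_name, priority = i,
      order_score = os$score, orientation = os$orientation,
      n_matched = round(os$score * core_len),
      completeness = if (length(req) > 0) present / length(req) else 0,
      rank_score = (present + sum(aux_ok)) / (length(req) + length(aux))
    )
  })
  sc <- dplyr::bind_rows(rows)
  sc <- sc[sc$order_score >= floor, , drop = FALSE]
  if (nrow(sc) == 0) return(unassigned)
  # n_matched breaks order-score ties toward the more specific signature: a
  # signature that is a subsequence of a longer one (F7 inside F14) must not
  # claim clusters the longer signature explains in full
  sc <- sc[order(-sc$order_score, -sc$n_matched, -sc$rank_score, sc$priority),
           , drop = FALSE]
  win <- sc[1, ]
  status <- if (win$completeness >= 1) "full"
    else if (win$completeness >= half_band[1] && win$completeness < half_band[2]) "half"
    else if (win$completeness > 0) "partial" else "none"
  tibble::tibble(class = win$class, status = status,
                 completeness = win$completeness,
                 order_score = win$order_score, orientation = win$orientation)
}

#' Count chemoreceptor genes genome-wide
#'
#' @param components Chemosensory component table.
#' @return Number of MCP (chemoreceptor) proteins, inside or outside clusters.
#' @export
count_chemoreceptors <- function(components) {
  sum(components$component == "MCP")
}

#' Run the full chemosensory census for one genome
#'
#' Identifies components, finds clusters, calls CheY (a single-REC-domain
#' protein located inside or immediately adjacent to a chemosensory cluster),
#' re-clusters with CheY included, and assigns a class to every cluster.
#'
#' @param genes Gene tibble.
#' @param hits Resolved, role-annotated domain hits.
#' @param tcs_roles Optional [classify_tcs()] output (for `K` tokens).
#' @param vocab Domain vocabulary.
#' @param signatures Signature list.
#' @param max_gap Cluster chaining gap (default 2).
#' @param floor,half_band Passed to [assign_f_class()].
#' @return A list: `components` (with CheY rows), `clusters`, `assignments`
#'   (one row per cluster), `n_receptors`.
#' @export
chemo_census <- function(genes, hits, tcs_roles = NULL,
                         vocab = default_vocabulary(),
                         signatures = default_f_signatures(), max_gap = 2,
                         floor = 0.4, half_band = c(0.4, 0.8)) {
  hits <- ensure_roles(hits, vocab)
  comps <- identify_che_components(hits, vocab)
  clusters <- find_che_clusters(genes, comps, max_gap)
  chey <- call_chey(genes, hits, comps, clusters)
  if (nrow(chey) > 0) {
    comps <- dplyr::bind_rows(comps, chey)
    clusters <- find_che_clusters(genes, comps, max_gap)
  }
  assignments <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    tokens <- tokenize_cluster(genes, comps, cl$replicon, cl$ordinal_start,
                               cl$ordinal_end, tcs_roles)
    pid <- genes$protein_id[match(cl$gene_ids[[1]], genes$gene_id)]
    ccomp <- comps[comps$protein_id %in% pid, , drop = FALSE]
    a <- assign_f_class(tokens, ccomp, comps, signatures, floor, half_band)
    tibble::tibble(cluster_id = cl$cluster_id, tokens = paste(tokens, collapse = ""), a)
  })
  if (nrow(clusters) == 0) {
    assignments <- tibble::tibble(cluster_id = integer(), tokens = character(),
                                  class = character(), status = character(),
                                  completeness = double(),
                                  order_score = double(),
                                  orientation = character())
  }
  list(components = comps, clusters = clusters, assignments = assignments,
       n_receptors = count_chemoreceptors(comps))
}

# CheY: a protein whose resolved architecture is exactly one REC domain, whose
# gene lies inside or within one gene of a chemosensory cluster.
call_chey <- function(genes, hits, components, clusters) {
  empty <- tibble::tibble(protein_id = character(), component = character(),
                          has_rec = logical())
  if (nrow(clusters) == 0) return(empty)
  s <- dplyr::summarise(dplyr::group_by(hits, .data$protein_id),
                        single_rec = dplyr::n() == 1 && all(.data$role %in% "REC"),
                        .groups = "drop")
  cand <- s$protein_id[s$single_rec]
  cand <- setdiff(cand, components$protein_id)
  if (length(cand) == 0) return(empty)
  g <- genes[!is.na(genes$protein_id) & genes$protein_id %in% cand, , drop = FALSE]
  inside <- vapply(seq_len(nrow(g)), function(i) {
    any(clusters$replicon == g$replicon[i] &
          g$ordinal[i] >= clusters$ordinal_start - 1L &
          g$ordinal[i] <= clusters$ordinal_end + 1L)
  }, logical(1))
  if (!any(inside)) return(empty)
  tibble::tibble(protein_id = g$protein_id[inside], component = "CheY",
                 has_rec = TRUE)
}
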