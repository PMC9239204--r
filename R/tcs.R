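#' Classify two-component system proteins
#'
#' Applies the domain-architecture rules for two-component system (TCS)
#' proteins to every protein in a resolved, role-annotated domain table:
#'
#' * **HK** -- histidine kinase: at least one HisKA and one HATPase domain,
#'   no receiver (REC) domain flanking the kinase core.
#' * **HHK** -- hybrid histidine kinase: HisKA + HATPase with a REC domain
#'   C-terminal of the kinase core.
#' * **HRR** -- hybrid response regulator: REC domain N-terminal of a
#'   HisKA + HATPase transmitter.
#' * **RR** -- response regulator: REC domain present but no HisKA+HATPase
#'   pair.
#' * **none** -- anything else (including HATPase-only proteins, which are
#'   STAS-kinase candidates, not HKs).
#'
#' REC position is decided by the REC domain midpoint relative to the first
#' HisKA start (N-terminal) or the last HATPase end (C-terminal). A protein
#' with REC domains on both sides, or only interior REC domains, is classified
#' HHK with a warning; the rule set does not cover that arrangement cleanly.
#'
#' @param hits Resolved domain hits annotated with [annotate_roles()] (the
#'   function annotates on the fly if the `role` column is missing).
#' @param vocab Domain vocabulary.
#' @return A tibble with one row per protein: `protein_id`, `role`
#'   (`HK`/`HHK`/`HRR`/`RR`/`none`), `rec_position`
#'   (`N_terminal`/`C_terminal`/`absent`).
#' @export
classify_tcs <- function(hits, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  s <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    has_hiska = any(.data$role %in% "HisKA"),
    has_hatpase = any(.data$role %in% "HATPase"),
    has_rec = any(.data$role %in% "REC"),
    kin_start = suppressWarnings(min(.data$env_start[.data$role %in% "HisKA"])),
    kin_end = suppressWarnings(max(.data$env_end[.data$role %in% "HATPase"])),
    rec_min_mid = suppressWarnings(min(((.data$env_start + .data$env_end) / 2)[.data$role %in% "REC"])),
    rec_max_mid = suppressWarnings(max(((.data$env_start + .data$env_end) / 2)[.data$role %in% "REC"])),
    .groups = "drop"
  )
  is_kinase <- s$has_hiska & s$has_hatpase
  rec_all_n <- is_kinase & s$has_rec & s$rec_max_mid < s$kin_start
  rec_all_c <- is_kinase & s$has_rec & s$rec_min_mid > s$kin_end
  rec_odd <- is_kinase & s$has_rec & !rec_all_n & !rec_all_c
  if (any(rec_odd)) {
    warning(sum(rec_odd), " kinase protein(s) with interior or two-sided REC ",
            "domains classified as HHK")
  }
  role <- dplyr::case_when(
    rec_all_n ~ "HRR",
    rec_all_c | rec_odd ~ "HHK",
    is_kinase ~ "HK",
    s$has_rec ~ "RR",
    TRUE ~ "none"
  )
  tibble::tibble(
    protein_id = s$protein_id,
    role = role,
    rec_position = dplyr::case_when(
      role == "HRR" ~ "N_terminal",
      role == "HHK" ~ "C_terminal",
      TRUE ~ "absent"
    )
  )
}

ensure_roles <- function(hits, vocab) {
  if (!"role" %in% names(hits)) hits <- annotate_roles(hits, vocab)
  hits
}

# gene table restricted to genes whose protein has one of `roles`
genes_with_role <- function(genes, tcs_roles, roles) {
  pids <- tcs_roles$protein_id[tcs_roles$role %in% roles]
  genes[!is.na(genes$protein_id) & genes$protein_id %in% pids, , drop = FALSE]
}

#' Link histidine kinase and response regulator genes by genomic distance
#'
#' Pairs HK/HHK genes with RR genes on the same replicon within `window`
#' intervening genes. Adjacent pairs (distance 0) are reported as
#' `adjacent_pair`; a non-adjacent pair is `one_to_one_within_window` when the
#' kinase sees exactly one RR in its window and that RR sees exactly one
#' kinase, otherwise `multi_within_window`.
#'
#' @param genes Gene tibble.
#' @param tcs_roles Output of [classify_tcs()].
#' @param window Maximum intervening genes for a link (default 4).
#' @return Tibble `hk_gene_id`, `rr_gene_id`, `link_type`, `distance`.
#' @export
link_hk_rr <- function(genes, tcs_roles, window = 4) {
  hk <- genes_with_role(genes, tcs_roles, c("HK", "HHK"))
  rr <- genes_with_role(genes, tcs_roles, "RR")
  p <- pairs_within(hk, rr, window)
  if (nrow(p) == 0) {
    return(tibble::tibble(hk_gene_id = character(), rr_gene_id = character(),
                          link_type = character(), distance = integer()))
  }
  n_rr_per_hk <- table(p$from_gene)
  n_hk_per_rr <- table(p$to_gene)
  link_type <- ifelse(
    p$distance == 0L, "adjacent_pair",
    ifelse(n_rr_per_hk[p$from_gene] == 1 & n_hk_per_rr[p$to_gene] == 1,
           "one_to_one_within_window", "multi_within_window")
  )
  out <- tibble::tibble(hk_gene_id = p$from_gene, rr_gene_id = p$to_gene,
                        link_type = as.character(link_type),
                        distance = as.integer(p$distance))
  dplyr::arrange(out, .data$hk_gene_id, .data$rr_gene_id)
}

#' Flag solo histidine kinase genes
#'
#' An HK or HHK gene is *solo* when every RR gene is more than `window` genes
#' away (strictly more than four intervening genes under the defaults): a
#' nearest RR at distance 4 is linked-eligible, at distance 5 it is solo.
#'
#' @inheritParams link_hk_rr
#' @return Tibble `gene_id`, `protein_id`, `role`, `nearest_rr_distance`,
#'   `solo` for every HK/HHK gene.
#' @export
flag_solo <- function(genes, tcs_roles, window = 4) {
  hk <- genes_with_role(genes, tcs_roles, c("HK", "HHK"))
  rr <- genes_with_role(genes, tcs_roles, "RR")
  hk <- nearest_distance(hk, rr)
  role <- tcs_roles$role[match(hk$protein_id, tcs_roles$protein_id)]
  tibble::tibble(gene_id = hk$gene_id, protein_id = hk$protein_id, role = role,
                 nearest_rr_distance = hk$nearest_distance,
                 solo = hk$nearest_distance > window)
}

#' Categorize response-regulator outputs
#'
#' Assigns each RR (and hybrid RR) one output category from its non-REC
#' domains: `cdgmp_enzyme` when the architecture carries a c-di-GMP turnover
#' domain (GGDEF, EAL or HD-GYP), otherwise `dna_binding` when it carries a
#' helix-turn-helix output domain from the vocabulary's HTH list, otherwise
#' `other_unknown`. A chimera with both a c-di-GMP domain and an HTH counts
#' as `cdgmp_enzyme`.
#'
#' @param hits Resolved, role-annotated domain hits.
#' @param tcs_roles Output of [classify_tcs()].
#' @param vocab Domain vocabulary.
#' @return Tibble `protein_id`, `role`, `category` for proteins with role RR
#'   or HRR.
#' @export
classify_rr_output <- function(hits, tcs_roles, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  rrs <- tcs_roles[tcs_roles$role %in% c("RR", "HRR"), , drop = FALSE]
  h <- hits[hits$protein_id %in% rrs$protein_id, , drop = FALSE]
  s <- dplyr::summarise(
    dplyr::group_by(h, .data$protein_id),
    has_cdgmp = any(.data$role %in% c("GGDEF", "EAL", "HD_GYP")),
    has_hth = any(.data$is_hth),
    .groups = "drop"
  )
  s <- dplyr::left_join(rrs, s, by = "protein_id")
  tibble::tibble(
    protein_id = s$protein_id,
    role = s$role,
    category = dplyr::case_when(
      s$has_cdgmp ~ "cdgmp_enzyme",
      s$has_hth ~ "dna_binding",
      TRUE ~ "other_unknown"
    )
  )
}

#' Detect gene clusters enriched in atypical histidine kinases
#'
#' Chains signaling genes (any system) that are separated by at most `max_gap`
#' non-signaling genes, and reports chains containing at least `min_atypical`
#' hybrid kinase (HHK) or hybrid response-regulator (HRR) genes -- the
#' hallmark of multistep phosphorelay neighborhoods.
#'
#' @param genes Gene tibble.
#' @param tcs_roles Output of [classify_tcs()].
#' @param signaling_genes Character vector of gene ids classified into any
#'   signaling system (TCS, c-di-GMP, chemosensory, ECF/cAMP/STYK).
#' @param max_gap Maximum intervening non-signaling genes within a chain
#'   (default 2).
#' @param min_atypical Minimum HHK+HRR genes per reported cluster (default 2).
#' @return Tibble `cluster_id`, `replicon`, `ordinal_start`, `ordinal_end`,
#'   `gene_ids` (list), `n_signaling_genes`, `n_atypical_hks`, sorted by
#'   decreasing size.
#' @export
detect_atypical_clusters <- function(genes, tcs_roles, signaling_genes,
                                     max_gap = 2, min_atypical = 2) {
  sg <- genes[genes$gene_id %in% signaling_genes, , drop = FALSE]
  sg <- dplyr::arrange(sg, .data$replicon, .data$ordinal)
  if (nrow(sg) == 0) {
    return(tibble::tibble(cluster_id = integer(), replicon = character(),
                          ordinal_start = integer(), ordinal_end = integer(),
                          gene_ids = list(), n_signaling_genes = integer(),
                          n_atypical_hks = integer()))
  }
  atyp_pids <- tcs_roles$protein_id[tcs_roles$role %in% c("HHK", "HRR")]
  grp <- chain_across_replicons(sg$replicon, sg$ordinal, max_gap)
  idx <- unname(split(seq_len(nrow(sg)), grp))
  is_atyp <- !is.na(sg$protein_id) & sg$protein_id %in% atyp_pids
  out <- tibble::tibble(
    replicon = vapply(idx, function(j) sg$replicon[j[1]], character(1)),
    ordinal_start = vapply(idx, function(j) as.integer(min(sg$ordinal[j])), integer(1)),
    ordinal_end = vapply(idx, function(j) as.integer(max(sg$ordinal[j])), integer(1)),
    gene_ids = lapply(idx, function(j) sg$gene_id[j]),
    n_signaling_genes = lengths(idx),
    n_atypical_hks = vapply(idx, function(j) sum(is_atyp[j]), integer(1))
  )
  out <- out[out$n_atypical_hks >= min_atypical, , drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$n_signaling_genes),
                        .data$replicon, .data$ordinal_start)
  tibble::tibble(cluster_id = seq_len(nrow(out)), out)
}
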