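#' Identify c-di-GMP turnover enzymes
#'
#' A protein enters the c-di-GMP census when its resolved architecture carries
#' a diguanylate cyclase domain (GGDEF) or a phosphodiesterase domain (EAL or
#' HD-GYP). All remaining domains -- sensory modules, REC domains, coupling
#' domains -- are recorded as partner domains.
#'
#' @param hits Resolved, role-annotated domain hits.
#' @param vocab Domain vocabulary.
#' @return Tibble with one row per enzyme protein: `protein_id`, `has_ggdef`,
#'   `has_eal`, `has_hdgyp`, `has_rec`, `n_partner`, `partner_domains`
#'   (list column), `n_hits`.
#' @export
identify_cdgmp <- function(hits, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  enz <- c("GGDEF", "EAL", "HD_GYP")
  s <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    has_ggdef = any(.data$role %in% "GGDEF"),
    has_eal = any(.data$role %in% "EAL"),
    has_hdgyp = any(.data$role %in% "HD_GYP"),
    has_rec = any(.data$role %in% "REC"),
    n_partner = sum(!(.data$role %in% enz) | is.na(.data$role)),
    partner_domains = list(.data$domain[!(.data$role %in% enz) | is.na(.data$role)]),
    n_hits = dplyr::n(),
    .groups = "drop"
  )
  s[s$has_ggdef | s$has_eal | s$has_hdgyp, , drop = FALSE]
}

#' Call the diguanylate cyclase A-site from sequence
#'
#' Scans the GGDEF domain subsequence for the active-site 5-mer. An exact
#' match to one of the four catalytically competent motifs -- `GGDEF`,
#' `GGEEF`, `SGDEF` or `AGDEF` -- calls the domain **active**. Otherwise the
#' likely A-site position is anchored by a two-stage relaxed pattern
#' (`xG[DE][EQ]F`, then `xx[DE]EF`) and the observed 5-mer is reported as
#' **degenerate**; with no anchor at all the call is degenerate with an empty
#' motif. A sequence that does not cover the domain interval yields
#' **unknown**.
#'
#' @param sequence Amino-acid string of the whole protein.
#' @param env_start,env_end 1-based inclusive bounds of the GGDEF hit.
#' @return A list with `state` (`active`/`degenerate`/`unknown`), `motif`
#'   (the observed 5-mer, `""` if unanchored), and `position` (1-based
#'   protein coordinate of the motif start, `NA` if unanchored).
#' @export
call_a_site <- function(sequence, env_start, env_end) {
  if (is.na(sequence) || nchar(sequence) < env_end) {
    warning("sequence does not cover the GGDEF domain interval")
    return(list(state = "unknown", motif = "", position = NA_integer_))
  }
  sub <- substr(sequence, env_start, env_end)
  active <- c("GGDEF", "GGEEF", "SGDEF", "AGDEF")
  pos <- vapply(active, function(m) {
    p <- regexpr(m, sub, fixed = TRUE)
    if (p < 0) NA_integer_ else as.integer(p)
  }, integer(1))
  if (any(!is.na(pos))) {
    i <- which.min(pos)
    return(list(state = "active", motif = active[[i]],
                position = env_start + pos[[i]] - 1L))
  }
  for (pat in c("[A-Z]G[DE][EQ]F", "[A-Z][A-Z][DE]EF")) {
    p <- regexpr(pat, sub)
    if (p > 0) {
      return(list(state = "degenerate",
                  motif = substr(sub, p, p + 4L),
                  position = env_start + as.integer(p) - 1L))
    }
  }
  list(state = "degenerate", motif = "", position = NA_integer_)
}

#' Call the c-di-GMP binding I-site from sequence
#'
#' The allosteric product-inhibition site of diguanylate cyclases is an
#' `RxxD` motif a few residues upstream of the A-site. The window 1--15
#' residues upstream of the located A-site start is searched for `R..D`;
#' without a located A-site the call is `unknown`.
#'
#' @param sequence Amino-acid string.
#' @param a_site_position 1-based position of the A-site motif start
#'   (from [call_a_site()]); `NA` for unanchored.
#' @param window Upstream window length in residues (default 15).
#' @return `"present"`, `"absent"` or `"unknown"`.
#' @export
call_i_site <- function(sequence, a_site_position, window = 15) {
  if (is.na(a_site_position)) return("unknown")
  lo <- max(1L, a_site_position - window)
  region <- substr(sequence, lo, a_site_position - 1L)
  if (grepl("R..D", region)) "present" else "absent"
}

#' A-site and I-site calls for every GGDEF-bearing protein
#'
#' Runs [call_a_site()] on every GGDEF domain hit and [call_i_site()] on the
#' located A-sites, then summarises to protein level: a protein is `active`
#' when any of its GGDEF domains is active; its I-site is `present` when any
#' domain's I-site is present.
#'
#' @param hits Resolved, role-annotated domain hits.
#' @param sequences Named character vector of protein sequences (names =
#'   protein ids). Proteins without a sequence are called `unknown`.
#' @param vocab Domain vocabulary.
#' @return Tibble `protein_id`, `a_site`, `a_site_motif`, `i_site`.
#' @export
call_motifs <- function(hits, sequences, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  gg <- hits[hits$role %in% "GGDEF", , drop = FALSE]
  if (nrow(gg) == 0) {
    return(tibble::tibble(protein_id = character(), a_site = character(),
                          a_site_motif = character(), i_site = character()))
  }
  seqs <- if (is.null(sequences)) character() else sequences
  calls <- purrr::pmap(
    list(gg$protein_id, gg$env_start, gg$env_end),
    function(pid, s, e) {
      sq <- if (pid %in% names(seqs)) seqs[[pid]] else NA_character_
      if (is.na(sq)) {
        return(tibble::tibble(protein_id = pid, state = "unknown",
                              motif = "", i_site = "unknown"))
      }
      a <- suppressWarnings(call_a_site(sq, s, e))
      tibble::tibble(protein_id = pid, state = a$state, motif = a$motif,
                     i_site = call_i_site(sq, a$position))
    })
  d <- dplyr::bind_rows(calls)
  rank_a <- c(active = 1, degenerate = 2, unknown = 3)
  dplyr::summarise(
    dplyr::group_by(d, .data$protein_id),
    a_site = c("active", "degenerate", "unknown")[min(rank_a[.data$state])],
    a_site_motif = if (any(.data$state == "active"))
      .data$motif[.data$state == "active"][1] else .data$motif[1],
    i_site = if (any(.data$i_site == "present")) "present"
      else if (any(.data$i_site == "absent")) "absent" else "unknown",
    .groups = "drop"
  )
}

#' Per-genome c-di-GMP enzyme category counts
#'
#' Tallies the six census categories: total diguanylate cyclases (any GGDEF
#' protein, degenerate included by default), DGCs with at least one partner
#' domain, phosphodiesterases with a partner domain, bifunctional
#' GGDEF+EAL/HD-GYP proteins, single-domain enzymes (exactly one enzymatic
#' domain and nothing else), and active DGCs (A-site motif intact).
#' Bifunctional proteins are counted only in `bifunctional`, keeping the
#' partner-domain categories close to a partition; set
#' `bifunctional_in_partner = TRUE` to also count them there.
#'
#' @param cdgmp Output of [identify_cdgmp()].
#' @param motifs Output of [call_motifs()] (may be empty; proteins without a
#'   call count as not active).
#' @param include_degenerate Count degenerate-GGDEF proteins in `total_dgc`
#'   (default TRUE).
#' @param bifunctional_in_partner See description.
#' @return One-row tibble of the six counts plus `n_enzymes` (all c-di-GMP
#'   enzymes of any kind).
#' @export
categorize_cdgmp <- function(cdgmp, motifs = NULL, include_degenerate = TRUE,
                             bifunctional_in_partner = FALSE) {
  a_site <- rep("unknown", nrow(cdgmp))
  if (!is.null(motifs) && nrow(motifs) > 0) {
    m <- match(cdgmp$protein_id, motifs$protein_id)
    a_site <- ifelse(is.na(m), "unknown", motifs$a_site[m])
  }
  active <- cdgmp$has_ggdef & a_site == "active"
  bifun <- cdgmp$has_ggdef & (cdgmp$has_eal | cdgmp$has_hdgyp)
  is_dgc <- cdgmp$has_ggdef & (include_degenerate | active)
  is_pde_only <- (cdgmp$has_eal | cdgmp$has_hdgyp) & !cdgmp$has_ggdef
  partner_ok <- if (bifunctional_in_partner) TRUE else !bifun
  tibble::tibble(
    total_dgc = sum(is_dgc),
    dgc_with_partner = sum(is_dgc & cdgmp$n_partner > 0 & partner_ok),
    pde_with_partner = sum(is_pde_only & cdgmp$n_partner > 0),
    bifunctional = sum(bifun),
    single_domain = sum(cdgmp$n_hits == 1),
    active_dgc = sum(active),
    n_enzymes = nrow(cdgmp)
  )
}

#' Flag REC-bearing c-di-GMP enzymes near histidine kinase genes
#'
#' A c-di-GMP enzyme carrying a REC domain is a likely phosphorylation target;
#' this marks whether a kinase gene (HK/HHK/HRR) lies within `window`
#' intervening genes. Enzymes without a REC domain get `NA`.
#'
#' @param genes Gene tibble.
#' @param cdgmp Output of [identify_cdgmp()].
#' @param tcs_roles Output of [classify_tcs()].
#' @param window Maximum intervening genes (default 4).
#' @return `cdgmp` with a `near_hk` logical column appended.
#' @export
flag_near_hk <- function(genes, cdgmp, tcs_roles, window = 4) {
  hk <- genes_with_role(genes, tcs_roles, c("HK", "HHK", "HRR"))
  cg <- genes[!is.na(genes$protein_id) &
                genes$protein_id %in% cdgmp$protein_id, , drop = FALSE]
  cg <- nearest_distance(cg, hk)
  d <- cg$nearest_distance[match(cdgmp$protein_id, cg$protein_id)]
  cdgmp$near_hk <- ifelse(cdgmp$has_rec, d <= window, NA)
  cdgmp
}
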