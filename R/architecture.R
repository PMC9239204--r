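#' Resolve raw domain hits into clean per-protein architectures
#'
#' Homology searches routinely report overlapping hits for the same protein
#' region (nested families, clan cross-hits). The architecture of a protein is
#' resolved greedily: hits are considered in order of descending bit score and
#' a candidate is rejected when it overlaps an already-accepted hit by more
#' than `max_overlap` of the shorter interval. Survivors are returned sorted
#' by start coordinate, giving the N-to-C domain order that every
#' classification rule reads.
#'
#' The result is *maximal*: no rejected hit can be added back without
#' violating the overlap policy.
#'
#' @param hits Domain-hit tibble (any number of proteins).
#' @param max_overlap Maximum tolerated overlap as a fraction of the shorter
#'   of the two intervals (default 0.2).
#' @return The subset of `hits` that survives, sorted by `protein_id` then
#'   `env_start`.
#' @export
resolve_architectures <- function(hits, max_overlap = 0.2) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, .data$protein_id, .data$env_start, .data$env_end)
  # Fast path: proteins whose sorted hits never overlap at all need no greedy
  # pass. This is the vast majority in real and synthetic data.
  grp <- hits$protein_id
  new_prot <- c(TRUE, grp[-1] != grp[-length(grp)])
  prev_end <- c(0L, hits$env_end[-nrow(hits)])
  conflict <- !new_prot & hits$env_start <= prev_end
  conflicted <- unique(grp[conflict])
  if (length(conflicted) == 0) return(hits)

  clean <- hits[!(grp %in% conflicted), , drop = FALSE]
  todo <- hits[grp %in% conflicted, , drop = FALSE]
  resolved <- dplyr::group_modify(
    dplyr::group_by(todo, .data$protein_id),
    function(df, key) greedy_resolve(df, max_overlap)
  )
  out <- dplyr::bind_rows(clean, dplyr::ungroup(resolved))
  dplyr::arrange(out, .data$protein_id, .data$env_start, .data$env_end)
}

greedy_resolve <- function(df, max_overlap) {
  ord <- order(-df$bitscore, df$env_start, df$env_end, df$domain)
  df <- df[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!any(pair_overlap_frac(df$env_start[i], df$env_end[i],
                               df$env_start[kept], df$env_end[kept]) > max_overlap)) {
      kept <- c(kept, i)
    }
  }
  out <- df[kept, , drop = FALSE]
  out[order(out$env_start, out$env_end), , drop = FALSE]
}

# overlap as fraction of the shorter interval; vectorised over the second pair
pair_overlap_frac <- function(s1, e1, s2, e2) {
  if (length(s2) == 0) return(numeric(0))
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  shorter <- pmin(e1 - s1 + 1L, e2 - s2 + 1L)
  ov / shorter
}
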