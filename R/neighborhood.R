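#' Gene distance and neighborhood utilities
#'
#' The whole census uses one notion of gene distance: the number of genes
#' lying *between* two genes on the same replicon,
#' `|ordinal_a - ordinal_b| - 1`, ignoring strand. Adjacent genes are at
#' distance 0; genes on different replicons are infinitely far apart. Every
#' record in the gene table -- coding or not -- occupies an ordinal, so
#' pseudogenes and RNA genes count as intervening genes, as they would when
#' counting "genes away" in a genome browser.
#'
#' @param genes Gene tibble from [read_gene_table()].
#' @param a,b Gene ids.
#' @return `gene_distance()`: a non-negative integer, or `Inf` across
#'   replicons.
#' @export
gene_distance <- function(genes, a, b) {
  ga <- genes[match(a, genes$gene_id), ]
  gb <- genes[match(b, genes$gene_id), ]
  if (any(is.na(ga$ordinal)) || any(is.na(gb$ordinal))) {
    stop("unknown gene id")
  }
  ifelse(ga$replicon == gb$replicon, abs(ga$ordinal - gb$ordinal) - 1, Inf)
}

# For each gene in `from`, the distance to the nearest gene in `to`
# (both tibbles with replicon + ordinal). Returns `from` with a
# `nearest_distance` column (Inf when no target shares the replicon).
nearest_distance <- function(from, to) {
  from$nearest_distance <- Inf
  for (rep in unique(from$replicon)) {
    t_ord <- sort(to$ordinal[to$replicon == rep])
    idx <- from$replicon == rep
    if (length(t_ord) == 0) next
    f_ord <- from$ordinal[idx]
    pos <- findInterval(f_ord, t_ord)
    lo <- ifelse(pos >= 1, t_ord[pmax(pos, 1)], NA_integer_)
    hi <- ifelse(pos < length(t_ord), t_ord[pmin(pos + 1, length(t_ord))], NA_integer_)
    d <- pmin(abs(f_ord - lo), abs(f_ord - hi), na.rm = TRUE)
    from$nearest_distance[idx] <- d - 1
  }
  from
}

# All (from, to) pairs within `window` intervening genes on the same replicon.
pairs_within <- function(from, to, window) {
  nf <- nrow(from)
  nt <- nrow(to)
  if (nf == 0 || nt == 0) {
    return(tibble::tibble(from_gene = character(), replicon = character(),
                          from_ord = integer(), to_gene = character(),
                          to_ord = integer(), distance = integer()))
  }
  i <- rep(seq_len(nf), each = nt)
  k <- rep.int(seq_len(nt), nf)
  keep <- from$replicon[i] == to$replicon[k]
  i <- i[keep]
  k <- k[keep]
  d <- abs(from$ordinal[i] - to$ordinal[k]) - 1L
  sel <- d <= window & from$gene_id[i] != to$gene_id[k]
  tibble::tibble(from_gene = from$gene_id[i[sel]],
                 replicon = from$replicon[i[sel]],
                 from_ord = from$ordinal[i[sel]],
                 to_gene = to$gene_id[k[sel]],
                 to_ord = to$ordinal[k[sel]],
                 distance = d[sel])
}

# Chain sorted ordinals into groups where consecutive members are separated by
# at most `max_gap` intervening genes. Returns an integer group id per input
# element (input must be sorted ascending).
chain_by_gap <- function(ordinals, max_gap) {
  if (length(ordinals) == 0) return(integer(0))
  breaks <- c(FALSE, diff(ordinals) - 1L > max_gap)
  cumsum(breaks) + 1L
}

# Same chaining over a table sorted by (replicon, ordinal): a chain never
# crosses a replicon boundary. Returns an integer group id per row.
chain_across_replicons <- function(replicon, ordinal, max_gap) {
  n <- length(ordinal)
  if (n == 0) return(integer(0))
  breaks <- c(FALSE, replicon[-1] != replicon[-n] |
                     diff(ordinal) - 1L > max_gap)
  cumsum(breaks) + 1L
}

#' Reverse a replicon's gene order
#'
#' Mirrors every replicon: gene order is reversed (ordinal `k` becomes
#' `n - 1 - k`), coordinates are reflected and strands flipped. Every
#' classification, link, cluster and census value in the package is invariant
#' under this transformation, which the test-suite exercises.
#'
#' @param genes Gene tibble.
#' @return A gene tibble of the same shape.
#' @export
reverse_genome <- function(genes) {
  out <- dplyr::group_modify(dplyr::group_by(genes, .data$replicon),
    function(df, key) {
      L <- max(df$end) + min(df$start)
      tibble::tibble(
        gene_id = df$gene_id,
        start = L - df$end,
        end = L - df$start,
        strand = ifelse(df$strand == "+", "-", "+"),
        protein_id = df$protein_id
      )
    })
  assign_ordinals(dplyr::ungroup(out))
}
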