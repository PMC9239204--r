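#' Census overview plot
#'
#' Draws per-genome counts of the major signal-transduction families as a
#' faceted bar panel, ordered by ecotype -- the at-a-glance comparison of
#' signaling investment across a genome collection.
#'
#' @param census Census tibble from [build_census()].
#' @param families Census count columns to show.
#' @return A ggplot object.
#' @export
plot_census <- function(census,
                        families = c("n_hk_total", "n_rr", "n_enzymes",
                                     "n_chemoreceptors", "n_ecf", "n_estyk")) {
  families <- intersect(families, names(census))
  long <- tidyr::pivot_longer(
    census[, c("genome_id", "ecotype", families)],
    dplyr::all_of(families), names_to = "family", values_to = "count")
  long$family <- factor(long$family, levels = families)
  long$genome_id <- stats::reorder(long$genome_id, as.integer(factor(long$ecotype)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome_id, y = .data$count,
                                     fill = .data$ecotype)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "proteins", fill = "ecotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Genome map of signaling genes
#'
#' Plots the classified signaling genes of one genome along its replicons,
#' colored by system, with chemosensory clusters visible as runs of adjacent
#' genes.
#'
#' @param result A `sigcensus_result` from [classify_genome()].
#' @return A ggplot object.
#' @export
plot_genome_map <- function(result) {
  stopifnot(inherits(result, "sigcensus_result"))
  d <- tidy(result)
  d <- d[!is.na(d$system), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 1e3, y = .data$system,
                                  color = .data$system)) +
    ggplot2::geom_point(shape = 124, size = 4, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$replicon)) +
    ggplot2::labs(x = "position (kb)", y = NULL,
                  title = result$genome_id) +
    ggplot2::theme_minimal()
}

#' @rdname plot_genome_map
#' @param object A `sigcensus_result`.
#' @param ... Ignored.
#' @export
autoplot.sigcensus_result <- function(object, ...) plot_genome_map(object)
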