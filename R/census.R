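#' Classify one genome end-to-end
#'
#' Runs every classification module over one genome -- two-component systems,
#' c-di-GMP enzymes with A-/I-site calls, the chemosensory census, ECF, cAMP,
#' STYK and quorum-sensing screens, combined-pathway detection and
#' atypical-kinase cluster detection -- and assembles the one-row census.
#'
#' @param genes Gene tibble ([read_gene_table()]).
#' @param hits Domain-hit tibble ([read_domain_table()]); resolved and
#'   annotated internally.
#' @param sequences Optional named character vector of protein sequences
#'   (needed only for A-/I-site motif calls).
#' @param genome_id Genome identifier carried into the census row.
#' @param ecotype Ecotype label (`vent_specialist`, `generalist`,
#'   `host_associated`, `unknown`).
#' @param vocab,signatures,qs_vocab Configuration objects (defaults built in).
#' @param opts Named list of thresholds overriding the defaults:
#'   `max_overlap` (0.2), `link_window` (4), `cluster_gap` (2),
#'   `min_atypical` (2), `ecf_window` (4), `camp_window` (6),
#'   `combined_window` (6), `class_floor` (0.4), `half_band` (c(0.4, 0.8)).
#' @return A `sigcensus_result` object: a list of per-module tibbles plus the
#'   one-row `census` tibble.
#' @export
classify_genome <- function(genes, hits, sequences = NULL,
                            genome_id = "genome", ecotype = "unknown",
                            vocab = default_vocabulary(),
                            signatures = default_f_signatures(),
                            qs_vocab = default_qs_vocabulary(),
                            opts = list()) {
  o <- utils::modifyList(list(
    max_overlap = 0.2, link_window = 4, cluster_gap = 2, min_atypical = 2,
    ecf_window = 4, camp_window = 6, combined_window = 6,
    class_floor = 0.4, half_band = c(0.4, 0.8)
  ), opts)

  resolved <- resolve_architectures(hits, o$max_overlap)
  resolved <- annotate_roles(resolved, vocab)

  tcs <- classify_tcs(resolved, vocab)
  rr_out <- classify_rr_output(resolved, tcs, vocab)
  solo <- flag_solo(genes, tcs, o$link_window)
  links <- link_hk_rr(genes, tcs, o$link_window)

  cdgmp <- identify_cdgmp(resolved, vocab)
  motifs <- call_motifs(resolved, sequences, vocab)
  cdgmp <- flag_near_hk(genes, cdgmp, tcs, o$link_window)
  cdgmp_counts <- categorize_cdgmp(cdgmp, motifs)

  chemo <- chemo_census(genes, resolved, tcs, vocab, signatures,
                        o$cluster_gap, o$class_floor, o$half_band)

  aux <- classify_aux(resolved, vocab)
  ecf242 <- detect_ecf242(genes, resolved, aux, o$ecf_window)
  camp <- detect_camp_clusters(genes, resolved, aux, o$camp_window)
  qs <- qs_screen(hits, qs_vocab)
  combined <- detect_combined_pathways(genes, resolved, aux, cdgmp,
                                       o$combined_window)

  signaling <- signaling_gene_ids(genes, tcs, cdgmp, chemo$components, aux)
  atypical <- detect_atypical_clusters(genes, tcs, signaling,
                                       o$cluster_gap, o$min_atypical)

  census <- census_row(genome_id, ecotype, genes, tcs, rr_out, solo,
                       cdgmp_counts, chemo, aux, ecf242, camp, qs, combined,
                       atypical, signatures)
  structure(list(
    genome_id = genome_id, genes = genes, tcs = tcs, rr_output = rr_out,
    solo = solo, links = links, cdgmp = cdgmp, cdgmp_motifs = motifs,
    cdgmp_counts = cdgmp_counts, chemo = chemo, aux = aux, ecf242 = ecf242,
    camp = camp, qs = qs, combined = combined, atypical = atypical,
    census = census
  ), class = "sigcensus_result")
}

signaling_gene_ids <- function(genes, tcs, cdgmp, che_components, aux) {
  pids <- unique(c(
    tcs$protein_id[tcs$role != "none"],
    cdgmp$protein_id,
    che_components$protein_id,
    aux$protein_id
  ))
  genes$gene_id[!is.na(genes$protein_id) & genes$protein_id %in% pids]
}

census_row <- function(genome_id, ecotype, genes, tcs, rr_out, solo,
                       cdgmp_counts, chemo, aux, ecf242, camp, qs, combined,
                       atypical, signatures) {
  n_role <- function(r) sum(tcs$role %in% r)
  rr_cat <- rr_out$category[rr_out$role == "RR"]
  n_rr <- n_role("RR")
  prop <- function(cat) if (n_rr > 0) sum(rr_cat == cat) / n_rr else NA_real_
  class_status <- stats::setNames(
    rep("none", length(signatures)),
    vapply(signatures, `[[`, "", "class_name"))
  a <- chemo$assignments
  for (cl in names(class_status)) {
    st <- a$status[a$class == cl]
    if (length(st) > 0) {
      # best status across clusters of the same class
      ord <- c(full = 1, half = 2, partial = 3, none = 4)
      class_status[[cl]] <- names(sort(ord[st]))[1]
    }
  }
  status_cols <- tibble::as_tibble(as.list(class_status))
  names(status_cols) <- paste0("class_", names(class_status))
  tibble::tibble(
    genome_id = genome_id,
    ecotype = ecotype,
    n_genes = nrow(genes),
    n_chemoreceptors = chemo$n_receptors,
    n_che_classes = sum(class_status %in% c("full", "half")),
    status_cols,
    n_hk = n_role("HK"),
    n_hhk = n_role("HHK"),
    n_hrr = n_role("HRR"),
    n_hk_total = n_role(c("HK", "HHK", "HRR")),
    n_solo = sum(solo$solo),
    n_rr = n_rr,
    n_rr_dna = sum(rr_cat == "dna_binding"),
    n_rr_cdgmp = sum(rr_cat == "cdgmp_enzyme"),
    n_rr_other = sum(rr_cat == "other_unknown"),
    rr_prop_dna = prop("dna_binding"),
    rr_prop_cdgmp = prop("cdgmp_enzyme"),
    rr_prop_other = prop("other_unknown"),
    cdgmp_counts,
    cdgmp_signaling = cdgmp_counts$active_dgc > 0,
    n_ecf = sum(aux$system == "ECF"),
    n_ecf242 = nrow(ecf242),
    n_ac = sum(aux$system == "AC"),
    n_camp_clusters = sum(camp$cyclases$cluster),
    n_crp = camp$n_crp,
    crp_without_cyclase = camp$crp_without_cyclase,
    n_estyk = sum(aux$system == "eSTYK"),
    n_stas_styk = sum(aux$system == "stas_STYK"),
    n_pp2c = sum(aux$system == "PP2C"),
    n_bifunctional_pp2c_pk = sum(aux$system == "bifunctional_PP2C_Pkinase"),
    n_stas = sum(aux$system == "STAS"),
    n_qs_present = sum(qs$present),
    n_combined = nrow(combined),
    n_atypical_clusters = nrow(atypical)
  )
}

#' Bind per-genome census rows into one table
#'
#' @param results A list of `sigcensus_result` objects (or one-row census
#'   tibbles).
#' @return The census tibble, one row per genome, in deterministic
#'   (genome_id) order.
#' @export
build_census <- function(results) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "sigcensus_result")) r$census else r
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$genome_id)
}

#' Aggregate the census by ecotype
#'
#' Pools response-regulator output counts within each ecotype group (so the
#' reported proportions weight every RR equally, not every genome) and adds
#' mean/median summaries of the main census counts. Groups with zero RRs get
#' `NA` proportions rather than 0/0.
#'
#' @param census Census tibble from [build_census()].
#' @return One row per ecotype.
#' @export
aggregate_by_ecotype <- function(census) {
  g <- dplyr::group_by(census, .data$ecotype)
  out <- dplyr::summarise(
    g,
    n_genomes = dplyr::n(),
    n_rr_total = sum(.data$n_rr),
    rr_prop_dna = ifelse(sum(.data$n_rr) > 0,
                         sum(.data$n_rr_dna) / sum(.data$n_rr), NA_real_),
    rr_prop_cdgmp = ifelse(sum(.data$n_rr) > 0,
                           sum(.data$n_rr_cdgmp) / sum(.data$n_rr), NA_real_),
    rr_prop_other = ifelse(sum(.data$n_rr) > 0,
                           sum(.data$n_rr_other) / sum(.data$n_rr), NA_real_),
    mean_hk_total = mean(.data$n_hk_total),
    median_hk_total = stats::median(.data$n_hk_total),
    mean_cdgmp_enzymes = mean(.data$n_enzymes),
    median_cdgmp_enzymes = stats::median(.data$n_enzymes),
    mean_chemoreceptors = mean(.data$n_chemoreceptors),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$ecotype)
}

#' Write census outputs
#'
#' Writes `census.tsv`, `census.json` and (when metadata allows)
#' `ecotype_summary.tsv` into a directory. Output is byte-deterministic for
#' identical inputs.
#'
#' @param census Census tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_census <- function(census, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(census, file.path(dir, "census.tsv"), progress = FALSE)
  jsonlite::write_json(census, file.path(dir, "census.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  summ <- aggregate_by_ecotype(census)
  readr::write_tsv(summ, file.path(dir, "ecotype_summary.tsv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.sigcensus_result <- function(x, ...) {
  cat("<sigcensus_result> genome", x$genome_id, "\n")
  cat("  genes:", nrow(x$genes), " proteins classified:\n")
  cat("  TCS: HK", sum(x$tcs$role == "HK"), "HHK", sum(x$tcs$role == "HHK"),
      "HRR", sum(x$tcs$role == "HRR"), "RR", sum(x$tcs$role == "RR"), "\n")
  cat("  c-di-GMP enzymes:", nrow(x$cdgmp),
      "(active DGC", x$cdgmp_counts$active_dgc, ")\n")
  cat("  chemosensory clusters:", nrow(x$chemo$clusters), "receptors:",
      x$chemo$n_receptors, "\n")
  cat("  ECF:", sum(x$aux$system == "ECF"),
      " AC:", sum(x$aux$system == "AC"),
      " eSTYK:", sum(x$aux$system == "eSTYK"),
      " stas_STYK:", sum(x$aux$system == "stas_STYK"), "\n")
  invisible(x)
}

#' Tidy a genome classification result
#'
#' Returns the per-protein classification table: one row per classified
#' protein with its system, role and gene location.
#'
#' @param x A `sigcensus_result`.
#' @param ... Unused.
#' @return A tibble `protein_id`, `gene_id`, `replicon`, `ordinal`, `start`,
#'   `end`, `strand`, `system`, `role`.
#' @export
tidy.sigcensus_result <- function(x, ...) {
  loc <- x$genes[!is.na(x$genes$protein_id),
                 c("protein_id", "gene_id", "replicon", "ordinal",
                   "start", "end", "strand")]
  rows <- dplyr::bind_rows(
    tibble::tibble(protein_id = x$tcs$protein_id[x$tcs$role != "none"],
                   system = "TCS",
                   role = x$tcs$role[x$tcs$role != "none"]),
    tibble::tibble(protein_id = x$cdgmp$protein_id, system = "c-di-GMP",
                   role = dplyr::case_when(
                     x$cdgmp$has_ggdef & (x$cdgmp$has_eal | x$cdgmp$has_hdgyp) ~ "bifunctional",
                     x$cdgmp$has_ggdef ~ "DGC",
                     TRUE ~ "PDE")),
    tibble::tibble(protein_id = x$chemo$components$protein_id,
                   system = "chemosensory",
                   role = x$chemo$components$component),
    tibble::tibble(protein_id = x$aux$protein_id, system = "auxiliary",
                   role = x$aux$system)
  )
  out <- dplyr::left_join(rows, loc, by = "protein_id")
  dplyr::arrange(out, .data$system, .data$role, .data$protein_id)
}

#' Glance at a genome classification result
#'
#' @param x A `sigcensus_result`.
#' @param ... Unused.
#' @return The one-row census tibble.
#' @export
glance.sigcensus_result <- function(x, ...) {
  x$census
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
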