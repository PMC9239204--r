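#' Run the signaling census over a genome collection
#'
#' Drives the whole pipeline from a configuration: read each genome's gene
#' table, domain-hit table and (optionally) protein sequences, classify it
#' with [classify_genome()], and write per-genome classification tables plus
#' the assembled census (`census.tsv`, `census.json`,
#' `ecotype_summary.tsv`) to the output directory. The run is deterministic:
#' identical inputs produce byte-identical outputs.
#'
#' @param config Either a path to a YAML file or a list with the same shape:
#'   \describe{
#'     \item{`output_dir`}{Directory for results (created if absent).}
#'     \item{`genomes`}{List of entries with `genome_id`, `genes` (path),
#'       `domains` (path), optional `sequences` (FASTA path) and optional
#'       `ecotype`.}
#'     \item{`metadata`}{Optional path to a `genome_id`/`ecotype` TSV; merged
#'       with per-genome `ecotype` entries (per-genome wins).}
#'     \item{`vocabulary`, `f_signatures`, `qs_vocabulary`}{Optional YAML
#'       paths overriding the built-in configuration.}
#'     \item{`evalue_threshold`}{Domain-hit E-value cutoff (default `1e-5`).}
#'     \item{`options`}{Named list forwarded to [classify_genome()] `opts`.}
#'   }
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `results` (per-genome `sigcensus_result`
#'   objects) and `census` (the combined tibble).
#' @export
run_census <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$genomes) || length(config$genomes) == 0) {
    stop("config lists no genomes")
  }
  out_dir <- config$output_dir %||% "sigcensus_results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vocab <- if (!is.null(config$vocabulary)) read_vocabulary(config$vocabulary)
           else default_vocabulary()
  sigs <- if (!is.null(config$f_signatures)) read_f_signatures(config$f_signatures)
          else default_f_signatures()
  qs_vocab <- if (!is.null(config$qs_vocabulary))
    read_qs_vocabulary(config$qs_vocabulary) else default_qs_vocabulary()
  meta <- if (!is.null(config$metadata)) read_metadata(config$metadata) else NULL
  thr <- config$evalue_threshold %||% 1e-5
  opts <- config$options %||% list()

  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  results <- list()
  for (g in config$genomes) {
    gid <- g$genome_id %||% stop("genome entry without genome_id")
    eco <- g$ecotype %||%
      (if (!is.null(meta) && gid %in% meta$genome_id)
         meta$ecotype[meta$genome_id == gid] else "unknown")
    say("classifying ", gid)
    genes <- read_gene_table(g$genes)
    hits <- read_domain_table(g$domains, evalue_threshold = thr)
    seqs <- if (!is.null(g$sequences)) read_protein_fasta(g$sequences) else NULL
    res <- classify_genome(genes, hits, seqs, genome_id = gid, ecotype = eco,
                           vocab = vocab, signatures = sigs,
                           qs_vocab = qs_vocab, opts = opts)
    results[[gid]] <- res
    readr::write_tsv(tidy(res), file.path(out_dir, paste0(gid, "_proteins.tsv")))
    log_lines <- c(log_lines, sprintf(
      "%s\tgenes=%d\thits_kept=%d\thits_dropped=%d", gid, nrow(genes),
      nrow(hits), attr(hits, "dropped") %||% 0L))
  }

  census <- build_census(results)
  write_census(census, out_dir)
  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  say("wrote census for ", nrow(census), " genomes to ", out_dir)
  invisible(list(results = results, census = census))
}

#' Materialize a synthetic genome to disk
#'
#' Writes the gene table, domain table, sequences and ground truth of a
#' [synth_generate()] result as plain-text files, ready for [run_census()].
#'
#' @param synth A [synth_generate()] result.
#' @param dir Output directory.
#' @return Invisibly, the named list of file paths written.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gid <- synth$genome_id
  paths <- list(
    genes = file.path(dir, paste0(gid, "_genes.tsv")),
    domains = file.path(dir, paste0(gid, "_domains.tsv")),
    sequences = file.path(dir, paste0(gid, "_proteins.faa")),
    truth = file.path(dir, paste0(gid, "_truth.tsv"))
  )
  write_gene_table(synth$genes, paths$genes)
  write_domain_table(synth$domains, paths$domains)
  if (length(synth$sequences) > 0) {
    write_protein_fasta(synth$sequences, paths$sequences)
  } else {
    paths$sequences <- NULL
  }
  readr::write_tsv(synth$truth$proteins, paths$truth)
  invisible(paths)
}
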