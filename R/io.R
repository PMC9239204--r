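#' Read an ordered gene table
#'
#' Reads the gene complement of one genome and assigns each gene an *ordinal*:
#' its 0-based position in coordinate order along its replicon. All
#' gene-neighborhood rules in the package ("within four genes", cluster gaps)
#' are defined on these ordinals, so genes are always re-sorted by start
#' coordinate regardless of file order. Non-coding and pseudogene records are
#' kept -- they occupy an ordinal, exactly as they occupy a slot in a genome
#' browser -- but only records with a `protein_id` can ever be classified.
#'
#' @param path Path to a GFF3 file or a TSV with header
#'   `gene_id,replicon,start,end,strand,protein_id` (empty `protein_id` for
#'   non-coding records).
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A tibble with columns `gene_id`, `replicon`, `ordinal`, `start`,
#'   `end`, `strand`, `protein_id` (NA for non-coding records). Coordinates are
#'   1-based inclusive.
#' @export
read_gene_table <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  genes <- if (format == "gff3") read_genes_gff3(path) else read_genes_tsv(path)
  if (nrow(genes) == 0) {
    warning("empty gene table: ", path)
    return(assign_ordinals(genes))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) stop("duplicate gene_id in ", path, ": ",
                            paste(utils::head(dup, 5), collapse = ", "))
  assign_ordinals(genes)
}

read_genes_tsv <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), replicon = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    strand = readr::col_character(), protein_id = readr::col_character()
  ), progress = FALSE)
  g$protein_id[!is.na(g$protein_id) & g$protein_id == ""] <- NA_character_
  g
}

read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- gr$type %in% c("gene", "CDS", "pseudogene", "tRNA", "rRNA", "ncRNA")
  if (any(keep)) gr <- gr[keep]
  meta <- as.data.frame(gr)
  id <- meta$ID
  if (is.null(id)) id <- meta$locus_tag
  if (is.null(id)) id <- paste0("gene", seq_len(nrow(meta)))
  pid <- meta$protein_id
  if (is.null(pid)) pid <- rep(NA_character_, nrow(meta))
  g <- tibble::tibble(
    gene_id = as.character(id),
    replicon = as.character(meta$seqnames),
    start = as.integer(meta$start),
    end = as.integer(meta$end),
    strand = ifelse(as.character(meta$strand) == "-", "-", "+"),
    protein_id = as.character(pid),
    type = as.character(meta$type)
  )
  # A gene and its CDS share coordinates; collapse to one record per locus,
  # preferring the row that carries a protein_id.
  g <- dplyr::arrange(g, .data$replicon, .data$start, .data$end,
                      is.na(.data$protein_id))
  g <- dplyr::distinct(g, .data$replicon, .data$start, .data$end, .keep_all = TRUE)
  g$type <- NULL
  g
}

assign_ordinals <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), replicon = character(),
                          ordinal = integer(), start = integer(),
                          end = integer(), strand = character(),
                          protein_id = character()))
  }
  stopifnot(all(genes$start <= genes$end))
  genes <- dplyr::arrange(genes, .data$replicon, .data$start, .data$end)
  genes <- dplyr::mutate(dplyr::group_by(genes, .data$replicon),
                         ordinal = seq_along(.data$start) - 1L)
  genes <- dplyr::ungroup(genes)
  dplyr::select(genes, "gene_id", "replicon", "ordinal", "start", "end",
                "strand", "protein_id")
}

#' Write a gene table as TSV
#'
#' Inverse of [read_gene_table()] (TSV dialect); reading the written file
#' reproduces the same records and ordinals.
#'
#' @param genes A gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- dplyr::select(genes, "gene_id", "replicon", "start", "end",
                       "strand", "protein_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a protein domain-hit table
#'
#' Accepts either the HMMER3 `hmmscan --domtblout` layout or a simple TSV with
#' header `protein_id,domain,start,end,evalue,score` (an optional `accession`
#' column is honoured). Hits with an E-value at or above `evalue_threshold`
#' are dropped; the number dropped is recorded in the `dropped` attribute.
#' The default threshold of 1e-5 follows the homology-search convention used
#' to build the census (hits with E < 1e-5 accepted).
#'
#' @param path Path to the table.
#' @param dialect `"auto"`, `"domtblout"` or `"tsv"`.
#' @param evalue_threshold Keep hits with `evalue < evalue_threshold`;
#'   use `Inf` to keep everything.
#' @return A tibble with columns `protein_id`, `domain`, `accession`,
#'   `env_start`, `env_end`, `evalue`, `bitscore`.
#' @export
read_domain_table <- function(path, dialect = c("auto", "domtblout", "tsv"),
                              evalue_threshold = 1e-5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("domain table not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(first) > 0 && grepl("\tprotein_id|^protein_id\t", first)) "tsv" else "domtblout"
  }
  hits <- if (dialect == "domtblout") read_domtblout(path) else read_domains_tsv(path)
  n0 <- nrow(hits)
  hits <- hits[hits$evalue < evalue_threshold, , drop = FALSE]
  bad <- hits$env_start < 1 | hits$env_end < hits$env_start | hits$evalue < 0
  if (any(bad)) {
    warning(sum(bad), " malformed domain row(s) skipped")
    hits <- hits[!bad, , drop = FALSE]
  }
  structure(tibble::as_tibble(hits), dropped = n0 - nrow(hits))
}

read_domains_tsv <- function(path) {
  h <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("protein_id", "domain", "start", "end", "evalue", "score")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) stop("domain TSV missing column(s): ",
                             paste(miss, collapse = ", "))
  tibble::tibble(
    protein_id = as.character(h$protein_id),
    domain = as.character(h$domain),
    accession = if ("accession" %in% names(h)) as.character(h$accession) else NA_character_,
    env_start = as.integer(h$start),
    env_end = as.integer(h$end),
    evalue = as.numeric(h$evalue),
    bitscore = as.numeric(h$score)
  )
}

# hmmscan --domtblout: whitespace-separated, 22 fixed columns then free text.
# Col 1 target (domain) name, 2 accession, 4 query (protein) name,
# 13 i-Evalue, 14 dom score, 20-21 env from/to.
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), domain = character(),
                          accession = character(), env_start = integer(),
                          env_end = integer(), evalue = double(),
                          bitscore = double()))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ok <- lengths(parts) >= 22
  if (any(!ok)) warning(sum(!ok), " malformed domtblout row(s) skipped")
  parts <- parts[ok]
  field <- function(i) vapply(parts, `[[`, "", i)
  acc <- field(2)
  acc <- sub("\\.\\d+$", "", acc)
  acc[acc == "-"] <- NA_character_
  tibble::tibble(
    protein_id = field(4),
    domain = field(1),
    accession = acc,
    env_start = as.integer(field(20)),
    env_end = as.integer(field(21)),
    evalue = as.numeric(field(13)),
    bitscore = as.numeric(field(14))
  )
}

#' Write a domain-hit table as TSV
#' @param hits A domain-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  out <- tibble::tibble(protein_id = hits$protein_id, domain = hits$domain,
                        accession = hits$accession, start = hits$env_start,
                        end = hits$env_end, evalue = hits$evalue,
                        score = hits$bitscore)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return A named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write protein sequences to FASTA
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0(">", names(sequences)[i]), sequences[[i]]), con)
  }
  invisible(path)
}

#' Read genome metadata (ecotype labels)
#'
#' @param path TSV with header `genome_id,ecotype` (and optionally `species`,
#'   `genome_size`). Ecotype must be one of `vent_specialist`, `generalist`,
#'   `host_associated`, `unknown`.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("genome_id", "ecotype") %in% names(m))) {
    stop("metadata must have genome_id and ecotype columns")
  }
  known <- c("vent_specialist", "generalist", "host_associated", "unknown")
  bad <- setdiff(unique(m$ecotype), known)
  if (length(bad) > 0) {
    warning("unknown ecotype label(s) mapped to 'unknown': ",
            paste(bad, collapse = ", "))
    m$ecotype[m$ecotype %in% bad] <- "unknown"
  }
  m
}
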