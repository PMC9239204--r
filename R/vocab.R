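#' Domain vocabulary: map domain identifiers to role tokens
#'
#' Classification rules in this package never test raw domain strings; they test
#' *role tokens* ("HisKA", "REC", "GGDEF", ...). A vocabulary maps every accepted
#' identifier for a domain -- Pfam accession (e.g. "PF00512"), Pfam name
#' ("HisKA"), or SMART name -- onto one role token, so that inputs annotated
#' with different naming dialects classify identically.
#'
#' `default_vocabulary()` returns the built-in vocabulary covering the domains
#' used by the two-component, c-di-GMP, chemosensory, ECF, cAMP and STYK rules.
#' `read_vocabulary()` loads a user YAML file with the same structure: a mapping
#' from role token to a list of accepted identifiers, plus an `hth_output`
#' list naming the DNA-binding output domains used for response-regulator
#' output typing.
#'
#' @param path Path to a YAML vocabulary file.
#' @return A `sigcensus_vocab` object: a named list of character vectors
#'   (role token -> accepted identifiers) with an `hth_output` attribute.
#' @examples
#' v <- default_vocabulary()
#' names(v)
#' @export
default_vocabulary <- function() {
  roles <- list(
    HisKA       = c("PF00512", "HisKA", "HisKA_2", "PF07568"),
    # HATPase family covers both the classical HK ATPase (PF02518) and the
    # HATPase_c_3 family (PF13581) used by STAS-kinases; HisKA presence
    # separates the two downstream.
    HATPase     = c("PF02518", "HATPase_c", "HATPase", "PF13581", "HATPase_c_3"),
    REC         = c("PF00072", "Response_reg", "REC"),
    Hpt         = c("PF01627", "Hpt", "HPT"),
    GGDEF       = c("PF00990", "GGDEF"),
    EAL         = c("PF00563", "EAL"),
    HD_GYP      = c("PF13487", "HD-GYP", "HD_GYP", "HD_5"),
    sigma70_r2  = c("PF04542", "Sigma70_r2"),
    sigma70_r4_2 = c("PF08281", "Sigma70_r4_2"),
    AC          = c("PF01295", "Adenylate_cycl", "PF00211", "Guanylate_cyc"),
    CHASE2      = c("PF05226", "CHASE2"),
    Pkinase     = c("PF00069", "Pkinase"),
    PP2C        = c("PF00481", "PP2C", "PF07228", "SpoIIE"),
    STAS        = c("PF01740", "STAS"),
    MCPsignal   = c("PF00015", "MCPsignal", "MA", "MCP_signal"),
    CheW        = c("PF01584", "CheW"),
    CheB        = c("PF01339", "CheB_methylest"),
    CheR        = c("PF01739", "CheR", "PF03705", "CheR_N"),
    CheC        = c("PF04509", "CheC"),
    CheX        = c("PF13690", "CheX"),
    CheD        = c("PF03975", "CheD"),
    CheZ        = c("PF04344", "CheZ"),
    FecR        = c("PF04773", "FecR"),
    TonB_receptor = c("PF00593", "TonB_dep_Rec", "Plug", "PF07715"),
    TPR         = c("PF00515", "TPR_1", "PF07719", "TPR_2", "PF13176", "TPR_7"),
    CAMP_PDE    = c("PF00233", "PDEase_I", "PF02112", "PDEase_II"),
    CRP         = c("PF00325", "Crp", "HTH_Crp_2", "PF13545")
  )
  hth <- c("PF00196", "GerE", "PF00486", "Trans_reg_C", "PF02954", "HTH_8",
           "PF12833", "HTH_18", "PF00165", "HTH_AraC", "PF01978", "HTH_10",
           "PF13384", "HTH_23", "PF04397", "LytTR")
  new_vocabulary(roles, hth)
}

new_vocabulary <- function(roles, hth_output) {
  ids <- unlist(roles, use.names = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("vocabulary maps identifier(s) to more than one role token: ",
         paste(dup, collapse = ", "))
  }
  structure(roles, hth_output = hth_output, class = "sigcensus_vocab")
}

#' @rdname default_vocabulary
#' @export
read_vocabulary <- function(path) {
  y <- yaml::read_yaml(path)
  hth <- as.character(y$hth_output %||% character())
  y$hth_output <- NULL
  roles <- lapply(y, as.character)
  new_vocabulary(roles, hth)
}

#' Translate domain identifiers to role tokens
#'
#' Vectorised lookup: each identifier (accession or name) is mapped to its role
#' token, or `NA` when the vocabulary does not know it. Hits are matched by
#' accession first, then by name.
#'
#' @param domain,accession Character vectors of domain names and (optionally)
#'   accessions, recycled against each other.
#' @param vocab A vocabulary from [default_vocabulary()] or [read_vocabulary()].
#' @return Character vector of role tokens (`NA` for unknown domains).
#' @export
domain_role <- function(domain, accession = NULL, vocab = default_vocabulary()) {
  lut <- vocab_lookup(vocab)
  role <- unname(lut[as.character(domain)])
  if (!is.null(accession)) {
    by_acc <- unname(lut[as.character(accession)])
    role <- dplyr::coalesce(by_acc, role)
  }
  role
}

vocab_lookup <- function(vocab) {
  toks <- rep(names(vocab), lengths(vocab))
  ids <- unlist(vocab, use.names = FALSE)
  stats::setNames(toks, ids)
}

#' Annotate a domain-hit table with role tokens
#'
#' Adds a `role` column (vocabulary role token or `NA`) and an `is_hth` column
#' flagging DNA-binding output domains.
#'
#' @param hits A domain-hit tibble (see [read_domain_table()]).
#' @param vocab A domain vocabulary.
#' @return The input tibble with `role` and `is_hth` columns appended.
#' @export
annotate_roles <- function(hits, vocab = default_vocabulary()) {
  hth <- attr(vocab, "hth_output")
  hits$role <- domain_role(hits$domain, hits$accession, vocab)
  hits$is_hth <- hits$domain %in% hth |
    (!is.na(hits$accession) & hits$accession %in% hth)
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
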