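#' Classify auxiliary signaling systems from domain architecture
#'
#' One pass over all proteins assigning the non-TCS, non-chemosensory,
#' non-c-di-GMP system labels:
#'
#' * **ECF** -- extracytoplasmic function sigma factor: an architecture of
#'   exactly one sigma70 region-2 and one region-4.2 domain and *nothing
#'   else* ("both and only"); any extra domain disqualifies.
#' * **AC** -- adenylate cyclase (Adenylate_cycl/Guanylate_cyc domain);
#'   `has_chase2` records the CHASE2 sensor.
#' * **eSTYK** -- eukaryotic-type Ser/Thr/Tyr kinase (Pkinase domain).
#' * **bifunctional_PP2C_Pkinase** -- kinase/phosphatase fusion (Pkinase +
#'   PP2C).
#' * **stas_STYK** -- HATPase-family kinase with no HisKA (so not a TCS
#'   kinase), no Hpt (so not CheA) and no Pkinase; phosphorylates
#'   single-STAS-domain proteins.
#' * **PP2C** -- PP2C-family phosphatase (no Pkinase, no HisKA).
#' * **STAS** -- a single STAS domain and nothing else.
#' * **CRP_like** -- cAMP receptor protein homolog.
#'
#' @param hits Resolved, role-annotated domain hits.
#' @param vocab Domain vocabulary.
#' @return Tibble `protein_id`, `system`, `has_chase2`, `has_rec` for every
#'   protein matching a system.
#' @export
classify_aux <- function(hits, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  s <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    n_hits = dplyr::n(),
    n_r2 = sum(.data$role %in% "sigma70_r2"),
    n_r4 = sum(.data$role %in% "sigma70_r4_2"),
    has_ac = any(.data$role %in% "AC"),
    has_chase2 = any(.data$role %in% "CHASE2"),
    has_pkinase = any(.data$role %in% "Pkinase"),
    has_pp2c = any(.data$role %in% "PP2C"),
    has_hatpase = any(.data$role %in% "HATPase"),
    has_hiska = any(.data$role %in% "HisKA"),
    has_hpt = any(.data$role %in% "Hpt"),
    has_rec = any(.data$role %in% "REC"),
    has_crp = any(.data$role %in% "CRP"),
    single_stas = dplyr::n() == 1 && all(.data$role %in% "STAS"),
    .groups = "drop"
  )
  system <- dplyr::case_when(
    s$n_r2 == 1 & s$n_r4 == 1 & s$n_hits == 2 ~ "ECF",
    s$has_ac ~ "AC",
    s$has_pkinase & s$has_pp2c ~ "bifunctional_PP2C_Pkinase",
    s$has_pkinase ~ "eSTYK",
    s$has_hatpase & !s$has_hiska & !s$has_hpt ~ "stas_STYK",
    s$has_pp2c & !s$has_hiska ~ "PP2C",
    s$single_stas ~ "STAS",
    s$has_crp ~ "CRP_like",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(protein_id = s$protein_id, system = system,
                        has_chase2 = s$has_chase2, has_rec = s$has_rec)
  out[!is.na(out$system), , drop = FALSE]
}

#' Exact-architecture test for ECF sigma factors
#'
#' @param hits Resolved, role-annotated domain hits for any number of
#'   proteins.
#' @param vocab Domain vocabulary.
#' @return Tibble `protein_id`, `is_ecf`: TRUE iff the architecture is exactly
#'   one sigma70 region-2 plus one region-4.2 domain.
#' @export
classify_ecf <- function(hits, vocab = default_vocabulary()) {
  hits <- ensure_roles(hits, vocab)
  s <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    is_ecf = sum(.data$role %in% "sigma70_r2") == 1 &&
      sum(.data$role %in% "sigma70_r4_2") == 1 && dplyr::n() == 2,
    .groups = "drop"
  )
  s
}

# genes whose protein carries a given role domain anywhere
genes_with_domain <- function(genes, hits, role) {
  pids <- unique(hits$protein_id[hits$role %in% role])
  genes[!is.na(genes$protein_id) & genes$protein_id %in% pids, , drop = FALSE]
}

#' Detect ECF242-type sigma/anti-sigma clusters
#'
#' The ECF242 group couples a sigma factor (FecI) to an anti-sigma factor
#' (FecR) and a TonB-dependent outer-membrane receptor (FecA). Every ECF gene
#' with a FecR-domain gene within `window` intervening genes is reported as a
#' candidate; TonB-dependent receptor genes in the window are recorded as
#' supporting members.
#'
#' @param genes Gene tibble.
#' @param hits Resolved, role-annotated domain hits.
#' @param aux Output of [classify_aux()].
#' @param window Neighborhood window (default 4).
#' @return Tibble `ecf_gene_id`, `fecr_gene_ids` (list), `tonb_gene_ids`
#'   (list), `n_members`.
#' @export
detect_ecf242 <- function(genes, hits, aux, window = 4) {
  ecf_pids <- aux$protein_id[aux$system == "ECF"]
  ecf_g <- genes[!is.na(genes$protein_id) &
                   genes$protein_id %in% ecf_pids, , drop = FALSE]
  fecr_g <- genes_with_domain(genes, hits, "FecR")
  tonb_g <- genes_with_domain(genes, hits, "TonB_receptor")
  empty <- tibble::tibble(ecf_gene_id = character(), fecr_gene_ids = list(),
                          tonb_gene_ids = list(), n_members = integer())
  if (nrow(ecf_g) == 0 || nrow(fecr_g) == 0) return(empty)
  pf <- pairs_within(ecf_g, fecr_g, window)
  if (nrow(pf) == 0) return(empty)
  pt <- pairs_within(ecf_g, tonb_g, window)
  out <- dplyr::summarise(dplyr::group_by(pf, ecf_gene_id = .data$from_gene),
                          fecr_gene_ids = list(sort(.data$to_gene)),
                          .groups = "drop")
  out$tonb_gene_ids <- lapply(out$ecf_gene_id, function(g) {
    sort(pt$to_gene[pt$from_gene == g])
  })
  out$n_members <- 1L + lengths(out$fecr_gene_ids) + lengths(out$tonb_gene_ids)
  dplyr::arrange(out, .data$ecf_gene_id)
}

#' Detect cAMP signaling gene clusters
#'
#' Adenylate cyclase genes frequently sit in a four-gene cluster with a
#' cAMP-hydrolysing phosphodiesterase, a FecR-domain outer-membrane protein
#' and a TPR protein. Each cyclase gene is reported with the support found in
#' its window; it is a `cluster` candidate when at least two of the three
#' partners are present. A cyclase with no partners still marks the cAMP
#' system as present. CRP-like regulators are summarised separately so that
#' genomes carrying CRP homologs but no cyclase can be flagged: such CRPs are
#' unlikely to be cAMP-regulated.
#'
#' @param genes Gene tibble.
#' @param hits Resolved, role-annotated domain hits.
#' @param aux Output of [classify_aux()].
#' @param window Neighborhood window (default 6).
#' @return A list: `cyclases` (tibble `gene_id`, `protein_id`, `has_chase2`,
#'   `has_pde`, `has_fecr`, `has_tpr`, `n_support`, `cluster`),
#'   `n_crp`, `crp_without_cyclase`.
#' @export
detect_camp_clusters <- function(genes, hits, aux, window = 6) {
  ac_pids <- aux$protein_id[aux$system == "AC"]
  ac_g <- genes[!is.na(genes$protein_id) &
                  genes$protein_id %in% ac_pids, , drop = FALSE]
  n_crp <- sum(aux$system == "CRP_like")
  support_in_window <- function(targets) {
    if (nrow(ac_g) == 0 || nrow(targets) == 0) {
      return(rep(FALSE, nrow(ac_g)))
    }
    p <- pairs_within(ac_g, targets, window)
    ac_g$gene_id %in% p$from_gene
  }
  cyc <- tibble::tibble(
    gene_id = ac_g$gene_id,
    protein_id = ac_g$protein_id,
    has_chase2 = aux$has_chase2[match(ac_g$protein_id, aux$protein_id)],
    has_pde = support_in_window(genes_with_domain(genes, hits, "CAMP_PDE")),
    has_fecr = support_in_window(genes_with_domain(genes, hits, "FecR")),
    has_tpr = support_in_window(genes_with_domain(genes, hits, "TPR"))
  )
  cyc$n_support <- rowSums(cbind(cyc$has_pde, cyc$has_fecr, cyc$has_tpr))
  cyc$cluster <- cyc$n_support >= 2
  list(cyclases = dplyr::arrange(cyc, .data$gene_id), n_crp = n_crp,
       crp_without_cyclase = n_crp > 0 && nrow(cyc) == 0)
}

#' Quorum-sensing domain screen
#'
#' For each configured QS pathway, checks the genome's domain hits for
#' synthase-diagnostic and receptor-ligand-binding domains. A pathway is
#' called **present** only when both sides are found; one side alone is noted
#' as partial.
#'
#' @param hits Domain-hit tibble (raw or resolved).
#' @param qs_vocab QS vocabulary: a named list, one entry per pathway, each
#'   with `synthase` and `receptor` character vectors of accepted domain
#'   identifiers. See [default_qs_vocabulary()].
#' @return Tibble `pathway`, `synthase_found`, `receptor_found`, `present`,
#'   `status` (`present`/`partial`/`absent`).
#' @export
qs_screen <- function(hits, qs_vocab = default_qs_vocabulary()) {
  ids <- unique(c(hits$domain, hits$accession))
  purrr::imap_dfr(qs_vocab, function(pw, name) {
    syn <- any(pw$synthase %in% ids)
    rec <- any(pw$receptor %in% ids)
    tibble::tibble(
      pathway = name, synthase_found = syn, receptor_found = rec,
      present = syn && rec,
      status = if (syn && rec) "present" else if (syn || rec) "partial" else "absent"
    )
  })
}

#' Default and user-supplied QS vocabularies
#'
#' The shipped defaults cover three well-studied pathways (acyl-homoserine
#' lactone, AI-2, CAI-1) with best-effort diagnostic domains; the real
#' inventory of QS component domains is curation-dependent, so users are
#' expected to override via YAML (`pathways: {name: {synthase: [...],
#' receptor: [...]}}`).
#'
#' @param path YAML file.
#' @return Named list of pathways.
#' @export
default_qs_vocabulary <- function() {
  list(
    AHL = list(synthase = c("PF00765", "Autoind_synth"),
               receptor = c("PF03472", "Autoind_bind")),
    AI2 = list(synthase = c("PF02664", "LuxS"),
               receptor = c("LuxP", "PF13407")),
    CAI1 = list(synthase = c("CqsA"),
                receptor = c("CqsS_6TM"))
  )
}

#' @rdname default_qs_vocabulary
#' @export
read_qs_vocabulary <- function(path) {
  y <- yaml::read_yaml(path)
  pw <- y$pathways %||% y
  lapply(pw, function(p) list(synthase = as.character(p$synthase),
                              receptor = as.character(p$receptor)))
}

#' Detect candidate combined (merged-system) pathways
#'
#' Searches gene neighborhoods for co-occurrence patterns that merge two or
#' more signaling mechanisms:
#'
#' * `pp2c_styk_stas_cdgmp`: a PP2C phosphatase, a STAS-kinase
#'   (stas_STYK), a STAS protein and a c-di-GMP turnover enzyme within one
#'   window -- kinase/phosphatase control of a STAS protein regulating the
#'   enzyme.
#' * `rec_pp2c_styk_mcp`: a REC-fused bifunctional PP2C-Pkinase protein with
#'   a STAS protein and a chemoreceptor in the window -- phosphorylation
#'   control feeding a receptor.
#' * `ecf_partial_plus_cyclase`: a sigma-factor region gene (full or partial
#'   ECF) adjacent to a cAMP or c-di-GMP enzyme gene.
#'
#' All members of a candidate lie within `window` intervening genes of the
#' rule's anchor gene. Confidence is `unverified` because transmembrane or
#' periplasmic-sensor annotation is not required; supplying `tm_proteins`
#' upgrades candidates whose enzyme or phosphatase is TM-annotated to `high`.
#'
#' @param genes Gene tibble.
#' @param hits Resolved, role-annotated domain hits.
#' @param aux Output of [classify_aux()].
#' @param cdgmp Output of [identify_cdgmp()].
#' @param window Neighborhood window (default 6).
#' @param tm_proteins Optional character vector of protein ids carrying
#'   transmembrane/periplasmic-sensor annotation.
#' @return Tibble `rule`, `anchor_gene_id`, `member_gene_ids` (list),
#'   `confidence`.
#' @export
detect_combined_pathways <- function(genes, hits, aux, cdgmp, window = 6,
                                     tm_proteins = NULL) {
  gene_of <- function(pids) {
    genes[!is.na(genes$protein_id) & genes$protein_id %in% pids, , drop = FALSE]
  }
  pp2c_g <- gene_of(aux$protein_id[aux$system == "PP2C"])
  styk_g <- gene_of(aux$protein_id[aux$system == "stas_STYK"])
  stas_g <- gene_of(aux$protein_id[aux$system == "STAS"])
  bifun_rec_g <- gene_of(aux$protein_id[
    aux$system == "bifunctional_PP2C_Pkinase" & aux$has_rec])
  cdgmp_g <- gene_of(cdgmp$protein_id)
  mcp_g <- genes_with_domain(genes, hits, "MCPsignal")
  sigma_g <- genes_with_domain(genes, hits, c("sigma70_r2", "sigma70_r4_2"))
  ac_g <- gene_of(aux$protein_id[aux$system == "AC"])
  cyc_or_cdgmp_g <- dplyr::distinct(dplyr::bind_rows(ac_g, cdgmp_g))

  hit_rule <- function(anchors, partners, rule) {
    if (nrow(anchors) == 0) return(NULL)
    rows <- lapply(seq_len(nrow(anchors)), function(i) {
      a <- anchors[i, ]
      members <- lapply(partners, function(p) {
        pw <- pairs_within(a, p, window)
        unique(pw$to_gene)
      })
      if (any(lengths(members) == 0)) return(NULL)
      all_members <- sort(unique(c(a$gene_id, unlist(members))))
      tibble::tibble(rule = rule, anchor_gene_id = a$gene_id,
                     member_gene_ids = list(all_members))
    })
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(
    hit_rule(pp2c_g, list(styk_g, stas_g, cdgmp_g), "pp2c_styk_stas_cdgmp"),
    hit_rule(bifun_rec_g, list(stas_g, mcp_g), "rec_pp2c_styk_mcp"),
    hit_rule(sigma_g, list(cyc_or_cdgmp_g), "ecf_partial_plus_cyclase")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(rule = character(), anchor_gene_id = character(),
                          member_gene_ids = list(), confidence = character()))
  }
  tm <- tm_proteins %||% character()
  member_pids <- lapply(out$member_gene_ids, function(ids) {
    genes$protein_id[match(ids, genes$gene_id)]
  })
  out$confidence <- ifelse(
    vapply(member_pids, function(p) any(p %in% tm), logical(1)),
    "high", "unverified")
  dplyr::arrange(out, .data$rule, .data$anchor_gene_id)
}
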