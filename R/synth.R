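#' Synthetic genomes with ground truth
#'
#' The generator builds whole genomes -- ordered gene tables, domain-hit
#' tables and (where needed) protein sequences -- from a list of *implant
#' directives*, each of which places a fully specified signaling feature
#' (a TCS pair, a solo kinase at an exact gene distance, a diguanylate
#' cyclase with a chosen A-site motif and I-site state, a chemosensory
#' cluster following a named class signature, an ECF242 cluster, ...) into a
#' background of decoy genes. Because every feature is implanted, the
#' expected classification of every protein, cluster and census column is
#' known by construction and returned as ground truth.
#'
#' Implant blocks are separated by at least `buffer` background genes
#' (default 8, larger than every neighborhood window used by the
#' classifiers), so directives cannot interfere with each other's
#' gene-distance rules. Domain hits are emitted directly into the domain
#' table -- the generator does not require a homology search to close the
#' loop -- and protein sequences are random over the 20-letter alphabet
#' except at implanted motif windows.
#'
#' @param seed Integer seed; output is byte-identical for identical seeds.
#' @param n_genes Genes per replicon.
#' @param n_replicons Number of replicons (blocks are distributed
#'   round-robin).
#' @param implants List of directive lists; each has a `type` plus
#'   type-specific fields (see `synth_implant()` and the vignette).
#' @param decoy_rate Probability that a background gene carries 1--2 decoy
#'   domains.
#' @param frac_noncoding Fraction of background genes emitted as non-coding
#'   records (no protein, but occupying an ordinal).
#' @param buffer Minimum background genes between implant blocks.
#' @param genome_id Identifier used in gene/protein ids.
#' @param ecotype Ecotype label carried into the truth.
#' @param signatures Chemosensory signature list used to lay out
#'   `che_cluster` implants.
#' @return A list with `genes`, `domains`, `sequences` (named character),
#'   `truth` (list: `proteins`, `che_clusters`, `atypical`, `qs`, `combined`,
#'   `expected` one-row census expectation), `genome_id`, `ecotype`.
#' @export
synth_generate <- function(seed, n_genes = 300, n_replicons = 1,
                           implants = list(), decoy_rate = 0.05,
                           frac_noncoding = 0.02, buffer = 8,
                           genome_id = "synthG", ecotype = "unknown",
                           signatures = default_f_signatures()) {
  with_local_seed(seed, {
    blocks <- unlist(lapply(implants, expand_implant, signatures = signatures),
                     recursive = FALSE)
    # round-robin assignment of blocks to replicons
    rep_of <- if (length(blocks) > 0) ((seq_along(blocks) - 1L) %% n_replicons) + 1L
              else integer(0)
    per_rep <- split(seq_along(blocks), factor(rep_of, levels = seq_len(n_replicons)))
    need <- vapply(seq_len(n_replicons), function(r) {
      idx <- per_rep[[r]]
      sum(vapply(idx, function(i) length(blocks[[i]]$templates), integer(1))) +
        as.integer(buffer) * (length(idx) + 1L)
    }, integer(1))
    if (any(need > n_genes)) {
      stop("unrealizable spec: implants + buffers need ", max(need),
           " genes per replicon but n_genes = ", n_genes)
    }

    gene_counter <- 0L
    prot_counter <- 0L
    all_templates <- list()
    gene_rep <- character(0)
    for (r in seq_len(n_replicons)) {
      idx <- per_rep[[r]]
      tpls <- list()
      for (i in idx) {
        tpls <- c(tpls, replicate(buffer, t_background(decoy_rate, frac_noncoding),
                                  simplify = FALSE),
                  blocks[[i]]$templates)
      }
      n_bg_tail <- n_genes - length(tpls)
      tpls <- c(tpls, replicate(n_bg_tail,
                                t_background(decoy_rate, frac_noncoding),
                                simplify = FALSE))
      all_templates <- c(all_templates, tpls)
      gene_rep <- c(gene_rep, rep(paste0("chr", r), length(tpls)))
    }

    n <- length(all_templates)
    gene_id <- sprintf("%s_g%05d", genome_id, seq_len(n))
    coding <- !vapply(all_templates, function(t) isTRUE(t$noncoding), logical(1))
    protein_id <- rep(NA_character_, n)
    protein_id[coding] <- sprintf("%s_p%05d", genome_id, seq_len(sum(coding)))

    plen <- vapply(all_templates, function(t) t$plen %||% 250L, integer(1))
    glen <- 3L * plen + 3L
    gaps <- 50L + as.integer(floor(stats::runif(n) * 150))
    genes <- tibble::tibble(gene_id = gene_id, replicon = gene_rep,
                            start = 0L, end = 0L,
                            strand = sample(c("+", "-"), n, replace = TRUE),
                            protein_id = protein_id)
    genes <- dplyr::group_modify(dplyr::group_by(genes, .data$replicon),
      function(df, key) {
        i <- match(df$gene_id, gene_id)
        st <- cumsum(c(1L, glen[i[-length(i)]] + gaps[i[-length(i)]]))
        df$start <- st
        df$end <- st + glen[i] - 1L
        df
      })
    genes <- assign_ordinals(dplyr::ungroup(genes))

    # domain table
    dom_rows <- lapply(seq_len(n), function(i) {
      d <- all_templates[[i]]$domains
      if (is.null(d) || is.na(protein_id[i])) return(NULL)
      k <- length(d$domain)
      list(protein_id = rep(protein_id[i], k), domain = d$domain,
           start = d$start, end = d$end)
    })
    dom_rows <- dom_rows[!vapply(dom_rows, is.null, logical(1))]
    nd <- sum(vapply(dom_rows, function(x) length(x$domain), integer(1)))
    domains <- tibble::tibble(
      protein_id = unlist(lapply(dom_rows, `[[`, "protein_id")),
      domain = unlist(lapply(dom_rows, `[[`, "domain")),
      accession = NA_character_,
      env_start = as.integer(unlist(lapply(dom_rows, `[[`, "start"))),
      env_end = as.integer(unlist(lapply(dom_rows, `[[`, "end"))),
      evalue = 10^-(8 + stats::runif(nd) * 30),
      bitscore = 50 + stats::runif(nd) * 250
    )

    # sequences (only proteins that need motif calls carry one)
    seq_idx <- which(vapply(all_templates, function(t) !is.null(t$seq), logical(1)))
    sequences <- stats::setNames(
      vapply(seq_idx, function(i) {
        sp <- all_templates[[i]]$seq
        make_dgc_sequence(plen[i], sp$ggdef_start, sp$ggdef_end,
                          sp$a_site, sp$i_site)
      }, character(1)),
      protein_id[seq_idx])

    # ground truth
    tdef <- list(tcs_role = "none", rr_output = NA_character_,
                 solo = NA, che = NA_character_, aux = NA_character_,
                 is_cdgmp = FALSE, has_ggdef = FALSE, has_eal = FALSE,
                 has_hdgyp = FALSE, has_partner = FALSE, single_domain = FALSE,
                 a_site = NA_character_, i_site = NA_character_, near_hk = NA)
    truths <- lapply(all_templates, function(t) utils::modifyList(tdef, t$truth %||% list()))
    proteins <- tibble::tibble(
      protein_id = protein_id, gene_id = gene_id,
      tcs_role = vapply(truths, `[[`, "", "tcs_role"),
      rr_output = vapply(truths, function(x) as.character(x$rr_output), ""),
      solo = vapply(truths, function(x) as.logical(x$solo), logical(1)),
      che = vapply(truths, function(x) as.character(x$che), ""),
      aux = vapply(truths, function(x) as.character(x$aux), ""),
      is_cdgmp = vapply(truths, `[[`, logical(1), "is_cdgmp"),
      has_ggdef = vapply(truths, `[[`, logical(1), "has_ggdef"),
      has_eal = vapply(truths, `[[`, logical(1), "has_eal"),
      has_hdgyp = vapply(truths, `[[`, logical(1), "has_hdgyp"),
      has_partner = vapply(truths, `[[`, logical(1), "has_partner"),
      single_domain = vapply(truths, `[[`, logical(1), "single_domain"),
      a_site = vapply(truths, function(x) as.character(x$a_site), ""),
      i_site = vapply(truths, function(x) as.character(x$i_site), ""),
      near_hk = vapply(truths, function(x) as.logical(x$near_hk), logical(1))
    )
    proteins <- proteins[coding, , drop = FALSE]

    block_truth <- lapply(blocks, `[[`, "truth")
    che_clusters <- dplyr::bind_rows(lapply(block_truth, `[[`, "che_cluster"))
    atypical <- dplyr::bind_rows(lapply(block_truth, `[[`, "atypical"))
    qs_truth <- dplyr::bind_rows(lapply(block_truth, `[[`, "qs"))
    combined <- dplyr::bind_rows(lapply(block_truth, `[[`, "combined"))
    extra_counts <- list(
      n_ecf242 = sum(vapply(block_truth, function(x) x$n_ecf242 %||% 0L, numeric(1))),
      n_camp_clusters = sum(vapply(block_truth, function(x) x$n_camp_clusters %||% 0L, numeric(1)))
    )
    truth <- list(proteins = proteins, che_clusters = che_clusters,
                  atypical = atypical, qs = qs_truth, combined = combined)
    truth$expected <- truth_census(genome_id, ecotype, nrow(genes), truth,
                                   extra_counts, signatures)
    list(genes = genes, domains = domains, sequences = sequences,
         truth = truth, genome_id = genome_id, ecotype = ecotype)
  })
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- expected census from ground truth ------------------------------------

truth_census <- function(genome_id, ecotype, n_genes, truth, extra, signatures) {
  p <- truth$proteins
  rr <- p$rr_output[p$tcs_role == "RR" & !is.na(p$rr_output)]
  n_rr <- sum(p$tcs_role == "RR")
  bifun <- p$has_ggdef & (p$has_eal | p$has_hdgyp)
  pde_only <- (p$has_eal | p$has_hdgyp) & !p$has_ggdef
  active <- !is.na(p$a_site) & p$a_site == "active"
  class_names <- vapply(signatures, `[[`, "", "class_name")
  status <- stats::setNames(rep("none", length(class_names)), class_names)
  if (nrow(truth$che_clusters) > 0) {
    ord <- c(full = 1, half = 2, partial = 3, none = 4)
    for (cl in class_names) {
      st <- truth$che_clusters$status[truth$che_clusters$class == cl]
      if (length(st) > 0) status[[cl]] <- names(sort(ord[st]))[1]
    }
  }
  status_cols <- tibble::as_tibble(as.list(status))
  names(status_cols) <- paste0("class_", names(status))
  n_ac <- sum(p$aux %in% "AC")
  n_crp <- sum(p$aux %in% "CRP_like")
  tibble::tibble(
    genome_id = genome_id, ecotype = ecotype, n_genes = n_genes,
    n_chemoreceptors = sum(p$che %in% "MCP"),
    n_che_classes = sum(status %in% c("full", "half")),
    status_cols,
    n_hk = sum(p$tcs_role == "HK"),
    n_hhk = sum(p$tcs_role == "HHK"),
    n_hrr = sum(p$tcs_role == "HRR"),
    n_hk_total = sum(p$tcs_role %in% c("HK", "HHK", "HRR")),
    n_solo = sum(p$solo, na.rm = TRUE),
    n_rr = n_rr,
    n_rr_dna = sum(rr == "dna_binding"),
    n_rr_cdgmp = sum(rr == "cdgmp_enzyme"),
    n_rr_other = sum(rr == "other_unknown"),
    rr_prop_dna = if (n_rr > 0) sum(rr == "dna_binding") / n_rr else NA_real_,
    rr_prop_cdgmp = if (n_rr > 0) sum(rr == "cdgmp_enzyme") / n_rr else NA_real_,
    rr_prop_other = if (n_rr > 0) sum(rr == "other_unknown") / n_rr else NA_real_,
    total_dgc = sum(p$has_ggdef),
    dgc_with_partner = sum(p$has_ggdef & p$has_partner & !bifun),
    pde_with_partner = sum(pde_only & p$has_partner),
    bifunctional = sum(bifun),
    single_domain = sum(p$single_domain),
    active_dgc = sum(active),
    n_enzymes = sum(p$is_cdgmp),
    cdgmp_signaling = sum(active) > 0,
    n_ecf = sum(p$aux %in% "ECF"),
    n_ecf242 = extra$n_ecf242,
    n_ac = n_ac,
    n_camp_clusters = extra$n_camp_clusters,
    n_crp = n_crp,
    crp_without_cyclase = n_crp > 0 && n_ac == 0,
    n_estyk = sum(p$aux %in% "eSTYK"),
    n_stas_styk = sum(p$aux %in% "stas_STYK"),
    n_pp2c = sum(p$aux %in% "PP2C"),
    n_bifunctional_pp2c_pk = sum(p$aux %in% "bifunctional_PP2C_Pkinase"),
    n_stas = sum(p$aux %in% "STAS"),
    n_qs_present = if (nrow(truth$qs) > 0) sum(truth$qs$present) else 0L,
    n_combined = if (nrow(truth$combined) > 0) sum(truth$combined$n) else 0L,
    n_atypical_clusters = nrow(truth$atypical)
  )
}

# ---- protein templates -----------------------------------------------------

dom_lengths <- c(
  HisKA = 66, HATPase_c = 110, HATPase_c_3 = 105, Response_reg = 112,
  GGDEF = 158, EAL = 230, `HD-GYP` = 170, MCPsignal = 180, CheW = 140,
  Hpt = 90, CheB_methylest = 190, CheR = 200, CheC = 190, CheX = 160,
  CheD = 160, CheZ = 180, PAS = 100, Cache_1 = 110, Pkinase = 250,
  PP2C = 230, STAS = 110, Sigma70_r2 = 70, Sigma70_r4_2 = 55,
  Adenylate_cycl = 180, CHASE2 = 200, FecR = 110, TonB_dep_Rec = 420,
  TPR_1 = 34, PDEase_I = 230, Crp = 180, Trans_reg_C = 77
)
decoy_domains <- c("ABC_tran", "Radical_SAM", "MFS_1", "Glycos_transf_1",
                   "Ribosomal_S2", "DUF4012", "HlyD", "Aminotran_1_2",
                   "SBP_bac_5", "Acetyltransf_1")

dom_layout <- function(names) {
  lens <- as.integer(ifelse(names %in% names(dom_lengths),
                            dom_lengths[names], 150L))
  linker <- 15L
  start <- cumsum(c(10L, lens[-length(lens)] + linker))
  list(domain = names, start = start, end = start + lens - 1L,
       plen = start[length(start)] + lens[length(lens)] + 20L)
}

tpl <- function(doms, truth = list(), seq = NULL) {
  if (is.null(doms)) return(list(domains = NULL, plen = 250L, truth = truth))
  lay <- dom_layout(doms)
  t <- list(domains = lay[c("domain", "start", "end")], plen = lay$plen,
            truth = truth, seq = seq)
  if (!is.null(seq)) {
    gi <- which(doms == "GGDEF")[1]
    t$seq$ggdef_start <- lay$start[gi]
    t$seq$ggdef_end <- lay$end[gi]
  }
  t
}

t_background <- function(decoy_rate, frac_noncoding) {
  if (stats::runif(1) < frac_noncoding) {
    return(list(domains = NULL, plen = 80L, truth = list(), noncoding = TRUE))
  }
  if (stats::runif(1) < decoy_rate) {
    k <- sample(1:2, 1)
    tpl(sample(decoy_domains, k))
  } else {
    list(domains = NULL, plen = as.integer(150 + floor(stats::runif(1) * 250)),
         truth = list())
  }
}

t_hk <- function(solo = FALSE) tpl(c("HisKA", "HATPase_c"),
                                   list(tcs_role = "HK", solo = solo))
t_hhk <- function(solo = FALSE) tpl(c("HisKA", "HATPase_c", "Response_reg"),
                                    list(tcs_role = "HHK", solo = solo))
t_hrr <- function() tpl(c("Response_reg", "HisKA", "HATPase_c"),
                        list(tcs_role = "HRR"))
t_rr <- function(output = "dna_binding", near_hk_if_cdgmp = NA) {
  if (output == "dna_binding") {
    tpl(c("Response_reg", "Trans_reg_C"),
        list(tcs_role = "RR", rr_output = "dna_binding"))
  } else if (output == "cdgmp_enzyme") {
    tpl(c("Response_reg", "GGDEF"),
        list(tcs_role = "RR", rr_output = "cdgmp_enzyme", is_cdgmp = TRUE,
             has_ggdef = TRUE, has_partner = TRUE, a_site = "active",
             i_site = "present", near_hk = near_hk_if_cdgmp),
        seq = list(a_site = "GGDEF", i_site = "present"))
  } else {
    tpl(c("Response_reg", "PAS"),
        list(tcs_role = "RR", rr_output = "other_unknown"))
  }
}
t_dgc <- function(a_site = "GGDEF", i_site = "present", partner = TRUE,
                  rec = FALSE, near_hk = NA) {
  doms <- c(if (rec) "Response_reg", if (partner && !rec) "PAS", "GGDEF")
  state <- if (a_site %in% c("GGDEF", "GGEEF", "SGDEF", "AGDEF")) "active" else "degenerate"
  tpl(doms, list(
    is_cdgmp = TRUE, has_ggdef = TRUE, has_partner = rec || partner,
    single_domain = !rec && !partner, a_site = state, i_site = i_site,
    near_hk = if (rec) near_hk else NA,
    tcs_role = if (rec) "RR" else "none",
    rr_output = if (rec) "cdgmp_enzyme" else NA_character_
  ), seq = list(a_site = a_site, i_site = i_site))
}
t_pde <- function(kind = "EAL", partner = TRUE) {
  doms <- c(if (partner) "PAS", kind)
  tpl(doms, list(is_cdgmp = TRUE, has_eal = kind == "EAL",
                 has_hdgyp = kind == "HD-GYP", has_partner = partner,
                 single_domain = !partner))
}
t_bifunctional <- function(a_site = "GGDEF") {
  state <- if (a_site %in% c("GGDEF", "GGEEF", "SGDEF", "AGDEF")) "active" else "degenerate"
  tpl(c("PAS", "GGDEF", "EAL"),
      list(is_cdgmp = TRUE, has_ggdef = TRUE, has_eal = TRUE,
           has_partner = TRUE, a_site = state, i_site = "present"),
      seq = list(a_site = a_site, i_site = "present"))
}
t_mcp <- function() tpl("MCPsignal", list(che = "MCP"))
t_chea <- function(rec = TRUE) {
  doms <- c("Hpt", "HATPase_c", if (rec) "Response_reg")
  tpl(doms, list(che = "CheA",
                 tcs_role = if (rec) "RR" else "none",
                 rr_output = if (rec) "other_unknown" else NA_character_))
}
t_chev <- function() tpl(c("CheW", "Response_reg"),
                         list(che = "CheV", tcs_role = "RR",
                              rr_output = "other_unknown"))
t_chew <- function() tpl("CheW", list(che = "CheW"))
t_cheb <- function(rec = TRUE) {
  doms <- c(if (rec) "Response_reg", "CheB_methylest")
  tpl(doms, list(che = "CheB",
                 tcs_role = if (rec) "RR" else "none",
                 rr_output = if (rec) "other_unknown" else NA_character_))
}
t_cher <- function() tpl("CheR", list(che = "CheR"))
t_ched <- function() tpl("CheD", list(che = "CheD"))
t_chey <- function() tpl("Response_reg",
                         list(che = "CheY", tcs_role = "RR",
                              rr_output = "other_unknown"))
t_stas <- function() tpl("STAS", list(che = "STAS", aux = "STAS"))
t_ecf <- function() tpl(c("Sigma70_r2", "Sigma70_r4_2"), list(aux = "ECF"))
t_ecf_negative <- function() tpl(c("Sigma70_r2", "Sigma70_r4_2", "PAS"), list())
t_sigma_partial <- function() tpl("Sigma70_r2", list())
t_fecr <- function() tpl("FecR", list())
t_tonb <- function() tpl("TonB_dep_Rec", list())
t_ac <- function() tpl(c("CHASE2", "Adenylate_cycl"), list(aux = "AC"))
t_camp_pde <- function() tpl("PDEase_I", list())
t_tpr <- function() tpl("TPR_1", list())
t_crp <- function() tpl("Crp", list(aux = "CRP_like"))
t_estyk <- function() tpl("Pkinase", list(aux = "eSTYK"))
t_pp2c <- function(sensor = FALSE) {
  tpl(c(if (sensor) "Cache_1", "PP2C"), list(aux = "PP2C"))
}
t_bif_pp2c_pk <- function(rec = FALSE) {
  doms <- c(if (rec) "Response_reg", "Pkinase", "PP2C")
  tpl(doms, list(aux = "bifunctional_PP2C_Pkinase",
                 tcs_role = if (rec) "RR" else "none",
                 rr_output = if (rec) "other_unknown" else NA_character_))
}
t_stas_styk <- function() tpl("HATPase_c_3", list(aux = "stas_STYK"))

che_templates <- function(token, class_name) {
  switch(token,
         A = t_chea(rec = class_name == "F3"),
         B = t_cheb(rec = class_name != "F3"),
         D = t_ched(), M = t_mcp(), R = t_cher(), S = t_stas(),
         V = t_chev(), W = t_chew(), Y = t_chey(),
         stop("no template for signature token ", token))
}

# ---- implant directives ----------------------------------------------------

#' @rdname synth_generate
#' @param type Directive type; see Details in the vignette. One of
#'   `tcs_pair`, `hhk`, `hrr`, `solo_hk`, `rr`, `dgc`, `pde`, `bifunctional`,
#'   `dgc_near_hk`, `che_cluster`, `orphan_mcp`, `ecf`, `ecf_negative`,
#'   `ecf242`, `camp_cluster`, `ac_alone`, `crp`, `styk`, `qs`, `combined`,
#'   `atypical_cluster`.
#' @param ... Directive parameters.
#' @export
synth_implant <- function(type, ...) c(list(type = type), list(...))

expand_implant <- function(d, signatures) {
  blk <- function(templates, truth = list()) list(list(templates = templates,
                                                       truth = truth))
  spacers <- function(k) replicate(k, list(domains = NULL, plen = 200L,
                                           truth = list()), simplify = FALSE)
  switch(d$type,
    tcs_pair = blk(list(t_hk(solo = FALSE), t_rr(d$output %||% "dna_binding",
                                                 near_hk_if_cdgmp = TRUE))),
    hhk = {
      dist <- d$rr_distance %||% Inf
      if (is.finite(dist)) {
        blk(c(list(t_hhk(solo = dist > 4)), spacers(dist),
              list(t_rr(d$output %||% "dna_binding"))))
      } else blk(list(t_hhk(solo = TRUE)))
    },
    hrr = blk(list(t_hrr())),
    solo_hk = {
      dist <- d$distance %||% 5
      if (is.finite(dist)) {
        blk(c(list(t_hk(solo = dist > 4)), spacers(dist),
              list(t_rr("dna_binding"))))
      } else blk(list(t_hk(solo = TRUE)))
    },
    rr = blk(list(t_rr(d$output %||% "dna_binding", near_hk_if_cdgmp = FALSE))),
    dgc = blk(list(t_dgc(d$a_site %||% "GGDEF", d$i_site %||% "present",
                         d$partner %||% TRUE, d$rec %||% FALSE,
                         near_hk = if (isTRUE(d$rec)) FALSE else NA))),
    dgc_near_hk = blk(list(t_dgc(d$a_site %||% "GGDEF", d$i_site %||% "present",
                                 partner = TRUE, rec = TRUE, near_hk = TRUE),
                           t_hk(solo = FALSE))),
    pde = blk(list(t_pde(d$kind %||% "EAL", d$partner %||% TRUE))),
    bifunctional = blk(list(t_bifunctional(d$a_site %||% "GGDEF"))),
    che_cluster = {
      cls <- d$class %||% "F3"
      sig <- signatures[[which(vapply(signatures, `[[`, "", "class_name") == cls)]]
      keep <- d$keep %||% sig$gene_order
      tpls <- lapply(keep, che_templates, class_name = cls)
      req_tok <- unname(vapply(sig$required_components,
                               function(c) che_token_map[[c]], ""))
      comp <- sum(req_tok %in% keep) / length(req_tok)
      status <- if (comp >= 1) "full" else if (comp >= 0.4 && comp < 0.8) "half"
                else if (comp > 0) "partial" else "none"
      out <- blk(tpls, truth = list(che_cluster = tibble::tibble(
        class = cls, status = status, completeness = comp)))
      if (cls == "F3") out <- c(out, blk(list(t_cheb(rec = FALSE))))
      out
    },
    orphan_mcp = {
      n <- d$n %||% 1
      unlist(replicate(n, blk(list(t_mcp())), simplify = FALSE),
             recursive = FALSE)
    },
    ecf = blk(list(t_ecf())),
    ecf_negative = blk(list(t_ecf_negative())),
    ecf242 = {
      copies <- d$copies %||% 1
      tpls <- unlist(replicate(copies, c(list(t_ecf(), t_fecr()),
                                         if (d$with_tonb %||% TRUE) list(t_tonb())),
                               simplify = FALSE), recursive = FALSE)
      blk(tpls, truth = list(n_ecf242 = copies))
    },
    camp_cluster = blk(list(t_ac(), t_camp_pde(), t_fecr(), t_tpr()),
                       truth = list(n_camp_clusters = 1L)),
    ac_alone = blk(list(t_ac())),
    crp = blk(list(t_crp())),
    styk = switch(d$kind %||% "eSTYK",
      eSTYK = blk(list(t_estyk(), t_pp2c())),
      bifunctional = blk(list(t_bif_pp2c_pk(rec = FALSE))),
      stas_styk = blk(list(t_stas_styk(), t_stas(), t_pp2c()))
    ),
    qs = {
      pw <- d$pathway %||% "AHL"
      both <- !identical(d$mode %||% "both", "synthase_only")
      qv <- default_qs_vocabulary()[[pw]]
      pick_name <- function(x) c(x[!grepl("^PF\\d", x)], x)[1]
      syn_dom <- pick_name(qv$synthase)
      rec_dom <- pick_name(qv$receptor)
      tpls <- c(list(tpl(syn_dom, list())),
                if (both) list(tpl(rec_dom, list())))
      blk(tpls, truth = list(qs = tibble::tibble(pathway = pw, present = both)))
    },
    combined = switch(d$rule,
      pp2c_styk_stas_cdgmp = blk(
        list(t_pp2c(sensor = TRUE), t_stas_styk(), t_stas(),
             t_dgc("GGDEF", "present", partner = TRUE)),
        truth = list(combined = tibble::tibble(rule = d$rule, n = 1L))),
      rec_pp2c_styk_mcp = blk(
        list(t_bif_pp2c_pk(rec = TRUE), t_stas(), t_mcp()),
        truth = list(combined = tibble::tibble(rule = d$rule, n = 1L))),
      ecf_partial_plus_cyclase = blk(
        list(t_sigma_partial(), t_ac()),
        truth = list(combined = tibble::tibble(rule = d$rule, n = 1L)))
    ),
    atypical_cluster = {
      n_sig <- d$n_signaling %||% 10
      n_atyp <- d$n_atypical %||% 2
      tpls <- list()
      for (i in seq_len(n_atyp)) tpls <- c(tpls, list(t_hhk(solo = FALSE),
                                                      t_rr("dna_binding")))
      while (length(tpls) + 2 <= n_sig) {
        tpls <- c(tpls, list(t_hk(solo = FALSE), t_rr("other_unknown")))
      }
      if (length(tpls) < n_sig) tpls <- c(tpls, list(t_dgc("GGDEF", "present")))
      blk(tpls, truth = list(atypical = tibble::tibble(
        n_signaling = length(tpls), n_atypical = n_atyp)))
    },
    stop("unknown implant type: ", d$type)
  )
}

# ---- sequences -------------------------------------------------------------

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_NO_F <- setdiff(AA, "F")
AA_NO_FR <- setdiff(AA, c("F", "R"))

make_dgc_sequence <- function(plen, ggdef_start, ggdef_end, a_site, i_site) {
  s <- sample(AA, plen, replace = TRUE)
  # no F inside the scanned domain except the implanted motif: rules out
  # accidental A-site anchors
  dom <- ggdef_start:ggdef_end
  s[dom] <- sample(AA_NO_F, length(dom), replace = TRUE)
  a_pos <- ggdef_start + 60L
  motif <- if (a_site %in% c("GGDEF", "GGEEF", "SGDEF", "AGDEF")) a_site
           else if (a_site == "degenerate") "GGDQF" else a_site
  s[a_pos:(a_pos + 4L)] <- strsplit(motif, "")[[1]]
  win <- (a_pos - 15L):(a_pos - 1L)
  s[win] <- sample(AA_NO_FR, length(win), replace = TRUE)
  if (identical(i_site, "present")) {
    s[a_pos - 6L] <- "R"
    s[a_pos - 3L] <- "D"
  }
  paste(s, collapse = "")
}

# ---- noise -----------------------------------------------------------------

#' Stochastic corruption of a domain table
#'
#' Independently drops each domain hit with probability `drop_domain_rate`
#' and, per protein, appends a decoy hit with probability `extra_decoy_rate`,
#' for measuring how classification recall degrades with annotation loss.
#'
#' @param domains Domain-hit tibble.
#' @param drop_domain_rate,extra_decoy_rate Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return A corrupted copy of `domains`.
#' @export
synth_perturb <- function(domains, drop_domain_rate = 0, extra_decoy_rate = 0,
                          seed = 1) {
  stopifnot(drop_domain_rate >= 0, drop_domain_rate <= 1,
            extra_decoy_rate >= 0, extra_decoy_rate <= 1)
  with_local_seed(seed, {
    keep <- stats::runif(nrow(domains)) >= drop_domain_rate
    out <- domains[keep, , drop = FALSE]
    if (extra_decoy_rate > 0) {
      prots <- unique(domains$protein_id)
      hit <- prots[stats::runif(length(prots)) < extra_decoy_rate]
      if (length(hit) > 0) {
        extra <- tibble::tibble(
          protein_id = hit,
          domain = sample(decoy_domains, length(hit), replace = TRUE),
          accession = NA_character_,
          env_start = 2000L, env_end = 2149L,
          evalue = 1e-10, bitscore = 60
        )
        out <- dplyr::bind_rows(out, extra)
      }
    }
    out
  })
}

#' Bare protein cohorts for noise experiments
#'
#' Emits a domain table and per-protein truth for `n_per_role` proteins of
#' each requested role, with no genome context -- the substrate for recall
#' measurements under [synth_perturb()].
#'
#' @param n_per_role Proteins per role.
#' @param roles Subset of `HK`, `HHK`, `HRR`, `RR`, `ECF`, `eSTYK`, `MCP`.
#' @param seed Integer seed.
#' @return List `domains`, `truth` (tibble `protein_id`, `role`,
#'   `n_required` -- the number of hits that must survive for the label to be
#'   retained).
#' @export
synth_protein_cohort <- function(n_per_role = 500,
                                 roles = c("HK", "HHK", "HRR", "RR", "ECF",
                                           "eSTYK", "MCP"),
                                 seed = 1) {
  makers <- list(HK = function() t_hk(), HHK = function() t_hhk(),
                 HRR = function() t_hrr(),
                 RR = function() tpl("Response_reg", list(tcs_role = "RR")),
                 ECF = function() t_ecf(), eSTYK = function() t_estyk(),
                 MCP = function() t_mcp())
  n_req <- c(HK = 2L, HHK = 3L, HRR = 3L, RR = 1L, ECF = 2L, eSTYK = 1L,
             MCP = 1L)
  with_local_seed(seed, {
    rows <- list(); truth <- list(); counter <- 0L
    for (r in roles) {
      t <- makers[[r]]()
      k <- length(t$domains$domain)
      pid <- sprintf("noise_p%06d", counter + seq_len(n_per_role))
      counter <- counter + n_per_role
      rows[[r]] <- tibble::tibble(
        protein_id = rep(pid, each = k),
        domain = rep(t$domains$domain, times = n_per_role),
        accession = NA_character_,
        env_start = rep(as.integer(t$domains$start), times = n_per_role),
        env_end = rep(as.integer(t$domains$end), times = n_per_role),
        evalue = 1e-20, bitscore = 100)
      truth[[r]] <- tibble::tibble(protein_id = pid, role = r,
                                   n_required = n_req[[r]])
    }
    list(domains = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}

# ---- fixtures --------------------------------------------------------------

#' Ecotype archetype fixtures
#'
#' Three synthetic genomes echoing the qualitative census patterns of the
#' three ecological strata: a hydrothermal-vent specialist (conserved F3
#' chemosensory class, modest TCS count, a c-di-GMP enzyme complement larger
#' than its kinase count), a free-living generalist (multiple chemosensory
#' classes, many kinases including hybrid HHK/HRR genes and atypical-kinase
#' clusters, ECF/cAMP/STYK systems), and a host-associated specialist (F3
#' only, a handful of classical TCS pairs, no active diguanylate cyclase, a
#' CRP homolog without a cyclase).
#'
#' @param ecotype One of `vent_specialist`, `generalist`, `host_associated`.
#' @param seed Integer seed.
#' @return A [synth_generate()] result.
#' @export
synth_archetype <- function(ecotype = c("vent_specialist", "generalist",
                                        "host_associated"), seed = 1) {
  ecotype <- match.arg(ecotype)
  imp <- switch(ecotype,
    vent_specialist = c(
      list(synth_implant("che_cluster", class = "F3"),
           synth_implant("orphan_mcp", n = 12)),
      replicate(8, synth_implant("tcs_pair"), simplify = FALSE),
      replicate(8, synth_implant("dgc"), simplify = FALSE),
      replicate(2, synth_implant("dgc", a_site = "SGDEF"), simplify = FALSE),
      list(synth_implant("dgc", a_site = "degenerate", i_site = "absent")),
      replicate(2, synth_implant("pde", kind = "EAL"), simplify = FALSE),
      replicate(2, synth_implant("pde", kind = "HD-GYP"), simplify = FALSE),
      replicate(2, synth_implant("bifunctional"), simplify = FALSE),
      list(synth_implant("dgc", partner = FALSE),
           synth_implant("pde", kind = "EAL", partner = FALSE),
           synth_implant("dgc_near_hk"))
    ),
    generalist = c(
      list(synth_implant("che_cluster", class = "F3"),
           synth_implant("che_cluster", class = "F7"),
           synth_implant("orphan_mcp", n = 10)),
      replicate(14, synth_implant("tcs_pair"), simplify = FALSE),
      replicate(3, synth_implant("tcs_pair", output = "other_unknown"),
                simplify = FALSE),
      replicate(2, synth_implant("hhk", rr_distance = 2), simplify = FALSE),
      replicate(2, synth_implant("hhk"), simplify = FALSE),
      replicate(2, synth_implant("hrr"), simplify = FALSE),
      list(synth_implant("solo_hk", distance = 6),
           synth_implant("atypical_cluster", n_signaling = 12, n_atypical = 3),
           synth_implant("atypical_cluster", n_signaling = 8, n_atypical = 2)),
      replicate(10, synth_implant("dgc"), simplify = FALSE),
      replicate(2, synth_implant("rr", output = "cdgmp_enzyme"), simplify = FALSE),
      replicate(4, synth_implant("pde", kind = "EAL"), simplify = FALSE),
      replicate(2, synth_implant("pde", kind = "HD-GYP"), simplify = FALSE),
      replicate(2, synth_implant("bifunctional"), simplify = FALSE),
      list(synth_implant("ecf242", copies = 2),
           synth_implant("ecf"),
           synth_implant("camp_cluster"),
           synth_implant("crp"),
           synth_implant("styk", kind = "eSTYK"),
           synth_implant("styk", kind = "stas_styk"),
           synth_implant("combined", rule = "pp2c_styk_stas_cdgmp"))
    ),
    host_associated = c(
      list(synth_implant("che_cluster", class = "F3"),
           synth_implant("orphan_mcp", n = 4)),
      replicate(5, synth_implant("tcs_pair"), simplify = FALSE),
      replicate(2, synth_implant("dgc", a_site = "degenerate",
                                 i_site = "absent"), simplify = FALSE),
      list(synth_implant("crp"))
    )
  )
  n_genes <- switch(ecotype, vent_specialist = 420, generalist = 800,
                    host_associated = 200)
  synth_generate(seed = seed, n_genes = n_genes, implants = imp,
                 genome_id = paste0("synth_", ecotype), ecotype = ecotype)
}

#' A randomized synthetic cohort
#'
#' Generates `n_genomes` genomes whose implant composition is drawn from the
#' full directive menu (every genome carries an F3 cluster; TCS, c-di-GMP,
#' chemosensory, ECF, cAMP, STYK, QS and combined-pathway features are drawn
#' with seeded randomness), for whole-pipeline recovery experiments.
#'
#' @param n_genomes Number of genomes.
#' @param n_genes Genes per genome.
#' @param seed Integer seed.
#' @return List of [synth_generate()] results.
#' @export
synth_cohort <- function(n_genomes = 30, n_genes = 1500, seed = 1) {
  seeds <- seed + seq_len(n_genomes) * 1000L
  lapply(seq_len(n_genomes), function(i) {
    with_local_seed(seeds[i] + 1L, {
      ri <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1) - 1L
      imp <- c(
        list(synth_implant("che_cluster", class = "F3"),
             synth_implant("orphan_mcp", n = ri(2, 12))),
        replicate(ri(4, 12), synth_implant("tcs_pair"), simplify = FALSE),
        replicate(ri(0, 3), synth_implant("tcs_pair", output = "other_unknown"),
                  simplify = FALSE),
        replicate(ri(0, 3), synth_implant("hhk", rr_distance = ri(1, 3)),
                  simplify = FALSE),
        replicate(ri(0, 2), synth_implant("hhk"), simplify = FALSE),
        replicate(ri(0, 2), synth_implant("hrr"), simplify = FALSE),
        list(synth_implant("solo_hk", distance = ri(5, 7))),
        replicate(ri(1, 8), synth_implant("dgc"), simplify = FALSE),
        replicate(ri(0, 2), synth_implant("dgc", a_site = "degenerate",
                                          i_site = "absent"), simplify = FALSE),
        replicate(ri(0, 3), synth_implant("pde", kind = "EAL"), simplify = FALSE),
        replicate(ri(0, 2), synth_implant("pde", kind = "HD-GYP"),
                  simplify = FALSE),
        replicate(ri(0, 2), synth_implant("bifunctional"), simplify = FALSE),
        if (i %% 2 == 0) list(synth_implant("che_cluster", class = "F7")),
        if (i %% 3 == 0) list(synth_implant("che_cluster", class = "F9",
                                            keep = c("M", "W", "B", "R"))),
        if (i %% 4 == 0) list(synth_implant("che_cluster", class = "F14")),
        if (i %% 2 == 1) list(synth_implant("ecf242", copies = ri(1, 2))),
        if (i %% 3 == 1) list(synth_implant("ecf"),
                              synth_implant("ecf_negative")),
        if (i %% 3 == 2) list(synth_implant("camp_cluster")),
        if (i %% 4 == 1) list(synth_implant("ac_alone")),
        if (i %% 2 == 0) list(synth_implant("crp")),
        if (i %% 3 == 0) list(synth_implant("styk", kind = "eSTYK")),
        if (i %% 4 == 2) list(synth_implant("styk", kind = "bifunctional")),
        if (i %% 3 == 1) list(synth_implant("styk", kind = "stas_styk")),
        if (i %% 5 == 0) list(synth_implant("qs", pathway = "AHL")),
        if (i %% 5 == 2) list(synth_implant("qs", pathway = "AI2",
                                            mode = "synthase_only")),
        if (i %% 4 == 3) list(synth_implant("combined",
                                            rule = "pp2c_styk_stas_cdgmp")),
        if (i %% 5 == 1) list(synth_implant("combined",
                                            rule = "rec_pp2c_styk_mcp")),
        if (i %% 5 == 4) list(synth_implant("combined",
                                            rule = "ecf_partial_plus_cyclase")),
        if (i %% 6 == 0) list(synth_implant("atypical_cluster",
                                            n_signaling = ri(6, 14),
                                            n_atypical = ri(2, 4))),
        list(synth_implant("dgc_near_hk"))
      )
      imp <- imp[!vapply(imp, is.null, logical(1))]
      imp
    }) -> implants
    synth_generate(seed = seeds[i], n_genes = n_genes, implants = implants,
                   genome_id = sprintf("synthC%02d", i),
                   ecotype = c("vent_specialist", "generalist",
                               "host_associated")[(i %% 3) + 1])
  })
}
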