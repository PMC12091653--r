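#' Proteome scan: SMR + HEIDI + FDR + colocalization per protein
#'
#' For each protein: locate the top cis-pQTL, run the SMR and HEIDI tests,
#' apply Benjamini-Hochberg correction across the scan, and run Bayesian
#' colocalization on the FDR-passing proteins' cis regions. A protein passes
#' when its BH-adjusted SMR p-value is below the FDR level AND HEIDI does not
#' reject (p >= 0.01); colocalization is labelled strong at PPH4 > 0.6.
#' Proteins failing I/O or instrument lookup are skipped with a logged
#' reason; the scan continues.
#'
#' @param proteins named list of pQTL [summary_table()]s.
#' @param gwas outcome [summary_table()].
#' @param ld `ld_matrix` or [reference_panel()].
#' @param gene_pos data frame with `protein_id`, `chrom`, `pos` giving each
#'   encoded gene's location.
#' @param config a [medmr_config()].
#' @return List with `smr` (one row per protein: b_xy, se, p_smr, p_heidi,
#'   fdr-adjusted p, pass flag, status) and `coloc` (rows for FDR-passing
#'   proteins).
#' @export
run_protein_scan <- function(proteins, gwas, ld, gene_pos,
                             config = medmr_config()) {
  empty_smr <- data.frame(protein_id = character(0), top_snp = character(0),
                          b_xy = numeric(0), se_xy = numeric(0),
                          p_smr = numeric(0), p_heidi = numeric(0),
                          n_heidi_snps = integer(0), p_fdr = numeric(0),
                          passes = logical(0), status = character(0),
                          stringsAsFactors = FALSE)
  if (length(proteins) == 0) return(list(smr = empty_smr, coloc = NULL))
  rows <- list()
  fits <- list()
  for (pid in names(proteins)) {
    gp <- gene_pos[gene_pos$protein_id == pid, ]
    if (nrow(gp) == 0) {
      msg("protein %s: no gene position; skipped", pid)
      rows[[pid]] <- data.frame(protein_id = pid, top_snp = NA_character_,
                                b_xy = NA_real_, se_xy = NA_real_,
                                p_smr = NA_real_, p_heidi = NA_real_,
                                n_heidi_snps = NA_integer_, p_fdr = NA_real_,
                                passes = FALSE, status = "no_gene_position",
                                stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(
      smr(proteins[[pid]], gwas, gp$chrom[1], gp$pos[1], ld, config),
      error = function(e) {
        msg("protein %s: %s; skipped", pid, conditionMessage(e))
        NULL
      })
    if (is.null(fit) || fit$status != "ok") {
      rows[[pid]] <- data.frame(protein_id = pid, top_snp = NA_character_,
                                b_xy = NA_real_, se_xy = NA_real_,
                                p_smr = NA_real_, p_heidi = NA_real_,
                                n_heidi_snps = NA_integer_, p_fdr = NA_real_,
                                passes = FALSE,
                                status = if (is.null(fit)) "error" else fit$status,
                                stringsAsFactors = FALSE)
      next
    }
    fits[[pid]] <- fit
    rows[[pid]] <- data.frame(protein_id = pid, top_snp = fit$top_snp,
                              b_xy = fit$b_xy, se_xy = fit$se_xy,
                              p_smr = fit$p_smr, p_heidi = fit$p_heidi,
                              n_heidi_snps = fit$n_heidi_snps,
                              p_fdr = NA_real_, passes = FALSE, status = "ok",
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$status == "ok"
  if (any(ok)) {
    adj <- bh_fdr(out$p_smr[ok], alpha = config$fdr_alpha)
    out$p_fdr[ok] <- adj$adjusted
    out$passes[ok] <- adj$significant &
      (is.na(out$p_heidi[ok]) | out$p_heidi[ok] >= config$heidi_alpha)
    # HEIDI-undefined proteins cannot be cleared of linkage; do not pass them
    out$passes[ok][is.na(out$p_heidi[ok])] <- FALSE
  }
  coloc_rows <- NULL
  for (pid in out$protein_id[out$passes]) {
    gp <- gene_pos[gene_pos$protein_id == pid, ]
    ptab <- proteins[[pid]]
    region <- as.data.frame(ptab)
    region <- region[region$chrom == as.character(gp$chrom[1]) &
                       abs(region$pos - gp$pos[1]) <= config$cis_window_kb * 1000, ]
    cl <- tryCatch(
      coloc_abf(summary_table(region, attr(ptab, "trait_id") %||% pid,
                              attr(ptab, "trait_type") %||% "quantitative",
                              check_pz = FALSE),
                gwas,
                priors = coloc_priors(config$coloc_p1, config$coloc_p2,
                                      config$coloc_p12),
                prior_sd1 = config$coloc_sd_quant,
                prior_sd2 = config$coloc_sd_binary),
      error = function(e) {
        msg("protein %s coloc: %s; skipped", pid, conditionMessage(e))
        NULL
      })
    if (!is.null(cl))
      coloc_rows <- rbind(coloc_rows,
                          data.frame(protein_id = pid, n_snps = cl$n_snps,
                                     pph0 = cl$pph0, pph1 = cl$pph1,
                                     pph2 = cl$pph2, pph3 = cl$pph3,
                                     pph4 = cl$pph4, strong = cl$strong,
                                     stringsAsFactors = FALSE))
  }
  list(smr = out, coloc = coloc_rows, fits = fits)
}

#' Exposure scan: five MR methods per lipid species
#'
#' For each lipid: select instruments at the relaxed lipid threshold, fit the
#' IVW estimate plus the four sensitivity methods, and flag nominal IVW
#' p < 0.05 (no multiplicity correction by default; set `fdr = TRUE` to add
#' BH-adjusted flags alongside).
#'
#' @param lipids named list of lipid [summary_table()]s.
#' @param gwas outcome [summary_table()].
#' @param ld `ld_matrix` or [reference_panel()].
#' @param config a [medmr_config()].
#' @param fdr also compute BH-adjusted flags across lipids (default FALSE).
#' @return Data frame, one row per (lipid, method), with `n_snp`, estimates,
#'   Q, Egger intercept columns, `flag` (IVW rows only) and `status`.
#' @export
run_lipid_scan <- function(lipids, gwas, ld, config = medmr_config(),
                           fdr = FALSE) {
  rows <- list()
  for (lid in names(lipids)) {
    iv <- tryCatch(
      select_instruments(lipids[[lid]], gwas, ld,
                         p_threshold = config$p_threshold_lipid,
                         r2_threshold = config$clump_r2,
                         window_kb = config$clump_window_kb,
                         f_min = config$f_min,
                         palindrome_window = config$palindrome_window,
                         max_af_diff = config$max_af_diff),
      error = function(e) {
        msg("lipid %s: %s; skipped", lid, conditionMessage(e)); NULL
      })
    if (is.null(iv) || iv$status != "ok") {
      rows[[lid]] <- data.frame(exposure_id = lid, method = NA_character_,
                                n_snp = 0L, beta = NA_real_, se = NA_real_,
                                pval = NA_real_, or = NA_real_,
                                or_lo = NA_real_, or_hi = NA_real_,
                                q = NA_real_, q_pval = NA_real_,
                                egger_intercept = NA_real_,
                                intercept_pval = NA_real_,
                                status = "non_estimable",
                                stringsAsFactors = FALSE)
      next
    }
    fit <- mr(iv, ivw_mode = config$ivw_mode, n_boot = config$n_boot,
              seed = config$boot_seed)
    est <- fit$estimates
    rows[[lid]] <- data.frame(exposure_id = lid, method = est$method,
                              n_snp = est$n_snp, beta = est$beta, se = est$se,
                              pval = est$pval, or = est$or, or_lo = est$or_lo,
                              or_hi = est$or_hi, q = est$q, q_pval = est$q_pval,
                              egger_intercept = est$egger_intercept,
                              intercept_pval = est$intercept_pval,
                              status = "ok", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # primary estimate per lipid = first IVW (or Wald, single-instrument) row
  cand <- which(out$method %in% c("ivw_mre", "ivw_fixed", "wald"))
  is_primary <- rep(FALSE, nrow(out))
  is_primary[cand[!duplicated(out$exposure_id[cand])]] <- TRUE
  out$flag <- NA
  out$flag[is_primary] <- out$pval[is_primary] < 0.05
  if (fdr && any(is_primary)) {
    out$p_fdr <- NA_real_
    adj <- bh_fdr(out$pval[is_primary], alpha = config$fdr_alpha)
    out$p_fdr[is_primary] <- adj$adjusted
  }
  out
}

#' Bidirectional MR between lipid species and proteins
#'
#' Forward (lipid -> protein) analyses use the relaxed lipid instrument
#' threshold (1e-5); reverse (protein -> lipid) analyses the stringent
#' proteome-wide threshold (5e-8). The direction is recorded per row.
#'
#' @param lipids,proteins named lists of [summary_table()]s.
#' @param ld `ld_matrix` or [reference_panel()].
#' @param config a [medmr_config()].
#' @param pairs optional data frame (`lipid_id`, `protein_id`) restricting
#'   the scan; default: all pairs.
#' @return Data frame as in [run_lipid_scan()] plus `direction`,
#'   `outcome_id`.
#' @export
run_bidirectional <- function(lipids, proteins, ld, config = medmr_config(),
                              pairs = NULL) {
  if (is.null(pairs))
    pairs <- expand.grid(lipid_id = names(lipids), protein_id = names(proteins),
                         stringsAsFactors = FALSE)
  if (nrow(pairs) == 0)
    return(data.frame())
  rows <- list()
  one <- function(exp_tab, out_tab, p_thr, direction, eid, oid) {
    iv <- tryCatch(
      select_instruments(exp_tab, out_tab, ld, p_threshold = p_thr,
                         r2_threshold = config$clump_r2,
                         window_kb = config$clump_window_kb,
                         f_min = config$f_min),
      error = function(e) NULL)
    if (is.null(iv) || iv$status != "ok")
      return(data.frame(direction = direction, exposure_id = eid,
                        outcome_id = oid, method = NA_character_, n_snp = 0L,
                        beta = NA_real_, se = NA_real_, pval = NA_real_,
                        status = "non_estimable", stringsAsFactors = FALSE))
    fit <- mr(iv, ivw_mode = config$ivw_mode, n_boot = config$n_boot,
              seed = config$boot_seed)
    est <- fit$estimates
    data.frame(direction = direction, exposure_id = eid, outcome_id = oid,
               method = est$method, n_snp = est$n_snp, beta = est$beta,
               se = est$se, pval = est$pval, status = "ok",
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pairs))) {
    lid <- pairs$lipid_id[i]; pid <- pairs$protein_id[i]
    rows[[paste0("f", i)]] <- one(lipids[[lid]], proteins[[pid]],
                                  config$p_threshold_lipid,
                                  "lipid_to_protein", lid, pid)
    rows[[paste0("r", i)]] <- one(proteins[[pid]], lipids[[lid]],
                                  config$p_threshold_protein,
                                  "protein_to_lipid", pid, lid)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble mediation results from leg estimates
#'
#' Builds the final mediation report from per-leg effect estimates (one row
#' per pathway: total effect, direct effect A, direct effect B, each with
#' SEs). Pathways whose mediation effect disagrees in sign with the total
#' effect are annotated as violating the additive mediation assumption.
#'
#' @param legs data frame with columns `pathway`, `total`, `se_total`, `a`,
#'   `se_a`, `b`, `se_b`.
#' @param raw pass `raw = TRUE` to skip report-time rounding.
#' @return A data frame (see [mediation_table()]); the underlying
#'   `mediation_result` objects are attached as attribute `"results"`.
#' @export
run_mediation <- function(legs, raw = FALSE) {
  need <- c("pathway", "total", "se_total", "a", "se_a", "b", "se_b")
  missing_cols <- setdiff(need, names(legs))
  if (length(missing_cols))
    stop("legs is missing column(s): ", paste(missing_cols, collapse = ", "))
  results <- lapply(seq_len(nrow(legs)), function(i) {
    row <- legs[i, ]
    if (anyNA(row[c("total", "se_total", "a", "se_a", "b", "se_b")]))
      return(structure(list(pathway_id = row$pathway, estimable = FALSE,
                            note = "missing leg estimate"),
                       class = "mediation_result"))
    mediation(row$total, row$se_total, row$a, row$se_a, row$b, row$se_b,
              pathway_id = row$pathway)
  })
  tab <- mediation_table(results, raw = raw)
  attr(tab, "results") <- results
  tab
}

#' Run the full scan pipeline on a simulated or provided study
#'
#' Convenience orchestration: lipid scan, protein scan, bidirectional MR and
#' the two-step mediation for the focal pathway, writing reports (TSV + JSON,
#' headers carrying seed, config hash and package version) when `out_dir` is
#' given.
#'
#' @param study a `simulated_study` (or a list with the same shape: `panel`,
#'   `tables$exposure`, `tables$mediator`, `tables$outcome`).
#' @param config a [medmr_config()].
#' @param gene_pos optional gene-position data frame for the protein scan;
#'   default: position of the mediator's strongest variant.
#' @param out_dir optional output directory.
#' @return List with `lipid_scan`, `protein_scan`, `bidirectional`,
#'   `mediation`.
#' @export
run_scan <- function(study, config = medmr_config(), gene_pos = NULL,
                     out_dir = NULL) {
  tabs <- study$tables
  if (is.null(gene_pos)) {
    med <- as.data.frame(tabs$mediator)
    top <- med[which.min(med$pval), ]
    gene_pos <- data.frame(protein_id = "mediator", chrom = top$chrom,
                           pos = top$pos, stringsAsFactors = FALSE)
  }
  lipid_scan <- run_lipid_scan(list(exposure = tabs$exposure), tabs$outcome,
                               study$panel, config)
  protein_scan <- run_protein_scan(list(mediator = tabs$mediator),
                                   tabs$outcome, study$panel, gene_pos, config)
  bidir <- run_bidirectional(list(exposure = tabs$exposure),
                             list(mediator = tabs$mediator), study$panel, config)
  med_fit <- two_step(tabs$exposure, tabs$mediator, tabs$outcome, study$panel,
                      config)
  out <- list(lipid_scan = lipid_scan, protein_scan = protein_scan$smr,
              coloc = protein_scan$coloc,
              mediation = mediation_table(list(med_fit)),
              mediation_fit = med_fit)
  if (!is.null(out_dir)) {
    header <- list(package = paste("medmr", as.character(utils::packageVersion("medmr"))),
                   seed = study$scenario$seed %||% NA,
                   config_hash = config_hash(unclass(config)))
    keep <- Filter(Negate(is.null), out[c("lipid_scan", "protein_scan",
                                          "coloc", "mediation")])
    write_report(keep, out_dir, header = header)
  }
  out
}
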