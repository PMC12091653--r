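#' Top cis-QTL lookup
#'
#' The single strongest variant within an inclusive window around the gene
#' (default +/- 1000 kb) passing the QTL significance threshold; ties in
#' p-value are broken by smaller position, then id. This variant serves as
#' the SMR instrument for its protein.
#'
#' @param pqtl a [summary_table()] of QTL associations for one protein.
#' @param gene_chrom,gene_pos gene location (chromosome and bp).
#' @param window_kb cis window half-width in kb, default 1000.
#' @param p_max significance ceiling, default 5e-8 (retain `pval <=`).
#' @return One-row data frame (the top record), or `NULL` if no variant
#'   passes (a no-instrument condition for that protein, reported by the
#'   caller, not an error).
#' @export
top_cis_qtl <- function(pqtl, gene_chrom, gene_pos, window_kb = 1000,
                        p_max = 5e-8) {
  d <- as.data.frame(pqtl)
  d <- d[d$chrom == as.character(gene_chrom) &
           abs(d$pos - gene_pos) <= window_kb * 1000 &
           d$pval <= p_max, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  d[order(d$pval, d$pos, d$variant_id)[1], , drop = FALSE]
}

#' SMR test of a molecular trait against a disease GWAS
#'
#' Summary-data-based MR with a single instrument: the causal-effect estimate
#' is the ratio of GWAS to QTL effects at the top cis-QTL, and its test
#' statistic combines the two z-scores as
#' `T = z_gwas^2 z_qtl^2 / (z_gwas^2 + z_qtl^2)`, referred to a chi-square
#' with 1 df. The SE is `|b_xy| sqrt(1/z_gwas^2 + 1/z_qtl^2)`.
#'
#' @param z_qtl,z_gwas z-scores (`beta/se`) in the QTL study and the GWAS.
#' @param beta_qtl,beta_gwas the corresponding effect sizes.
#' @return List with `b_xy`, `se_xy`, `t_smr`, `p_smr`.
#' @examples
#' smr_test(z_qtl = 10, z_gwas = 3, beta_qtl = 0.5, beta_gwas = 0.15)
#' @export
smr_test <- function(z_qtl, z_gwas, beta_qtl, beta_gwas) {
  if (z_qtl == 0) stop("z_qtl must be nonzero")
  b_xy <- beta_gwas / beta_qtl
  denom <- z_gwas^2 + z_qtl^2
  t_smr <- if (denom == 0) 0 else z_gwas^2 * z_qtl^2 / denom
  p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  se_xy <- if (z_gwas == 0) abs(b_xy / z_qtl) * sqrt(1 + z_qtl^2) # degenerate guard
  else abs(b_xy) * sqrt(1 / z_gwas^2 + 1 / z_qtl^2)
  list(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr, p_smr = p_smr)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (SMR estimates agree across
#' the LD region) from linkage of distinct causal variants (they do not).
#' Eligible variants are those with QTL `pval` below `p_eligible`, LD
#' r-squared with the top variant strictly inside `r2_range`, capped at
#' `max_snps` by descending |z_qtl|; at least `min_snps` are required,
#' otherwise the test is undefined and the reason recorded. For each eligible
#' variant the deviation `d_i = b_xy(i) - b_xy(top)` is formed; its covariance
#' matrix follows from the LD correlations and per-variant SEs by first-order
#' propagation, and the statistic `T = sum(z_d^2)` is referred to a
#' Satterthwaite scaled chi-square matching the mean and variance of the
#' correlated quadratic form (an eigenvalue-free tail approximation, adequate
#' at the 0.01 decision threshold).
#'
#' @param pqtl,gwas [summary_table()]s sharing the region's variants.
#' @param top_id variant id of the top cis-QTL.
#' @param ld `ld_matrix` or [reference_panel()] covering the region.
#' @param p_eligible QTL p-value ceiling for eligible variants (1.57e-3,
#'   i.e. a z of about 3.16).
#' @param r2_range open interval of r-squared with the top variant, default
#'   (0.05, 0.9).
#' @param max_snps,min_snps cap (20) and floor (3) on eligible variants.
#' @return List with `p_heidi` (`NA` when undefined), `n_snps`, `t_heidi`,
#'   `reason`.
#' @export
heidi_test <- function(pqtl, gwas, top_id, ld, p_eligible = 1.57e-3,
                       r2_range = c(0.05, 0.9), max_snps = 20, min_snps = 3) {
  q <- as.data.frame(pqtl)
  g <- as.data.frame(gwas)
  shared <- intersect(q$variant_id, g$variant_id)
  if (!top_id %in% shared) stop("top variant absent from one of the tables")
  ld <- resolve_ld(ld, intersect(shared, colnames(if (inherits(ld, "reference_panel")) ld$dosages else ld)))
  shared <- intersect(shared, colnames(ld))
  q <- q[match(shared, q$variant_id), ]
  g <- g[match(shared, g$variant_id), ]
  zq <- q$beta / q$se
  r_top <- unclass(ld)[, top_id][shared]
  elig <- shared != top_id & q$pval <= p_eligible &
    r_top^2 > r2_range[1] & r_top^2 < r2_range[2]
  idx <- which(elig)
  if (length(idx) > max_snps) idx <- idx[order(-abs(zq[idx]))[seq_len(max_snps)]]
  if (length(idx) < min_snps)
    return(list(p_heidi = NA_real_, n_snps = length(idx), t_heidi = NA_real_,
                reason = sprintf("only %d eligible SNP(s), need %d",
                                 length(idx), min_snps)))
  sel <- c(which(shared == top_id), idx)     # top first
  bx <- q$beta[sel]; sx <- q$se[sel]
  by <- g$beta[sel]; sy <- g$se[sel]
  R <- unclass(ld)[shared[sel], shared[sel]]
  b_xy <- by / bx
  m <- length(sel) - 1L

  # cov(b_xy_i, b_xy_j) by first-order propagation: gradient (1/bx, -by/bx^2)
  # wrt (by, bx); GWAS and QTL effect estimates are correlated across SNPs
  # with the LD correlation, independent between the two studies.
  cov_b <- outer(1 / bx, 1 / bx) * R * outer(sy, sy) +
    outer(by / bx^2, by / bx^2) * R * outer(sx, sx)
  # d_i = b_xy_{i} - b_xy_{top}; i = 2..m+1
  J <- cbind(-1, diag(m))                    # maps b_xy vector to d
  cov_d <- J %*% cov_b %*% t(J)
  d <- b_xy[-1] - b_xy[1]
  sd_d <- sqrt(diag(cov_d))
  z_d <- d / sd_d
  t_heidi <- sum(z_d^2)
  C <- cov_d / outer(sd_d, sd_d)             # correlation of d
  mu <- m
  v <- 2 * sum(C^2)
  scale <- v / (2 * mu)
  df <- 2 * mu^2 / v
  p <- stats::pchisq(t_heidi / scale, df = df, lower.tail = FALSE)
  list(p_heidi = p, n_snps = m, t_heidi = t_heidi, reason = NA_character_)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]) with significance
#' flags at the requested FDR level.
#'
#' @param pvals p-values in (0, 1].
#' @param alpha FDR level, default 0.05.
#' @return List with `adjusted` and logical `significant`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) stop("empty p-value list")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, significant = adj < alpha)
}

#' SMR + HEIDI for one protein
#'
#' Convenience wrapper: find the top cis-QTL, harmonize the GWAS record to
#' the QTL's effect allele, run the SMR test there and the HEIDI test over
#' the surrounding region.
#'
#' @param pqtl,gwas [summary_table()]s (protein QTL scan and disease GWAS).
#' @param gene_chrom,gene_pos gene location.
#' @param ld `ld_matrix` or [reference_panel()] covering the cis region.
#' @param config a [medmr_config()].
#' @return An object of class `smr_fit`: list with `protein_id`, `top_snp`,
#'   `b_xy`, `se_xy`, `p_smr`, `p_heidi`, `n_heidi_snps`, `status`.
#' @export
smr <- function(pqtl, gwas, gene_chrom, gene_pos, ld, config = medmr_config()) {
  protein_id <- attr(pqtl, "trait_id") %||% "protein"
  h <- harmonize(pqtl, gwas, palindrome_window = config$palindrome_window,
                 max_af_diff = config$max_af_diff)
  kept <- h[h$status == "kept", , drop = FALSE]
  if (nrow(kept) == 0)
    return(structure(list(protein_id = protein_id, status = "no_shared_variants"),
                     class = "smr_fit"))
  # rebuild aligned region tables from the harmonized pairs
  qtab <- data.frame(variant_id = kept$variant_id, chrom = kept$chrom,
                     pos = kept$pos, beta = kept$beta_exp, se = kept$se_exp,
                     pval = kept$pval_exp)
  gtab <- data.frame(variant_id = kept$variant_id, chrom = kept$chrom,
                     pos = kept$pos, beta = kept$beta_out, se = kept$se_out,
                     pval = kept$pval_out)
  top <- top_cis_qtl(qtab, gene_chrom, gene_pos,
                     window_kb = config$cis_window_kb,
                     p_max = config$p_threshold_protein)
  if (is.null(top))
    return(structure(list(protein_id = protein_id, status = "no_cis_instrument"),
                     class = "smr_fit"))
  grec <- gtab[gtab$variant_id == top$variant_id, ]
  st <- smr_test(z_qtl = top$beta / top$se, z_gwas = grec$beta / grec$se,
                 beta_qtl = top$beta, beta_gwas = grec$beta)
  ids_in_ld <- intersect(qtab$variant_id,
                         colnames(if (inherits(ld, "reference_panel")) ld$dosages else ld))
  hd <- heidi_test(qtab[qtab$variant_id %in% ids_in_ld, ],
                   gtab[gtab$variant_id %in% ids_in_ld, ],
                   top$variant_id, ld,
                   p_eligible = config$heidi_p_eligible,
                   r2_range = config$heidi_r2_range,
                   max_snps = config$heidi_max_snps,
                   min_snps = config$heidi_min_snps)
  structure(list(protein_id = protein_id, top_snp = top$variant_id,
                 b_xy = st$b_xy, se_xy = st$se_xy, t_smr = st$t_smr,
                 p_smr = st$p_smr, p_heidi = hd$p_heidi,
                 n_heidi_snps = hd$n_snps, heidi_reason = hd$reason,
                 status = "ok"),
            class = "smr_fit")
}

#' @export
print.smr_fit <- function(x, ...) {
  cat(sprintf("SMR fit: %s [%s]\n", x$protein_id, x$status))
  if (x$status == "ok") {
    cat(sprintf("  top cis-QTL %s: b_xy = %.4f (se %.4f), p_smr = %.3g\n",
                x$top_snp, x$b_xy, x$se_xy, x$p_smr))
    if (is.na(x$p_heidi))
      cat(sprintf("  HEIDI undefined (%s)\n", x$heidi_reason))
    else
      cat(sprintf("  HEIDI p = %.3g over %d SNP(s)\n", x$p_heidi, x$n_heidi_snps))
  }
  invisible(x)
}
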