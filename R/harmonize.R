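#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Variants shared by id are aligned so that both traits report the effect of
#' the same allele. When the outcome's alleles are swapped relative to the
#' exposure, the outcome beta is negated and its effect-allele frequency
#' reflected (`1 - eaf`). Palindromic variants (A/T or C/G single-base pairs,
#' whose strand cannot be resolved from alleles alone) are kept only when both
#' allele frequencies are present and both fall outside the ambiguity window;
#' they are then aligned by frequency (if the frequencies sit on opposite
#' sides of 0.5, the outcome is treated as strand-flipped). Indel alleles
#' (length > 1) never enter palindrome logic. Finally, kept pairs with an
#' allele-frequency difference above `max_af_diff` are dropped as discordant.
#'
#' @param exp,out [summary_table()] objects for exposure and outcome.
#' @param palindrome_window ambiguity window on eaf, default `c(0.42, 0.58)`.
#' @param max_af_diff maximum tolerated |eaf_exp - eaf_out|, default 0.2.
#' @return A data frame of class `harmonized_pairs`, one row per shared
#'   variant, with exposure/outcome effects, a `flipped` flag and a `status`
#'   in `kept`, `dropped_palindromic`, `dropped_allele_mismatch`,
#'   `dropped_af_discordant`.
#' @export
harmonize <- function(exp, out, palindrome_window = c(0.42, 0.58),
                      max_af_diff = 0.2) {
  shared <- intersect(exp$variant_id, out$variant_id)
  if (length(shared) == 0)
    stop("no shared variants between exposure and outcome tables")
  e <- as.data.frame(exp)[match(shared, exp$variant_id), ]
  o <- as.data.frame(out)[match(shared, out$variant_id), ]

  n <- length(shared)
  beta_out <- o$beta; se_out <- o$se; eaf_out <- o$eaf; pval_out <- o$pval
  flipped <- rep(FALSE, n)
  status <- rep("kept", n)

  pal <- function(a1, a2) {
    (nchar(a1) == 1 & nchar(a2) == 1) &
      ((a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
       (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C"))
  }
  is_pal <- pal(e$effect_allele, e$other_allele) & pal(o$effect_allele, o$other_allele)

  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele

  # non-palindromic resolution by allele labels
  idx_swap <- which(swap & !same & !is_pal)
  if (length(idx_swap)) {
    beta_out[idx_swap] <- -beta_out[idx_swap]
    eaf_out[idx_swap] <- 1 - eaf_out[idx_swap]
    flipped[idx_swap] <- TRUE
  }
  status[!same & !swap & !is_pal] <- "dropped_allele_mismatch"

  # palindromic: allele labels cannot distinguish swap from strand flip;
  # resolve by frequency, require both frequencies informative
  if (any(is_pal)) {
    lo <- palindrome_window[1]; hi <- palindrome_window[2]
    for (i in which(is_pal)) {
      fe <- e$eaf[i]; fo <- eaf_out[i]
      if (is.na(fe) || is.na(fo) || (fe >= lo && fe <= hi) || (fo >= lo && fo <= hi)) {
        status[i] <- "dropped_palindromic"
        next
      }
      if ((fe - 0.5) * (fo - 0.5) < 0) {  # opposite sides: strand/allele flip
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      }
    }
  }

  af_bad <- status == "kept" & !is.na(e$eaf) & !is.na(eaf_out) &
    abs(e$eaf - eaf_out) > max_af_diff
  status[af_bad] <- "dropped_af_discordant"

  res <- data.frame(
    variant_id = shared, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf, pval_exp = e$pval,
    n_exp = e$n,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
    pval_out = pval_out, n_out = o$n,
    flipped = flipped, status = status,
    stringsAsFactors = FALSE
  )
  n_drop <- sum(status != "kept")
  if (n_drop > 0)
    msg("harmonize: dropped %d of %d shared variants (%s)", n_drop, n,
        paste(names(table(status[status != "kept"])),
              table(status[status != "kept"]), collapse = ", "))
  class(res) <- c("harmonized_pairs", "data.frame")
  res
}

#' Greedy LD clumping
#'
#' Repeatedly retains the most significant unretired variant and retires every
#' other variant on the same chromosome within `window_kb` (inclusive, both
#' sides) whose squared correlation with it is at least `r2_threshold`. Ties
#' in p-value are broken by smaller position, then lexicographic id, so the
#' result is invariant to input row order.
#'
#' @param records data frame with `variant_id`, `chrom`, `pos`, `pval`
#'   (e.g. a [summary_table()] subset).
#' @param ld `ld_matrix` (or [reference_panel()]) covering all candidates.
#' @param r2_threshold squared-correlation threshold, default 0.001.
#' @param window_kb window half-width in kb, default 10000.
#' @return Character vector of retained variant ids, ordered by p-value.
#' @export
clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(records) == 0) return(character(0))
  ld <- resolve_ld(ld, records$variant_id)
  ord <- order(records$pval, records$pos, records$variant_id)
  rec <- records[ord, , drop = FALSE]
  retired <- rep(FALSE, nrow(rec))
  keep <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (retired[i]) next
    keep <- c(keep, rec$variant_id[i])
    cand <- which(!retired & seq_len(nrow(rec)) > i &
                    rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_kb * 1000)
    if (length(cand)) {
      r2 <- unclass(ld)[rec$variant_id[i], rec$variant_id[cand]]^2
      retired[cand[r2 >= r2_threshold]] <- TRUE
    }
  }
  keep
}

#' Instrument-strength F-statistic
#'
#' Per-variant F computed as the squared z-score, `(beta/se)^2`; values below
#' 10 conventionally indicate weak instruments.
#'
#' @param beta,se effect estimate and standard error (vectorised).
#' @return Numeric vector of F values.
#' @examples
#' f_statistic(0.1, 0.03)  # ~11.1, retained at the F >= 10 floor
#' f_statistic(0.1, 0.04)  # 6.25, excluded
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Select instrumental variables for a two-sample MR analysis
#'
#' Pipeline: p-value thresholding of the exposure scan, greedy LD clumping,
#' allele harmonization against the outcome, and an instrument-strength filter
#' retaining variants with F >= `f_min` (the boundary is kept).
#'
#' @param exp,out exposure and outcome [summary_table()]s.
#' @param ld `ld_matrix` or [reference_panel()] covering the candidates.
#' @param p_threshold exposure significance threshold (retain `pval <=`),
#'   e.g. 5e-8 for proteins, 1e-5 for lipid species.
#' @param r2_threshold,window_kb clumping parameters (defaults 0.001, 10000).
#' @param f_min F-statistic floor, default 10.
#' @param palindrome_window,max_af_diff passed to [harmonize()].
#' @return An object of class `iv_set`: list with `exposure_id`, `outcome_id`,
#'   `data` (kept harmonized pairs), `f_stats`, `params`, and `status`
#'   (`"ok"` or `"no_instruments"` — an empty selection is a reported
#'   condition, not an error).
#' @export
select_instruments <- function(exp, out, ld, p_threshold,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10, palindrome_window = c(0.42, 0.58),
                               max_af_diff = 0.2) {
  params <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, f_min = f_min)
  empty <- function() structure(
    list(exposure_id = attr(exp, "trait_id"), outcome_id = attr(out, "trait_id"),
         data = harmonize_empty(), f_stats = numeric(0), params = params,
         status = "no_instruments"),
    class = "iv_set")

  cand <- as.data.frame(exp)[exp$pval <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(empty())
  cand <- cand[cand$variant_id %in% out$variant_id, , drop = FALSE]
  if (nrow(cand) == 0) return(empty())
  keep_ids <- clump(cand, ld, r2_threshold = r2_threshold, window_kb = window_kb)

  exp_sub <- as.data.frame(exp)[exp$variant_id %in% keep_ids, , drop = FALSE]
  h <- harmonize(exp_sub, out, palindrome_window = palindrome_window,
                 max_af_diff = max_af_diff)
  h <- h[h$status == "kept", , drop = FALSE]
  if (nrow(h) == 0) return(empty())
  f <- f_statistic(h$beta_exp, h$se_exp)
  strong <- f >= f_min
  h <- h[strong, , drop = FALSE]
  f <- f[strong]
  if (nrow(h) == 0) return(empty())
  ord <- order(h$pval_exp, h$pos, h$variant_id)
  h <- h[ord, , drop = FALSE]
  f <- f[ord]
  rownames(h) <- NULL
  structure(list(exposure_id = attr(exp, "trait_id"),
                 outcome_id = attr(out, "trait_id"),
                 data = h, f_stats = f,
                 params = params, status = "ok"),
            class = "iv_set")
}

harmonize_empty <- function() {
  res <- data.frame(variant_id = character(0), chrom = character(0),
                    pos = integer(0), effect_allele = character(0),
                    other_allele = character(0), beta_exp = numeric(0),
                    se_exp = numeric(0), eaf_exp = numeric(0),
                    pval_exp = numeric(0), n_exp = numeric(0),
                    beta_out = numeric(0), se_out = numeric(0),
                    eaf_out = numeric(0), pval_out = numeric(0),
                    n_out = numeric(0), flipped = logical(0),
                    status = character(0), stringsAsFactors = FALSE)
  class(res) <- c("harmonized_pairs", "data.frame")
  res
}

#' @export
print.iv_set <- function(x, ...) {
  cat(sprintf("IV set: %s -> %s, %d instrument(s) [%s]\n",
              x$exposure_id, x$outcome_id, nrow(x$data), x$status))
  if (nrow(x$data))
    cat(sprintf("  min F = %.2f, p threshold = %g\n",
                min(x$f_stats), x$params$p_threshold))
  invisible(x)
}
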