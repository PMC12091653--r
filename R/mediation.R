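#' Product-of-coefficients mediation effect with error propagation
#'
#' The mediated (indirect) effect along an exposure -> mediator -> outcome
#' chain is the product of the two leg estimates, `a * b`. Its standard error
#' follows from first-order error propagation,
#' `se = sqrt(a^2 se_b^2 + b^2 se_a^2)`, and the p-value from the normal
#' approximation to `a*b / se`.
#'
#' @param a,se_a exposure -> mediator effect and SE.
#' @param b,se_b mediator -> outcome effect and SE.
#' @return List with `mediation`, `se`, `p`.
#' @examples
#' mediation_effect(-0.045, 0.017, -0.062, 0.028)
#' @export
mediation_effect <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  med <- a * b
  se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  p <- if (se == 0) {
    if (med == 0) 1 else 0
  } else two_sided_p(med / se)
  list(mediation = med, se = se, p = p)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * mediation / total` percent (signed). The SE of the proportion uses
#' the independence delta method on the ratio,
#' `100 |mediation/total| sqrt((se_med/mediation)^2 + (se_total/total)^2)`,
#' and the CI is `proportion +/- 1.959964 * se`. A zero mediation effect
#' yields proportion 0 with an undefined (flagged) CI; a zero total effect is
#' an undefined-proportion condition.
#'
#' @param mediation,se_mediation mediated effect and SE.
#' @param total,se_total total exposure -> outcome effect and SE.
#' @return List with `proportion` (percent), `ci` (length-2, `NA` when
#'   undefined), `se`, and `note` (additivity caveats: sign disagreement with
#'   the total effect, or |proportion| above 100%).
#' @export
mediated_proportion <- function(mediation, se_mediation, total, se_total) {
  if (total == 0) stop("total effect is zero; proportion undefined")
  prop <- 100 * mediation / total
  if (mediation == 0)
    return(list(proportion = 0, ci = c(NA_real_, NA_real_), se = NA_real_,
                note = "zero mediation effect; CI undefined"))
  se_prop <- 100 * abs(mediation / total) *
    sqrt((se_mediation / mediation)^2 + (se_total / total)^2)
  ci <- prop + c(-1, 1) * Z95 * se_prop
  note <- NA_character_
  if (sign(total) != sign(mediation))
    note <- "mediation and total effects have opposite signs (additive mediation assumption violated)"
  else if (abs(prop) > 100)
    note <- "|proportion| exceeds 100%"
  list(proportion = prop, ci = ci, se = se_prop, note = note)
}

#' Assemble a mediation result from leg estimates
#'
#' Combines a total effect and the two direct legs (A: exposure -> mediator,
#' B: mediator -> outcome) into the product-of-coefficients mediation effect,
#' its error-propagated SE and p-value, and the mediated proportion with CI.
#'
#' @param total,se_total total exposure -> outcome effect.
#' @param a,se_a direct effect A.
#' @param b,se_b direct effect B.
#' @param pathway_id character label, e.g. "lipid-protein-disease".
#' @param estimators optional character vector recording which estimator
#'   produced each leg.
#' @return An object of class `mediation_result`.
#' @export
mediation <- function(total, se_total, a, se_a, b, se_b,
                      pathway_id = "exposure-mediator-outcome",
                      estimators = NULL) {
  me <- mediation_effect(a, se_a, b, se_b)
  pr <- mediated_proportion(me$mediation, me$se, total, se_total)
  structure(list(pathway_id = pathway_id,
                 total = total, se_total = se_total,
                 direct_a = a, se_a = se_a,
                 direct_b = b, se_b = se_b,
                 mediation = me$mediation, se_mediation = me$se,
                 p_mediation = me$p,
                 proportion = pr$proportion, prop_ci = pr$ci,
                 prop_se = pr$se, note = pr$note,
                 estimators = estimators, estimable = TRUE),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation pathway: %s\n", x$pathway_id))
  if (!x$estimable) {
    cat(sprintf("  non-estimable: %s\n", x$note))
    return(invisible(x))
  }
  # report-time rounding: 3 dp for betas, 2 significant figures for percents
  cat(sprintf("  total = %.3f  direct A = %.3f  direct B = %.3f\n",
              x$total, x$direct_a, x$direct_b))
  cat(sprintf("  mediation = %.3f (se %.3f, p = %.3g)\n",
              x$mediation, x$se_mediation, x$p_mediation))
  if (all(is.finite(x$prop_ci)))
    cat(sprintf("  proportion mediated = %s%% (95%% CI %s, %s)\n",
                signif(x$proportion, 2), signif(x$prop_ci[1], 2),
                signif(x$prop_ci[2], 2)))
  else
    cat(sprintf("  proportion mediated = %s%% (CI undefined)\n",
                signif(x$proportion, 2)))
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Format mediation results as a report table
#'
#' One row per pathway with the total effect, direct effects A and B, the
#' mediation effect, its p-value and the mediated proportion with CI --
#' rounding (3 dp betas, 2 significant-figure percents) applied at report
#' time only.
#'
#' @param results a `mediation_result` or list of them.
#' @param raw if `TRUE`, skip rounding.
#' @return A data frame.
#' @export
mediation_table <- function(results, raw = FALSE) {
  if (inherits(results, "mediation_result")) results <- list(results)
  rows <- lapply(results, function(x) {
    if (!isTRUE(x$estimable))
      return(data.frame(pathway = x$pathway_id, total = NA_real_,
                        direct_a = NA_real_, direct_b = NA_real_,
                        mediation = NA_real_, p = NA_real_,
                        proportion_pct = NA_real_, prop_lo = NA_real_,
                        prop_hi = NA_real_, note = x$note %||% "non-estimable",
                        stringsAsFactors = FALSE))
    data.frame(pathway = x$pathway_id,
               total = if (raw) x$total else round(x$total, 3),
               direct_a = if (raw) x$direct_a else round(x$direct_a, 3),
               direct_b = if (raw) x$direct_b else round(x$direct_b, 3),
               mediation = if (raw) x$mediation else round(x$mediation, 3),
               p = if (raw) x$p_mediation else signif(x$p_mediation, 2),
               proportion_pct = if (raw) x$proportion else signif(x$proportion, 2),
               prop_lo = if (raw) x$prop_ci[1] else signif(x$prop_ci[1], 2),
               prop_hi = if (raw) x$prop_ci[2] else signif(x$prop_ci[2], 2),
               note = if (is.na(x$note)) "" else x$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-step MR mediation from summary tables
#'
#' Runs three MR fits -- exposure -> mediator, mediator -> outcome and
#' exposure -> outcome (the total effect) -- and assembles the
#' product-of-coefficients mediation result. Each leg uses
#' [select_instruments()] with its own significance threshold (the mediator
#' leg defaults to the stringent protein threshold) and the IVW
#' multiplicative-random-effects estimator by default; any leg without
#' instruments renders the pathway non-estimable (reported, not an error).
#'
#' @param exposure,mediator,outcome [summary_table()]s.
#' @param ld `ld_matrix` or [reference_panel()].
#' @param config a [medmr_config()]; `p_threshold_lipid` governs the
#'   exposure legs and `p_threshold_protein` the mediator leg.
#' @param methods_leg estimator reported per leg (default `"ivw"`).
#' @return A `mediation_result` (with `fits` attached).
#' @export
two_step <- function(exposure, mediator, outcome, ld, config = medmr_config(),
                     methods_leg = "ivw") {
  pathway <- paste(attr(exposure, "trait_id") %||% "exposure",
                   attr(mediator, "trait_id") %||% "mediator",
                   attr(outcome, "trait_id") %||% "outcome", sep = "-")
  leg <- function(exp_tab, out_tab, p_thr) {
    iv <- select_instruments(exp_tab, out_tab, ld, p_threshold = p_thr,
                             r2_threshold = config$clump_r2,
                             window_kb = config$clump_window_kb,
                             f_min = config$f_min,
                             palindrome_window = config$palindrome_window,
                             max_af_diff = config$max_af_diff)
    if (iv$status != "ok") return(NULL)
    mr(iv, methods = unique(c(methods_leg, "ivw")), ivw_mode = config$ivw_mode,
       n_boot = config$n_boot, seed = config$boot_seed)
  }
  fit_a <- leg(exposure, mediator, config$p_threshold_lipid)
  fit_b <- leg(mediator, outcome, config$p_threshold_protein)
  fit_t <- leg(exposure, outcome, config$p_threshold_lipid)
  if (is.null(fit_a) || is.null(fit_b) || is.null(fit_t)) {
    missing_leg <- c("exposure->mediator", "mediator->outcome",
                     "exposure->outcome")[c(is.null(fit_a), is.null(fit_b),
                                            is.null(fit_t))]
    res <- structure(list(pathway_id = pathway, estimable = FALSE,
                          note = paste("no instruments for leg(s):",
                                       paste(missing_leg, collapse = ", "))),
                     class = "mediation_result")
    return(res)
  }
  pick <- function(fit) {
    est <- fit$estimates
    row <- est[est$method %in% c("ivw_mre", "ivw_fixed", "wald"), ][1, ]
    row
  }
  ra <- pick(fit_a); rb <- pick(fit_b); rt <- pick(fit_t)
  res <- mediation(total = rt$beta, se_total = rt$se,
                   a = ra$beta, se_a = ra$se, b = rb$beta, se_b = rb$se,
                   pathway_id = pathway,
                   estimators = c(a = ra$method, b = rb$method, total = rt$method))
  res$fits <- list(a = fit_a, b = fit_b, total = fit_t)
  res
}
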