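#' Per-variant Wald ratios
#'
#' The per-instrument causal estimate: outcome effect divided by exposure
#' effect, with the first-order (delta-method) standard error
#' `se_out / |beta_exp|`. The second-order SE, which also carries the exposure
#' uncertainty, is available behind a flag.
#'
#' @param x an `iv_set` or a data frame with `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` (and optionally `variant_id`).
#' @param second_order if `TRUE`, use
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#' @return Data frame with `variant_id`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratios <- function(x, second_order = FALSE) {
  d <- if (inherits(x, "iv_set")) x$data else as.data.frame(x)
  if (nrow(d) == 0) stop("empty instrument set")
  if (any(d$beta_exp == 0))
    stop("degenerate instrument(s) with zero exposure effect: ",
         paste(d$variant_id[d$beta_exp == 0], collapse = ", "))
  ratio <- d$beta_out / d$beta_exp
  se_ratio <- if (second_order)
    sqrt(d$se_out^2 / d$beta_exp^2 + d$beta_out^2 * d$se_exp^2 / d$beta_exp^4)
  else d$se_out / abs(d$beta_exp)
  data.frame(variant_id = d$variant_id %||% paste0("iv", seq_len(nrow(d))),
             ratio = ratio, se_ratio = se_ratio, weight = 1 / se_ratio^2,
             stringsAsFactors = FALSE)
}

mr_estimate_row <- function(method, beta, se, pval, n_snp, q = NA_real_,
                            q_pval = NA_real_, intercept = NA_real_,
                            intercept_se = NA_real_, intercept_pval = NA_real_) {
  data.frame(method = method, beta = beta, se = se, pval = pval,
             n_snp = n_snp, or = exp(beta),
             or_lo = exp(beta - Z95 * se), or_hi = exp(beta + Z95 * se),
             q = q, q_pval = q_pval,
             egger_intercept = intercept, intercept_se = intercept_se,
             intercept_pval = intercept_pval, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of Wald ratios with weights `1/se_ratio^2`; algebraically the
#' zero-intercept weighted least-squares slope of outcome on exposure effects.
#' Fixed-effects SE is `1/sqrt(sum(w))`; the multiplicative random-effects
#' mode scales it by `max(1, sqrt(Q/(k-1)))`, the usual floor-at-one
#' overdispersion correction. Cochran's Q and its chi-square p-value
#' (k-1 df) quantify heterogeneity.
#'
#' @param ratios output of [wald_ratios()].
#' @param mode `"fixed"` or `"multiplicative_random"`.
#' @return One-row estimate data frame (see [mr()]).
#' @export
ivw <- function(ratios, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(ratios)
  if (k == 0) stop("empty instrument set")
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (ratios$ratio - beta)^2)
  q_pval <- if (k >= 2) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  if (mode == "multiplicative_random" && k >= 2)
    se <- se * max(1, sqrt(q / (k - 1)))
  mr_estimate_row(if (mode == "fixed") "ivw_fixed" else "ivw_mre",
                  beta, se, two_sided_p(beta / se), k, q, q_pval)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting all exposure effects to
#' be non-negative so the intercept — the directional-pleiotropy test — is
#' interpretable. Coefficient SEs carry the multiplicative scaling
#' `max(1, sqrt(RSS_w/(k-2)))`; p-values use the t distribution with k-2 df.
#'
#' @param pairs harmonized pairs (`beta_exp`, `se_exp`, `beta_out`, `se_out`)
#'   or an `iv_set`.
#' @return One-row estimate data frame including intercept columns.
#' @export
mr_egger <- function(pairs) {
  d <- if (inherits(pairs, "iv_set")) pairs$data else as.data.frame(pairs)
  k <- nrow(d)
  if (k < 3) stop("MR-Egger requires at least 3 instruments")
  sgn <- ifelse(d$beta_exp < 0, -1, 1)
  x <- d$beta_exp * sgn
  y <- d$beta_out * sgn
  w <- 1 / d$se_out^2
  X <- cbind(1, x)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * y))
  fit <- X %*% coefs
  rss <- sum(w * (y - fit)^2)
  sigma2 <- rss / (k - 2)
  vcv <- solve(xtwx) * max(1, sigma2)
  se <- sqrt(diag(vcv))
  tstat <- coefs / se
  pt2 <- function(t) 2 * stats::pt(-abs(t), df = k - 2)
  mr_estimate_row("egger", coefs[2], se[2], pt2(tstat[2]), k,
                  q = rss, q_pval = stats::pchisq(rss, k - 2, lower.tail = FALSE),
                  intercept = coefs[1], intercept_se = se[1],
                  intercept_pval = pt2(tstat[1]))
}

# cumulative-weight-crossing weighted median of ratios
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  cw <- cumsum(weight[ord]) / sum(weight)
  stats::approx(x = cw, y = r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The estimate is the value at which the cumulative normalized weight of the
#' sorted Wald ratios crosses one half (linear interpolation); it is
#' consistent when at least half of the weight comes from valid instruments.
#' The SE is the standard deviation of the estimate over `n_boot` parametric
#' bootstrap replicates in which each ratio is resampled from
#' `N(ratio_i, se_ratio_i)` (weights held fixed), under a local seeded RNG
#' stream that leaves the caller's stream untouched.
#'
#' @param ratios output of [wald_ratios()].
#' @param n_boot bootstrap replicates, default 1000 (values below 100 warn).
#' @param seed bootstrap seed, recorded in the fit.
#' @return One-row estimate data frame.
#' @export
weighted_median <- function(ratios, n_boot = 1000, seed = 42) {
  k <- nrow(ratios)
  if (k < 3) stop("weighted median requires at least 3 instruments")
  if (n_boot < 100)
    warning("n_boot < 100 gives an unstable bootstrap SE", call. = FALSE)
  est <- weighted_median_point(ratios$ratio, ratios$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      r <- stats::rnorm(k, ratios$ratio, ratios$se_ratio)
      weighted_median_point(r, ratios$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate_row("weighted_median", est, se, two_sided_p(est / se), k)
}

# profile objective: -2 * profile log-likelihood of theta (up to a constant)
ml_objective <- function(theta, bx, by, sx, sy) {
  sum((by - theta * bx)^2 / (sy^2 + theta^2 * sx^2))
}

#' Maximum-likelihood causal estimate
#'
#' Models the observed exposure/outcome effect pairs as independent normals
#' around `(xi_i, theta * xi_i)` with known SDs; the nuisance means `xi_i` are
#' profiled out analytically, leaving a one-dimensional objective in `theta`
#' minimised numerically (tolerance 1e-10). The SE comes from the curvature
#' (observed information) of the profile log-likelihood at the optimum.
#'
#' @param pairs harmonized pairs or an `iv_set`.
#' @return One-row estimate data frame.
#' @export
max_likelihood <- function(pairs) {
  d <- if (inherits(pairs, "iv_set")) pairs$data else as.data.frame(pairs)
  k <- nrow(d)
  if (k < 2) stop("maximum likelihood requires at least 2 instruments")
  bx <- d$beta_exp; by <- d$beta_out; sx <- d$se_exp; sy <- d$se_out
  start <- sum(by * bx / sy^2) / sum(bx^2 / sy^2)  # IVW as anchor
  span <- max(1, 20 * abs(start))
  opt <- stats::optimize(ml_objective, interval = c(start - span, start + span),
                         bx = bx, by = by, sx = sx, sy = sy, tol = 1e-10)
  theta <- opt$minimum
  h <- max(1e-5, 1e-5 * abs(theta))
  f0 <- ml_objective(theta, bx, by, sx, sy)
  fp <- ml_objective(theta + h, bx, by, sx, sy)
  fm <- ml_objective(theta - h, bx, by, sx, sy)
  d2 <- (fp - 2 * f0 + fm) / h^2          # of -2 loglik; info = d2 / 2
  if (!is.finite(d2) || d2 <= 0)
    stop("maximum-likelihood curvature not positive definite at the optimum; ",
         "theta = ", format(theta))
  se <- sqrt(2 / d2)
  mr_estimate_row("max_likelihood", theta, se, two_sided_p(theta / se), k)
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The package's central fitting function: given a harmonized instrument set
#' it computes the primary inverse-variance-weighted estimate together with
#' the standard sensitivity analyses (MR-Egger, weighted median, maximum
#' likelihood) and Cochran's Q, returning a classed fit with `print`,
#' `summary`, `coef` and `confint` methods. With a single instrument the
#' Wald ratio is returned.
#'
#' @param x an `iv_set` from [select_instruments()], or harmonized pairs.
#' @param methods subset of `c("ivw", "ivw_fixed", "egger",
#'   "weighted_median", "max_likelihood")`; methods whose minimum instrument
#'   count is not met are skipped with a message.
#' @param ivw_mode default IVW mode (`"multiplicative_random"` keeps the
#'   floor-at-one overdispersion scaling; the fixed-effects estimate is always
#'   reported alongside).
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param second_order use second-order Wald-ratio SEs.
#' @return An object of class `mr_fit`: list with `estimates` (one row per
#'   method), `ratios`, `exposure_id`, `outcome_id`, `n_snp`, `seed`.
#' @examples
#' d <- data.frame(beta_exp = c(0.12, 0.1, 0.15, 0.09),
#'                 se_exp = 0.01, beta_out = c(0.024, 0.02, 0.031, 0.017),
#'                 se_out = 0.005)
#' fit <- mr(d)
#' coef(fit)
#' @export
mr <- function(x, methods = c("ivw", "ivw_fixed", "egger", "weighted_median",
                              "max_likelihood"),
               ivw_mode = c("multiplicative_random", "fixed"),
               n_boot = 1000, seed = 42, second_order = FALSE) {
  ivw_mode <- match.arg(ivw_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  d <- if (inherits(x, "iv_set")) x$data else as.data.frame(x)
  exposure_id <- if (inherits(x, "iv_set")) x$exposure_id else NA_character_
  outcome_id <- if (inherits(x, "iv_set")) x$outcome_id else NA_character_
  k <- nrow(d)
  if (k == 0) stop("empty instrument set; nothing to fit")
  ratios <- wald_ratios(d, second_order = second_order)

  rows <- list()
  if (k == 1) {
    rows$wald <- mr_estimate_row("wald", ratios$ratio, ratios$se_ratio,
                                 two_sided_p(ratios$ratio / ratios$se_ratio), 1L)
  } else {
    if ("ivw" %in% methods) rows$ivw <- ivw(ratios, mode = ivw_mode)
    if ("ivw_fixed" %in% methods && ivw_mode != "fixed")
      rows$ivw_fixed <- ivw(ratios, mode = "fixed")
    if ("egger" %in% methods) {
      if (k >= 3) rows$egger <- mr_egger(d)
      else msg("skipping MR-Egger: %d instrument(s) < 3", k)
    }
    if ("weighted_median" %in% methods) {
      if (k >= 3) rows$wm <- weighted_median(ratios, n_boot = n_boot, seed = seed)
      else msg("skipping weighted median: %d instrument(s) < 3", k)
    }
    if ("max_likelihood" %in% methods) rows$ml <- max_likelihood(d)
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  structure(list(estimates = est, ratios = ratios, exposure_id = exposure_id,
                 outcome_id = outcome_id, n_snp = k, seed = seed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$exposure_id %||% "?", x$outcome_id %||% "?", x$n_snp))
  est <- x$estimates
  out <- data.frame(method = est$method,
                    beta = round(est$beta, digits),
                    se = round(est$se, digits),
                    p = signif(est$pval, digits),
                    OR = round(est$or, digits),
                    OR_95 = sprintf("(%.*f, %.*f)", digits, est$or_lo,
                                    digits, est$or_hi))
  print(out, row.names = FALSE)
  qrow <- est[est$method %in% c("ivw_mre", "ivw_fixed"), ][1, ]
  if (nrow(est) && is.finite(qrow$q))
    cat(sprintf("Cochran Q = %.3f (p = %.3g)\n", qrow$q, qrow$q_pval))
  eg <- est[est$method == "egger", ]
  if (nrow(eg))
    cat(sprintf("Egger intercept = %.4f (p = %.3g)\n",
                eg$egger_intercept, eg$intercept_pval))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$estimates)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}

#' Odds-ratio / log-odds conversions
#'
#' `or_to_beta` and `beta_to_or` move between the odds-ratio and log-odds
#' scales; `ci_to_se` back-derives a standard error from a 95% confidence
#' interval reported on the OR scale: `(log(upper) - log(lower)) / (2 * 1.959964)`.
#'
#' @param or_value odds ratio(s), > 0.
#' @examples
#' or_to_beta(1.102)  # 0.097
#' or_to_beta(0.956)  # -0.045
#' @export
or_to_beta <- function(or_value) {
  if (any(!is.finite(or_value) | or_value <= 0)) stop("odds ratios must be positive")
  log(or_value)
}

#' @rdname or_to_beta
#' @param beta log odds ratio(s).
#' @export
beta_to_or <- function(beta) exp(beta)

#' @rdname or_to_beta
#' @param lower,upper 95% CI bounds on the OR scale, `upper > lower > 0`.
#' @export
ci_to_se <- function(lower, upper) {
  if (any(!is.finite(lower) | !is.finite(upper) | lower <= 0 | upper <= lower))
    stop("need upper > lower > 0")
  (log(upper) - log(lower)) / (2 * Z95)
}
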