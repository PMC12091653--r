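#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximate Bayes factor comparing a normal effect prior of
#' standard deviation `prior_sd` against the point null, computed from a
#' single estimate and standard error. With `V = se^2`, `W = prior_sd^2` and
#' `z = beta/se`:
#' `labf = 0.5 * log(V/(V+W)) + z^2 * W / (2 * (V+W))`.
#'
#' @param beta,se effect estimate and standard error (vectorised), `se > 0`.
#' @param prior_sd prior effect-size SD (> 0); 0.15 is the usual choice for
#'   quantitative traits, 0.2 on the log-OR scale for binary traits.
#' @return Log Bayes factor(s).
#' @export
labf <- function(beta, se, prior_sd) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), and both traits (`p12`); defaults 1e-4, 1e-4, 1e-5.
#'
#' @param p1,p2,p12 priors in (0, 1) with `p12 <= min(p1, p2)`.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Bayesian colocalization over a region via approximate Bayes factors
#'
#' Evaluates the five mutually exclusive hypotheses for a genomic region
#' shared by two traits: H0 no association with either trait; H1/H2
#' association with one trait only; H3 association with both through distinct
#' causal variants; H4 association with both through a single shared causal
#' variant. Per-SNP log approximate Bayes factors are combined in log space
#' (log-sum-exp throughout); the H3 double sum is computed as the product of
#' marginal sums minus the diagonal, in O(n). Variants present in only one
#' trait are dropped (complete-case) with a logged count.
#'
#' @param region1,region2 [summary_table()]s (or plain data frames with
#'   `variant_id`, `beta`, `se`) for the two traits over the region. If both
#'   carry allele columns they are harmonized first.
#' @param priors a [coloc_priors()].
#' @param prior_sd1,prior_sd2 per-trait prior effect SDs (defaults 0.15
#'   quantitative, 0.2 binary, chosen from each table's `trait_type` when
#'   available).
#' @return An object of class `coloc_fit`: `n_snps`, `pph0`..`pph4`
#'   (posterior probabilities summing to one), `strong` flag at
#'   `pph4 > 0.6`, and the priors used.
#' @export
coloc_abf <- function(region1, region2, priors = coloc_priors(),
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  pick_sd <- function(tab, given) {
    if (!is.null(given)) return(given)
    if (identical(attr(tab, "trait_type"), "binary")) 0.2 else 0.15
  }
  sd1 <- pick_sd(region1, prior_sd1)
  sd2 <- pick_sd(region2, prior_sd2)

  d1 <- as.data.frame(region1)
  d2 <- as.data.frame(region2)
  if (all(c("effect_allele", "other_allele") %in% names(d1)) &&
      all(c("effect_allele", "other_allele") %in% names(d2)) &&
      inherits(region1, "summary_table") && inherits(region2, "summary_table")) {
    h <- harmonize(region1, region2)
    kept <- h[h$status == "kept", , drop = FALSE]
    d1 <- data.frame(variant_id = kept$variant_id, beta = kept$beta_exp,
                     se = kept$se_exp)
    d2 <- data.frame(variant_id = kept$variant_id, beta = kept$beta_out,
                     se = kept$se_out)
  } else {
    shared <- intersect(d1$variant_id, d2$variant_id)
    n_only <- (nrow(d1) - length(shared)) + (nrow(d2) - length(shared))
    if (n_only > 0)
      msg("coloc: dropped %d variant(s) present in only one trait", n_only)
    d1 <- d1[match(shared, d1$variant_id), ]
    d2 <- d2[match(shared, d2$variant_id), ]
  }
  n <- nrow(d1)
  if (n == 0) stop("empty shared region after matching")

  l1 <- labf(d1$beta, d1$se, sd1)
  l2 <- labf(d2$beta, d2$se, sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)

  lh0 <- 0
  lh1 <- log(priors$p1) + ls1
  lh2 <- log(priors$p2) + ls2
  # sum_{i != j} exp(l1_i + l2_j) = (sum_i)(sum_j) - diagonal, log space
  lh3 <- if (n < 2) -Inf else {
    diff <- ls12 - (ls1 + ls2)
    log(priors$p1) + log(priors$p2) + ls1 + ls2 +
      log1p(-pmin(exp(diff), 1 - 1e-16))
  }
  lh4 <- log(priors$p12) + ls12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  post <- exp(lh - logsumexp(lh))
  post <- post / sum(post)
  structure(list(n_snps = n, pph0 = post[1], pph1 = post[2], pph2 = post[3],
                 pph3 = post[4], pph4 = post[5], strong = post[5] > 0.6,
                 priors = priors, prior_sd = c(sd1, sd2)),
            class = "coloc_fit")
}

#' @export
print.coloc_fit <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNP(s):\n", x$n_snps))
  cat(sprintf("  PPH0 = %.4f  PPH1 = %.4f  PPH2 = %.4f  PPH3 = %.4f  PPH4 = %.4f\n",
              x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  cat(if (x$strong) "  strong evidence of a shared causal variant (PPH4 > 0.6)\n"
      else "  no strong colocalization evidence\n")
  invisible(x)
}
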