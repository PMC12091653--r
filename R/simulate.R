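#' Simulation scenarios for the lipid -> protein -> disease causal chain
#'
#' A scenario bundles everything needed to generate a reference panel, an
#' individual-level causal chain (quantitative exposure, quantitative
#' mediator, binary outcome) and per-variant marginal GWAS summary
#' statistics. LD is block-wise: within each block, dosages have a target
#' pairwise correlation `rho` (the latent Gaussian correlation is calibrated
#' so the *dosage* correlation hits the target).
#'
#' @param n_individuals cohort size, default 20000.
#' @param n_variants number of variants, default 500.
#' @param n_blocks number of LD blocks (blocks are placed 20,000 kb apart so
#'   inter-block variants never share a clumping window), default 10.
#' @param rho target within-block dosage correlation, |rho| < 1, default 0.3.
#' @param maf_range minor-allele-frequency range, subset of (0, 0.5].
#' @param a,b,c_prime chain coefficients: exposure -> mediator (SD units),
#'   mediator -> outcome (log-OR per SD), direct exposure -> outcome (log-OR).
#' @param h2_exposure,h2_mediator genetic variance of each quantitative trait.
#' @param n_causal_exposure,n_causal_mediator causal variants per trait
#'   (distinct sets, spread across blocks).
#' @param outcome_direct optional named numeric vector of direct per-allele
#'   log-OR genetic effects on the outcome (names = variant indices as
#'   integers), used by the linkage preset.
#' @param prevalence disease prevalence in (0, 1), default 0.047 (the
#'   case fraction of a 7921-case / 159,201-control GWAS).
#' @param seed integer seed; part of the scenario and echoed into outputs.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_individuals = 20000, n_variants = 500,
                                n_blocks = 10, rho = 0.3,
                                maf_range = c(0.05, 0.5),
                                a = -0.045, b = -0.062, c_prime = 0.094,
                                h2_exposure = 0.3, h2_mediator = 0.3,
                                n_causal_exposure = 20, n_causal_mediator = 20,
                                outcome_direct = NULL,
                                prevalence = 0.047, seed = 1L) {
  stopifnot(n_individuals >= 10, n_variants >= 2, n_blocks >= 1,
            n_variants %% n_blocks == 0)
  if (abs(rho) >= 1) stop("degenerate LD block: |rho| must be < 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a subset of (0, 0.5]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  stopifnot(h2_exposure >= 0, h2_exposure < 1, h2_mediator >= 0, h2_mediator < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 n_blocks = as.integer(n_blocks), rho = rho,
                 maf_range = maf_range, a = a, b = b, c_prime = c_prime,
                 h2_exposure = h2_exposure, h2_mediator = h2_mediator,
                 n_causal_exposure = as.integer(n_causal_exposure),
                 n_causal_mediator = as.integer(n_causal_mediator),
                 outcome_direct = outcome_direct,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# bivariate-normal orthant probability P(Z1 < t, Z2 < t | r), by quadrature
bvn_lower <- function(t, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(t)^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((t - r * z) / sqrt(1 - r^2))
  stats::integrate(f, -Inf, t, rel.tol = 1e-9)$value
}

# latent Gaussian correlation that yields dosage (phi) correlation `target`
# for two variants thresholded at MAF `maf`
calibrate_latent_rho <- function(target, maf) {
  if (abs(target) < 1e-10) return(0)
  t <- stats::qnorm(maf)
  phi <- function(r) (bvn_lower(t, r) - maf^2) / (maf * (1 - maf))
  lim <- phi(0.9999 * sign(target))
  if (abs(target) >= abs(lim)) return(0.9999 * sign(target))
  stats::uniroot(function(r) phi(r) - target,
                 interval = sort(c(0, 0.9999 * sign(target))),
                 tol = 1e-8)$root
}

#' Simulate a reference genotype panel with block LD
#'
#' Haplotypes arise from block-wise equicorrelated latent Gaussians
#' thresholded at the MAF quantile; a dosage is the sum of two independent
#' haplotypes. The latent within-block correlation is calibrated (via the
#' tetrachoric relationship at the block's mean MAF) so that the realised
#' *dosage* correlation matches the scenario's `rho`. Blocks are placed
#' 20,000 kb apart on one chromosome, variants 10 kb apart within a block.
#' Fully reproducible from the scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return A [reference_panel()] with attributes `maf` and `scenario_seed`.
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- scenario$n_individuals
  m <- scenario$n_variants
  bs <- m %/% scenario$n_blocks
  with_seed(scenario$seed, {
    if (scenario$rho < 0)
      stop("block-wide equicorrelation requires rho >= 0")
    # variants in strong LD necessarily have near-equal allele frequencies,
    # so MAF varies across blocks but only jitters within a block
    maf_block <- stats::runif(scenario$n_blocks,
                              scenario$maf_range[1], scenario$maf_range[2])
    maf <- pmin(pmax(rep(maf_block, each = bs) +
                       stats::runif(m, -0.01, 0.01),
                     scenario$maf_range[1]), scenario$maf_range[2])
    g <- matrix(0L, n, m)
    for (blk in seq_len(scenario$n_blocks)) {
      cols <- ((blk - 1) * bs + 1):(blk * bs)
      r_lat <- calibrate_latent_rho(scenario$rho, mean(maf[cols]))
      for (hap in 1:2) {
        shared <- stats::rnorm(n)
        zz <- sqrt(r_lat) * shared +
          sqrt(1 - r_lat) * matrix(stats::rnorm(n * length(cols)), n)
        thr <- matrix(stats::qnorm(maf[cols]), n, length(cols), byrow = TRUE)
        g[, cols] <- g[, cols] + (zz < thr)
      }
    }
    ids <- sprintf("rs%05d", seq_len(m))
    colnames(g) <- ids
    # one chromosome per block: clumping windows and cis regions never span
    # blocks, and positions stay well inside integer range at any block count
    block_of <- rep(seq_len(scenario$n_blocks), each = bs)
    within <- seq_len(m) - (block_of - 1L) * bs
    map <- data.frame(variant_id = ids, chrom = as.character(block_of),
                      pos = within * 10000L,
                      stringsAsFactors = FALSE)
    panel <- reference_panel(g, map)
    attr(panel, "maf") <- maf
    attr(panel, "scenario_seed") <- scenario$seed
    panel
  })
}

#' Simulate the individual-level causal chain
#'
#' `exposure = genetic score + noise` (unit variance), `mediator = a *
#' exposure + its own genetic score + noise` (unit variance), and a binary
#' outcome drawn from `Bernoulli(plogis(alpha + b * mediator + c' * exposure
#' + direct genetic effects))` with the intercept `alpha` solved by
#' root-finding so the expected prevalence matches the scenario.
#'
#' @param panel a [reference_panel()] from [simulate_panel()].
#' @param scenario the matching [simulation_scenario()].
#' @return List with `exposure`, `mediator`, `outcome` (0/1), `truth`
#'   (causal indices, per-variant effects, attained prevalence, alpha).
#' @export
simulate_chain <- function(panel, scenario) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(scenario, "simulation_scenario"))
  g <- panel$dosages
  n <- nrow(g); m <- ncol(g)
  with_seed(scenario$seed + 1L, {
    maf <- colMeans(g) / 2
    per_var <- function(idx, h2) {
      v <- 2 * maf[idx] * (1 - maf[idx])
      sqrt(h2 / length(idx) / pmax(v, 1e-8))
    }
    # explicit causal architecture (presets) beats random placement
    if (!is.null(scenario$causal_mediator)) {
      idx_med <- scenario$causal_mediator$idx
      delta <- rep_len(scenario$causal_mediator$effects, length(idx_med))
    } else idx_med <- NULL
    # random placement keeps exposure and mediator causal variants in
    # disjoint LD blocks: exposure instruments then satisfy the exclusion
    # restriction instead of tagging the mediator's own genetic effects
    bs <- m %/% scenario$n_blocks
    block_of <- rep(seq_len(scenario$n_blocks), each = bs)
    exp_blocks <- seq_len(max(1L, scenario$n_blocks %/% 2L))
    med_blocks <- setdiff(seq_len(scenario$n_blocks), exp_blocks)
    if (!length(med_blocks)) med_blocks <- exp_blocks  # single block: best effort
    if (!is.null(scenario$causal_exposure)) {
      idx_exp <- scenario$causal_exposure$idx
      gamma <- rep_len(scenario$causal_exposure$effects, length(idx_exp))
    } else {
      pool <- setdiff(which(block_of %in% exp_blocks), idx_med)
      idx_exp <- sort(sample(pool, scenario$n_causal_exposure))
      gamma <- per_var(idx_exp, scenario$h2_exposure)
    }
    if (is.null(idx_med)) {
      pool <- setdiff(which(block_of %in% med_blocks), idx_exp)
      idx_med <- sort(sample(pool, scenario$n_causal_mediator))
      delta <- per_var(idx_med, scenario$h2_mediator)
    }

    score_exp <- as.vector(g[, idx_exp, drop = FALSE] %*% gamma)
    exposure <- score_exp + stats::rnorm(n, 0, sqrt(max(1e-6, 1 - stats::var(score_exp))))
    score_med <- as.vector(g[, idx_med, drop = FALSE] %*% delta)
    resid_var <- 1 - scenario$a^2 - stats::var(score_med)
    mediator <- scenario$a * exposure + score_med +
      stats::rnorm(n, 0, sqrt(max(1e-6, resid_var)))

    lp <- scenario$b * mediator + scenario$c_prime * exposure
    if (!is.null(scenario$outcome_direct)) {
      od <- scenario$outcome_direct
      idx_out <- as.integer(names(od))
      lp <- lp + as.vector(g[, idx_out, drop = FALSE] %*% unname(od))
    }
    fprev <- function(alpha) mean(stats::plogis(alpha + lp)) - scenario$prevalence
    if (fprev(-40) > 0 || fprev(40) < 0)
      stop("target prevalence unattainable for this linear predictor")
    alpha <- stats::uniroot(fprev, c(-40, 40), tol = 1e-10)$root
    outcome <- stats::rbinom(n, 1, stats::plogis(alpha + lp))
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = list(idx_exposure = idx_exp, gamma = gamma,
                      idx_mediator = idx_med, delta = delta,
                      a = scenario$a, b = scenario$b,
                      c_prime = scenario$c_prime, alpha = alpha,
                      prevalence_attained = mean(outcome)))
  })
}

# vectorised per-variant simple linear regression (matches lm per column)
lin_marginal <- function(g, y) {
  n <- nrow(g)
  gbar <- colMeans(g)
  ybar <- mean(y)
  sxx <- colSums(g^2) - n * gbar^2
  sxy <- as.vector(crossprod(g, y)) - n * gbar * ybar
  syy <- sum(y^2) - n * ybar^2
  beta <- sxy / sxx
  sigma2 <- pmax(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tt <- beta / se
  data.frame(beta = beta, se = se, pval = 2 * stats::pt(-abs(tt), df = n - 2))
}

# per-variant logistic regression by Newton-Raphson; returns NA on separation
logit_marginal_one <- function(g, y, max_iter = 25, tol = 1e-8) {
  p0 <- mean(y)
  b <- c(log(p0 / (1 - p0)), 0)
  for (it in seq_len(max_iter)) {
    eta <- b[1] + b[2] * g
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    u <- y - mu
    s <- c(sum(u), sum(g * u))
    i11 <- sum(w); i12 <- sum(w * g); i22 <- sum(w * g^2)
    det <- i11 * i22 - i12^2
    if (!is.finite(det) || det <= 1e-12) return(c(NA_real_, NA_real_))
    step <- c(i22 * s[1] - i12 * s[2], -i12 * s[1] + i11 * s[2]) / det
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  if (!all(is.finite(b)) || abs(b[2]) > 15) return(c(NA_real_, NA_real_))
  se2 <- i11 / det
  c(b[2], sqrt(se2))
}

#' Marginal GWAS summary statistics from individual-level data
#'
#' Regresses the trait on each dosage column separately: simple linear
#' regression for quantitative traits (two-sided t p-values, matching
#' [stats::lm()]), logistic regression by Newton-Raphson for binary traits
#' (Wald p-values). Variants showing separation in the logistic fit are
#' flagged and dropped with a logged count. The effect allele is the dosage
#' allele, so `eaf` is exactly `colMeans(dosages)/2`.
#'
#' @param traits numeric trait vector aligned to panel rows (0/1 for binary).
#' @param panel a [reference_panel()].
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id trait label.
#' @return A [summary_table()].
#' @export
summary_stats <- function(traits, panel, trait_type = c("quantitative", "binary"),
                          trait_id = "trait") {
  trait_type <- match.arg(trait_type)
  g <- panel$dosages
  stopifnot(length(traits) == nrow(g))
  n <- nrow(g)
  if (trait_type == "quantitative") {
    res <- lin_marginal(g, traits)
  } else {
    est <- vapply(seq_len(ncol(g)), function(j) logit_marginal_one(g[, j], traits),
                  numeric(2))
    res <- data.frame(beta = est[1, ], se = est[2, ])
    res$pval <- two_sided_p(res$beta / res$se)
  }
  df <- data.frame(variant_id = panel$map$variant_id, chrom = panel$map$chrom,
                   pos = panel$map$pos, effect_allele = "A", other_allele = "G",
                   eaf = colMeans(g) / 2, beta = res$beta, se = res$se,
                   pval = pmax(res$pval, 1e-300),  # keep extreme hits representable
                   n = n, stringsAsFactors = FALSE)
  bad <- !is.finite(df$beta) | !is.finite(df$se)
  if (any(bad)) {
    msg("summary_stats(%s): dropped %d variant(s) (separation or zero variance)",
        trait_id, sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  n_case <- if (trait_type == "binary") sum(traits == 1) else NA_integer_
  n_control <- if (trait_type == "binary") sum(traits == 0) else NA_integer_
  summary_table(df, trait_id = trait_id, trait_type = trait_type,
                n_case = n_case, n_control = n_control, check_pz = FALSE)
}

#' Simulate a complete summary-statistic study
#'
#' Panel + causal chain + the three marginal summary tables (exposure,
#' mediator, binary outcome), with the generating truth attached for
#' recovery tests.
#'
#' @param scenario a [simulation_scenario()].
#' @return An object of class `simulated_study`: list with `panel`,
#'   `tables` (named `exposure`, `mediator`, `outcome`), `truth`, `scenario`.
#' @export
simulate_study <- function(scenario) {
  panel <- simulate_panel(scenario)
  chain <- simulate_chain(panel, scenario)
  tables <- list(
    exposure = summary_stats(chain$exposure, panel, "quantitative", "exposure"),
    mediator = summary_stats(chain$mediator, panel, "quantitative", "mediator"),
    outcome = summary_stats(chain$outcome, panel, "binary", "outcome"))
  structure(list(panel = panel, tables = tables, truth = chain$truth,
                 scenario = scenario),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study: n = %d, %d variants, seed %d\n",
              x$scenario$n_individuals, x$scenario$n_variants, x$scenario$seed))
  cat(sprintf("  chain: a = %.3f, b = %.3f, c' = %.3f, prevalence %.3f\n",
              x$scenario$a, x$scenario$b, x$scenario$c_prime,
              x$truth$prevalence_attained))
  invisible(x)
}

#' Named simulation presets
#'
#' Deterministic scenarios covering the analyses the package automates:
#' \describe{
#'   \item{`null`}{heritable exposure and mediator, no causal chain
#'     (a = b = c' = 0); type-I calibration.}
#'   \item{`shared_causal`}{one strong cis-pQTL drives the mediator and, via
#'     the mediator, the outcome: SMR signal with HEIDI pass and
#'     colocalization H4.}
#'   \item{`linkage`}{distinct causal variants in moderate LD (target dosage
#'     r-squared about 0.4) drive mediator and outcome with opposite signs:
#'     HEIDI rejection and colocalization H3.}
#'   \item{`mediation_chain`}{effect sizes shaped like the worked mediation
#'     example (a = -0.045, b = -0.062, total about 0.097 with direct effect
#'     c' making up the rest).}
#' }
#'
#' @param name preset name; omit to list all presets.
#' @param ... overrides forwarded to [simulation_scenario()] (e.g. a smaller
#'   `n_individuals` for quick runs).
#' @return A `simulation_scenario`, or a named list of them if `name` is
#'   missing.
#' @export
scenario_presets <- function(name = NULL, ...) {
  defaults <- list(
    null = list(a = 0, b = 0, c_prime = 0, seed = 201L),
    shared_causal = list(n_individuals = 60000, n_variants = 40,
                         n_blocks = 1, rho = 0.45,
                         a = 0, b = 1.0, c_prime = 0, h2_exposure = 0.05,
                         n_causal_exposure = 2, seed = 202L),
    linkage = list(n_individuals = 60000, n_variants = 40,
                   n_blocks = 1, rho = 0.63,
                   a = 0, b = 0, c_prime = 0, h2_exposure = 0.05,
                   n_causal_exposure = 2,
                   outcome_direct = stats::setNames(-0.35, "24"),
                   seed = 203L),
    mediation_chain = list(seed = 204L)
  )
  build <- function(nm, overrides) {
    sc <- do.call(simulation_scenario,
                  utils::modifyList(defaults[[nm]], overrides))
    if (nm %in% c("shared_causal", "linkage"))
      sc$causal_mediator <- list(idx = 20L, effects = 0.3)
    sc
  }
  if (is.null(name))
    return(stats::setNames(lapply(names(defaults), build, overrides = list(...)),
                           names(defaults)))
  if (!name %in% names(defaults))
    stop("unknown preset: ", name, "; available: ",
         paste(names(defaults), collapse = ", "))
  build(name, list(...))
}

#' Asymptotic sampler of region-level marginal summary statistics
#'
#' Draws marginal effect estimates for a region directly from their joint
#' asymptotic distribution given LD, skipping individual-level data: with
#' standardized genotypes and trait, the marginal effects are `R %*% lambda`
#' (`lambda` = joint causal effects in SD units) and the estimates are
#' multivariate normal around them with covariance `R / n`. This is the
#' standard large-sample model for GWAS z-statistics under LD and is used for
#' replicate-heavy calibration of SMR/HEIDI and colocalization operating
#' characteristics; the individual-level generator ([simulate_study()])
#' remains the end-to-end path.
#'
#' @param R LD correlation matrix (variant ids as dimnames, or ids are
#'   synthesised).
#' @param lambda joint causal effects per variant (SD units), length
#'   `ncol(R)`.
#' @param n effective sample size.
#' @param trait_id,trait_type forwarded to [summary_table()].
#' @return A [summary_table()] on the standardized scale (`se = 1/sqrt(n)`).
#' @export
simulate_region_stats <- function(R, lambda, n, trait_id = "trait",
                                  trait_type = "quantitative") {
  R <- as.matrix(R)
  m <- ncol(R)
  stopifnot(length(lambda) == m)
  ids <- colnames(R) %||% sprintf("rs%05d", seq_len(m))
  L <- chol(R + diag(1e-8, m))
  bmarg <- as.vector(R %*% lambda)
  bhat <- bmarg + as.vector(crossprod(L, stats::rnorm(m))) / sqrt(n)
  se <- rep(1 / sqrt(n), m)
  df <- data.frame(variant_id = ids, chrom = "1", pos = seq_len(m) * 10000L,
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = bhat, se = se,
                   pval = pmax(two_sided_p(bhat / se), 1e-300),
                   n = n, stringsAsFactors = FALSE)
  summary_table(df, trait_id = trait_id, trait_type = trait_type,
                check_pz = FALSE)
}

#' Equicorrelation LD matrix helper
#' @param m number of variants.
#' @param rho common pairwise correlation.
#' @param ids optional variant ids.
#' @return An `ld_matrix`.
#' @export
ld_equicorrelation <- function(m, rho, ids = sprintf("rs%05d", seq_len(m))) {
  R <- matrix(rho, m, m)
  diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  as_ld_matrix(R)
}
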