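test_that("Wald ratios: arithmetic, zero outcome, sign symmetry", {
  d <- data.frame(variant_id = "v1", beta_exp = 0.2, se_exp = 0.01,
                  beta_out = 0.1, se_out = 0.05)
  r <- wald_ratios(d)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se_ratio, 0.25)
  expect_equal(r$weight, 16)
  d$beta_out <- 0
  expect_equal(wald_ratios(d)$ratio, 0)
  d2 <- data.frame(beta_exp = -0.2, se_exp = 0.01, beta_out = -0.1,
                   se_out = 0.05)
  expect_equal(wald_ratios(d2)$ratio, 0.5)
  expect_equal(wald_ratios(d2)$se_ratio, 0.25)
  d3 <- data.frame(variant_id = "bad", beta_exp = 0, se_exp = 0.01,
                   beta_out = 0.1, se_out = 0.05)
  expect_error(wald_ratios(d3), "bad")
})

test_that("IVW equals the zero-intercept WLS oracle on random instances", {
  set.seed(101)
  for (rep in 1:20) {
    k <- 10
    bx <- rnorm(k, 0.2, 0.05)
    sy <- runif(k, 0.01, 0.05)
    by <- 0.3 * bx + rnorm(k, 0, sy)
    d <- data.frame(beta_exp = bx, se_exp = 0.01, beta_out = by, se_out = sy)
    ratios <- wald_ratios(d)
    fit <- ivw(ratios, mode = "fixed")
    oracle <- wls_origin(bx, by, 1 / sy^2)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("IVW identities: single ratio, constant ratios, mode agreement", {
  one <- data.frame(beta_exp = 0.2, se_exp = 0.01, beta_out = 0.08,
                    se_out = 0.03)
  r1 <- wald_ratios(one)
  f1 <- ivw(r1, "fixed")
  expect_equal(f1$beta, r1$ratio)
  expect_equal(f1$se, r1$se_ratio)

  const <- data.frame(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01,
                      beta_out = c(0.07, 0.14, 0.28),
                      se_out = c(0.02, 0.04, 0.08))
  rc <- wald_ratios(const)
  ff <- ivw(rc, "fixed"); fm <- ivw(rc, "multiplicative_random")
  expect_equal(ff$beta, 0.7)
  expect_equal(fm$beta, 0.7)
  expect_equal(ff$q, 0, tolerance = 1e-12)
  expect_equal(ff$se, fm$se)  # Q = 0: the floor keeps the fixed SE
})

test_that("MR-Egger recovers an exact line and matches the lm oracle", {
  x <- c(0.1, 0.2, 0.3, 0.5)
  y <- 0.1 + 0.5 * x
  d <- data.frame(beta_exp = x, se_exp = 0.01, beta_out = y,
                  se_out = c(0.02, 0.03, 0.02, 0.04))
  fit <- mr_egger(d)
  expect_equal(fit$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$q, 0, tolerance = 1e-16)

  set.seed(7)
  y2 <- 0.05 + 0.4 * x + rnorm(4, 0, 0.03)
  d2 <- data.frame(beta_exp = x, se_exp = 0.01, beta_out = y2,
                   se_out = c(0.02, 0.03, 0.02, 0.04))
  fit2 <- mr_egger(d2)
  lmfit <- lm(y2 ~ x, weights = 1 / d2$se_out^2)
  sm <- summary(lmfit)
  expect_equal(fit2$beta, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit2$egger_intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  # lm's SEs use sigma-hat; ours floor the scaling at 1
  scale_ratio <- max(1, sm$sigma^2) / sm$sigma^2
  expect_equal(fit2$se^2, unname(sm$coefficients[2, 2]^2) * scale_ratio,
               tolerance = 1e-8)
  expect_error(mr_egger(d[1:2, ]), "3")
})

test_that("Egger slope agrees with IVW when pleiotropy is absent", {
  set.seed(12)
  k <- 50
  bx <- rnorm(k, 0.3, 0.05)
  sy <- rep(0.01, k)
  by <- 0.25 * bx + rnorm(k, 0, sy)
  d <- data.frame(beta_exp = bx, se_exp = 1e-4, beta_out = by, se_out = sy)
  e <- mr_egger(d)
  i <- ivw(wald_ratios(d), "fixed")
  expect_lt(abs(e$beta - i$beta), 3 * e$se)
  expect_lt(abs(e$egger_intercept), 3 * e$intercept_se)
})

test_that("weighted median: constants, majority weight, crossing oracle", {
  const <- data.frame(ratio = rep(0.4, 3), se_ratio = c(0.1, 0.2, 0.3))
  const$weight <- 1 / const$se_ratio^2
  wm <- weighted_median(const, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.4)

  # one ratio with > 50% of total weight is returned
  dom <- data.frame(ratio = c(1, 2, 3), se_ratio = c(0.05, 0.5, 0.5))
  dom$weight <- 1 / dom$se_ratio^2   # weights ~ (400, 4, 4)
  expect_equal(weighted_median(dom, n_boot = 200, seed = 1)$beta, 1)

  # 5-ratio instance against an explicit cumulative-weight crossing
  r <- c(0.2, 0.5, 0.1, 0.9, 0.4)
  w <- c(1, 2, 3, 1, 4)
  ord <- order(r)
  cw <- cumsum(w[ord]) / sum(w)
  i <- which(cw >= 0.5)[1]
  expected <- if (i == 1) r[ord][1] else {
    r0 <- r[ord][i - 1]; r1 <- r[ord][i]
    r0 + (0.5 - cw[i - 1]) / (cw[i] - cw[i - 1]) * (r1 - r0)
  }
  d5 <- data.frame(ratio = r, se_ratio = 1 / sqrt(w), weight = w)
  expect_equal(weighted_median(d5, n_boot = 200, seed = 1)$beta, expected,
               tolerance = 1e-12)
})

test_that("weighted-median bootstrap is seeded and leaves the RNG alone", {
  d <- data.frame(ratio = c(0.1, 0.3, 0.2, 0.5), se_ratio = c(0.1, 0.2, 0.1, 0.3))
  d$weight <- 1 / d$se_ratio^2
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  f1 <- weighted_median(d, n_boot = 300, seed = 5)
  after <- rnorm(1)
  f2 <- weighted_median(d, n_boot = 300, seed = 5)
  expect_identical(f1$se, f2$se)
  expect_identical(before, after)  # caller's stream untouched
  expect_warning(weighted_median(d, n_boot = 50, seed = 1), "unstable")
})

test_that("maximum likelihood matches a grid-search oracle and exact limits", {
  d <- data.frame(beta_exp = c(0.2, 0.35, 0.15), se_exp = c(0.02, 0.03, 0.02),
                  beta_out = c(0.09, 0.13, 0.08), se_out = c(0.03, 0.02, 0.03))
  fit <- max_likelihood(d)
  grid <- seq(-1, 2, by = 1e-6)
  obj <- vapply(grid, function(th)
    sum((d$beta_out - th * d$beta_exp)^2 / (d$se_out^2 + th^2 * d$se_exp^2)),
    numeric(1))
  expect_equal(fit$beta, grid[which.min(obj)], tolerance = 2e-6)

  # noiseless proportional effects give the exact constant
  dp <- data.frame(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.02,
                   beta_out = c(0.06, 0.12, 0.24), se_out = 0.02)
  expect_equal(max_likelihood(dp)$beta, 0.6, tolerance = 1e-8)

  # se_exp -> 0: ML approaches the IVW estimate
  set.seed(3)
  k <- 20
  bx <- rnorm(k, 0.3, 0.1)
  by <- 0.2 * bx + rnorm(k, 0, 0.01)
  dl <- data.frame(beta_exp = bx, se_exp = 1e-8, beta_out = by, se_out = 0.01)
  expect_lt(abs(max_likelihood(dl)$beta - ivw(wald_ratios(dl), "fixed")$beta),
            1e-3)
  expect_error(max_likelihood(dp[1, , drop = FALSE]), "2")
})

test_that("the mr() fit dispatches methods, respects minima, exposes S3 methods", {
  d <- data.frame(beta_exp = c(0.2, 0.3, 0.25, 0.4), se_exp = 0.02,
                  beta_out = c(0.1, 0.16, 0.12, 0.21), se_out = 0.02)
  fit <- mr(d, seed = 11)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw_mre", "ivw_fixed", "egger", "weighted_median",
                    "max_likelihood"))
  expect_true(all(fit$estimates$or == exp(fit$estimates$beta)))
  expect_true(all(fit$estimates$or_lo < fit$estimates$or_hi))
  # p-values match the stated conventions
  est <- fit$estimates
  normal_rows <- est$method %in% c("ivw_mre", "ivw_fixed", "weighted_median",
                                   "max_likelihood")
  expect_equal(est$pval[normal_rows],
               2 * pnorm(-abs(est$beta[normal_rows] / est$se[normal_rows])))
  eg <- est[est$method == "egger", ]
  expect_equal(eg$pval, 2 * pt(-abs(eg$beta / eg$se), df = eg$n_snp - 2))

  expect_named(coef(fit), est$method)
  ci <- confint(fit)
  expect_equal(dim(ci), c(nrow(est), 2))
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_output(print(fit), "ivw_mre")

  # single instrument: Wald ratio only
  w <- mr(d[1, ])
  expect_equal(w$estimates$method, "wald")
  # two instruments: Egger and weighted median skipped with a message
  expect_message(f2 <- mr(d[1:2, ]), "skipping")
  expect_false(any(c("egger", "weighted_median") %in% f2$estimates$method))
})

test_that("Egger intercept p-values are uniform under no pleiotropy", {
  # residuals are overdispersed relative to the reported SEs, the regime the
  # multiplicative-random-effects scaling assumes; with exactly homoskedastic
  # noise the floor at 1 makes the intercept test conservative, never invalid
  set.seed(202)
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    k <- 20
    bx <- rnorm(k, 0.3, 0.05)
    sy <- rep(0.02, k)
    by <- 0.1 * bx + rnorm(k, 0, 1.7 * sy)
    mr_egger(data.frame(beta_exp = bx, se_exp = 1e-6, beta_out = by,
                        se_out = sy))$intercept_pval
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # homoskedastic case: conservative (type I at or below nominal)
  set.seed(203)
  pv2 <- vapply(seq_len(reps), function(i) {
    k <- 20
    bx <- rnorm(k, 0.3, 0.05)
    sy <- rep(0.02, k)
    by <- 0.1 * bx + rnorm(k, 0, sy)
    mr_egger(data.frame(beta_exp = bx, se_exp = 1e-6, beta_out = by,
                        se_out = sy))$intercept_pval
  }, numeric(1))
  expect_lt(mean(pv2 < 0.05), 0.05 + 2.576 * sqrt(0.05 * 0.95 / reps))
})

test_that("IVW and ML recover the causal effect from the individual-level chain", {
  ests <- t(vapply(1:10, function(s) {
    sc <- scenario_presets("mediation_chain", n_individuals = 20000,
                           n_variants = 100, n_blocks = 10,
                           a = 0.2, n_causal_exposure = 20,
                           n_causal_mediator = 20, seed = 400 + s)
    st <- suppressMessages(simulate_study(sc))
    iv <- suppressMessages(select_instruments(st$tables$exposure,
                                              st$tables$mediator, st$panel,
                                              p_threshold = 1e-5))
    c(ivw = ivw(wald_ratios(iv$data), "fixed")$beta,
      ml = max_likelihood(iv$data)$beta)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, "ivw"]) - 0.2), 0.02)
  expect_lt(abs(mean(ests[, "ml"]) - 0.2), 0.02)
})

test_that("odds-ratio conversions reproduce printed effect sizes", {
  expect_equal(round(or_to_beta(1.102), 3), 0.097)
  expect_equal(round(or_to_beta(0.956), 3), -0.045)
  expect_equal(or_to_beta(1), 0)
  expect_equal(beta_to_or(or_to_beta(1.37)), 1.37, tolerance = 1e-12)
  expect_equal(ci_to_se(0.139, 0.889),
               (log(0.889) - log(0.139)) / (2 * qnorm(0.975)),
               tolerance = 1e-6)
  expect_error(or_to_beta(-1), "positive")
  expect_error(ci_to_se(0.9, 0.5), "upper")
})
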