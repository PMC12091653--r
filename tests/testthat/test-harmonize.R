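test_that("allele alignment: identical, swapped and mismatched alleles", {
  e <- make_table(2, effect_allele = c("A", "A"), other_allele = c("G", "G"),
                  beta = c(0.2, 0.2), eaf = 0.3)
  # same orientation
  o_same <- make_table(2, effect_allele = c("A", "A"), other_allele = c("G", "G"),
                       beta = c(0.3, 0.3), eaf = 0.3)
  h <- suppressMessages(harmonize(e, o_same))
  expect_true(all(h$status == "kept"))
  expect_false(any(h$flipped))
  expect_equal(h$beta_out, c(0.3, 0.3))

  # swapped alleles: beta negated, eaf reflected
  o_swap <- make_table(2, effect_allele = c("G", "G"), other_allele = c("A", "A"),
                       beta = c(0.3, 0.3), eaf = 0.7)
  h2 <- suppressMessages(harmonize(e, o_swap))
  expect_true(all(h2$flipped))
  expect_equal(h2$beta_out, c(-0.3, -0.3))
  expect_equal(h2$eaf_out, c(0.3, 0.3))

  # mismatched allele pair
  o_bad <- make_table(2, effect_allele = c("A", "A"), other_allele = c("C", "C"),
                      beta = 0.3, eaf = 0.3)
  h3 <- suppressMessages(harmonize(e, o_bad))
  expect_true(all(h3$status == "dropped_allele_mismatch"))
})

test_that("palindromic variants follow the frequency rule table", {
  pal_case <- function(eaf_exp, eaf_out) {
    e <- make_table(1, effect_allele = "A", other_allele = "T", eaf = eaf_exp,
                    beta = 0.2)
    o <- make_table(1, effect_allele = "A", other_allele = "T", eaf = eaf_out,
                    beta = 0.3)
    suppressMessages(harmonize(e, o))
  }
  # ambiguous frequency on either side drops the variant
  for (pair in list(c(0.50, 0.30), c(0.30, 0.50), c(0.44, 0.30),
                    c(0.30, 0.56), c(NA, 0.30))) {
    h <- pal_case(pair[1], pair[2])
    expect_equal(h$status, "dropped_palindromic",
                 info = paste(pair, collapse = "/"))
  }
  # both clear, same side: kept unflipped
  h_same <- pal_case(0.20, 0.25)
  expect_equal(h_same$status, "kept")
  expect_false(h_same$flipped)
  expect_equal(h_same$beta_out, 0.3)
  # opposite sides of 0.5: treated as strand flip
  h_opp <- pal_case(0.20, 0.80)
  expect_equal(h_opp$status, "kept")
  expect_true(h_opp$flipped)
  expect_equal(h_opp$beta_out, -0.3)
  expect_equal(h_opp$eaf_out, 0.2)
  # indel alleles never enter palindrome logic
  e <- make_table(1, effect_allele = "AT", other_allele = "A", eaf = 0.5)
  o <- make_table(1, effect_allele = "AT", other_allele = "A", eaf = 0.5,
                  beta = 0.3)
  expect_equal(suppressMessages(harmonize(e, o))$status, "kept")
})

test_that("allele-frequency discordance above 0.2 is dropped with status", {
  e <- make_table(1, eaf = 0.10)
  o <- make_table(1, eaf = 0.35, beta = 0.3)
  h <- suppressMessages(harmonize(e, o))
  expect_equal(h$status, "dropped_af_discordant")
  # boundary: exactly 0.2 is tolerated
  o2 <- make_table(1, eaf = 0.30, beta = 0.3)
  expect_equal(suppressMessages(harmonize(e, o2))$status, "kept")
})

test_that("harmonization is involution-safe and errors on disjoint tables", {
  e <- make_table(3, effect_allele = c("A", "C", "T"),
                  other_allele = c("G", "A", "C"),
                  beta = c(0.1, -0.2, 0.3), eaf = c(0.2, 0.6, 0.35))
  o <- make_table(3, effect_allele = c("G", "C", "T"),
                  other_allele = c("A", "A", "C"),
                  beta = c(0.5, 0.1, -0.2), eaf = c(0.8, 0.6, 0.35))
  h1 <- suppressMessages(harmonize(e, o))
  # rebuild outcome table from harmonized effects; nothing should change
  o2 <- o
  o2$beta <- h1$beta_out[match(o2$variant_id, h1$variant_id)]
  o2$eaf <- h1$eaf_out[match(o2$variant_id, h1$variant_id)]
  o2$effect_allele <- h1$effect_allele[match(o2$variant_id, h1$variant_id)]
  o2$other_allele <- h1$other_allele[match(o2$variant_id, h1$variant_id)]
  h2 <- suppressMessages(harmonize(e, o2))
  expect_false(any(h2$flipped))
  expect_equal(h2$beta_out, h1$beta_out)

  far <- make_table(2, variant_id = c("zz1", "zz2"))
  expect_error(suppressMessages(harmonize(e, far)), "no shared variants")
})

test_that("greedy clumping follows the hand-simulated trace", {
  ids <- paste0("v", 1:5)
  rec <- data.frame(variant_id = ids, chrom = "1", pos = c(100, 200, 300, 400, 500) * 1000L,
                    pval = c(1e-8, 1e-6, 1e-7, 1e-5, 1e-4),
                    stringsAsFactors = FALSE)
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- 0.95   # v1 tags v2
  R[3, 4] <- R[4, 3] <- 0.95   # v3 tags v4
  dimnames(R) <- list(ids, ids)
  ld <- as_ld_matrix(R)
  # greedy: keep v1 (retire v2), keep v3 (retire v4), keep v5
  expect_equal(clump(rec, ld, r2_threshold = 0.1, window_kb = 10000),
               c("v1", "v3", "v5"))
  # all independent: everything retained, ordered by p
  expect_equal(clump(rec, as_ld_matrix(`dimnames<-`(diag(5), list(ids, ids))),
                     r2_threshold = 0.1),
               ids[order(rec$pval)])
  # dominance between two correlated variants
  rec2 <- rec[1:2, ]
  expect_equal(clump(rec2, ld, r2_threshold = 0.1), "v1")
  # outside the window the correlation is irrelevant
  rec3 <- rec[1:2, ]
  rec3$pos <- c(0L, 20000000L)
  expect_equal(clump(rec3, ld, r2_threshold = 0.1, window_kb = 10000),
               c("v1", "v2"))
  # invariant to input row order
  shuffled <- rec[c(4, 1, 5, 3, 2), ]
  expect_equal(clump(shuffled, ld, r2_threshold = 0.1), c("v1", "v3", "v5"))
  expect_error(clump(rbind(rec, data.frame(variant_id = "v9", chrom = "1",
                                           pos = 1L, pval = 0.5)), ld),
               "v9")
})

test_that("F statistic is the squared z-score with the boundary kept", {
  expect_equal(f_statistic(0.1, 0.03), (0.1 / 0.03)^2)
  expect_equal(f_statistic(0.1, 0.04), 6.25)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_error(f_statistic(0.1, 0), "positive")
  # selection keeps F exactly at the floor
  e <- make_table(2, beta = c(sqrt(10) * 0.02, 0.02), se = 0.02, pos = c(1e5, 3e7))
  o <- make_table(2, beta = 0.1, se = 0.02, pos = c(1e5, 3e7))
  ld <- ld_equicorrelation(2, 0, ids = e$variant_id)
  iv <- suppressMessages(select_instruments(e, o, ld, p_threshold = 1))
  expect_equal(iv$data$variant_id, e$variant_id[1])
  expect_equal(min(iv$f_stats), 10, tolerance = 1e-12)
})

test_that("instrument selection: monotone in the p threshold, typed when empty", {
  set.seed(42)
  sc <- scenario_presets("mediation_chain", n_individuals = 3000,
                         n_variants = 60, n_blocks = 6,
                         n_causal_exposure = 8, n_causal_mediator = 8,
                         seed = 31)
  st <- suppressMessages(simulate_study(sc))
  sizes <- vapply(c(1e-4, 1e-5, 1e-6, 1e-8), function(p) {
    iv <- suppressMessages(select_instruments(st$tables$exposure,
                                              st$tables$outcome, st$panel,
                                              p_threshold = p))
    nrow(iv$data)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # iv-set invariants
  iv <- suppressMessages(select_instruments(st$tables$exposure,
                                            st$tables$outcome, st$panel,
                                            p_threshold = 1e-5))
  expect_true(all(iv$f_stats >= 10))
  expect_true(all(iv$data$pval_exp <= 1e-5))
  r2 <- unclass(compute_ld(st$panel, iv$data$variant_id))^2
  same_window <- outer(iv$data$chrom, iv$data$chrom, "==") &
    outer(iv$data$pos, iv$data$pos, function(a, b) abs(a - b) <= 1e7)
  expect_true(all(r2[upper.tri(r2)] < 0.001 | !same_window[upper.tri(r2)]))
  # no signal at an impossible threshold: typed condition, not an error
  none <- suppressMessages(select_instruments(st$tables$exposure,
                                              st$tables$outcome, st$panel,
                                              p_threshold = 1e-300))
  expect_equal(none$status, "no_instruments")
  expect_equal(nrow(none$data), 0)
})

test_that("a heritable exposure yields an instrument count in the lipid-scan range", {
  sc <- scenario_presets("mediation_chain", n_individuals = 6000,
                         n_variants = 100, n_blocks = 10,
                         n_causal_exposure = 10, n_causal_mediator = 10,
                         seed = 77)
  st <- suppressMessages(simulate_study(sc))
  iv <- suppressMessages(select_instruments(st$tables$exposure,
                                            st$tables$outcome, st$panel,
                                            p_threshold = 1e-5))
  expect_gte(nrow(iv$data), 4)
  expect_lte(nrow(iv$data), 26)
})
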