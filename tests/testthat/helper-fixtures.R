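# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# a minimal valid summary-statistic data frame, override any column
make_records <- function(n = 3, variant_id = sprintf("rs%03d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.02,
                         pval = NULL, n_samples = 10000) {
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, chrom = rep_len(chrom, n),
             pos = rep_len(pos, n),
             effect_allele = rep_len(effect_allele, n),
             other_allele = rep_len(other_allele, n),
             eaf = rep_len(eaf, n), beta = beta, se = se,
             pval = rep_len(pval, n), n = rep_len(n_samples, n),
             stringsAsFactors = FALSE)
}

make_table <- function(..., trait_id = "trait", trait_type = "quantitative") {
  suppressMessages(summary_table(make_records(...), trait_id = trait_id,
                                 trait_type = trait_type, check_pz = FALSE))
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# independent zero-intercept weighted least squares (the IVW oracle)
wls_origin <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  list(beta = beta, se = sqrt(1 / sum(w * x^2)))
}

# region pair with a single shared causal variant, drawn from the asymptotic
# summary-statistic model (standardized scale)
sim_shared_region <- function(m = 30, rho = 0.6, n1 = 30000, n2 = 50000,
                              l1 = 0.12, bxy = -0.3, causal = 1L) {
  R <- ld_equicorrelation(m, rho)
  lam1 <- replace(numeric(m), causal, l1)
  lam2 <- bxy * lam1
  list(pqtl = simulate_region_stats(R, lam1, n1, "protein"),
       gwas = simulate_region_stats(R, lam2, n2, "disease", "binary"),
       R = R, causal = causal)
}

# region pair with distinct causal variants in LD
sim_linkage_region <- function(m = 30, rho = 0.6, n1 = 30000, n2 = 50000,
                               l1 = 0.12, l2 = -0.05,
                               causal1 = 5L, causal2 = 10L) {
  R <- ld_equicorrelation(m, rho)
  lam1 <- replace(numeric(m), causal1, l1)
  lam2 <- replace(numeric(m), causal2, l2)
  list(pqtl = simulate_region_stats(R, lam1, n1, "protein"),
       gwas = simulate_region_stats(R, lam2, n2, "disease", "binary"),
       R = R, causal1 = causal1, causal2 = causal2)
}

# brute-force colocalization oracle: enumerate every causal configuration
coloc_enumerate <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(l1)
  bf1 <- exp(l1); bf2 <- exp(l2)
  h <- c(h0 = 1, h1 = p1 * sum(bf1), h2 = p2 * sum(bf2), h3 = 0,
         h4 = p12 * sum(bf1 * bf2))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) h["h3"] <- h["h3"] + p1 * p2 * bf1[i] * bf2[j]
  h / sum(h)
}
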