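---
title: "Two-step MR mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmr)
```

## The scientific question

Circulating lipid species are associated with gastric-cancer risk, and so
are several plasma proteins. `medmr` asks the causal version of the joint
question: how much of the effect of a lipid exposure on a binary disease
outcome travels *through* a protein mediator? The design is two-sample
Mendelian randomization (MR) throughout — genetic variants serve as
instruments, and only per-variant marginal GWAS summary statistics (beta,
SE, p, allele frequencies, sample size) are required, never individual-level
data.

The analysis has three legs, each itself an MR fit:

1. exposure → outcome (the *total* effect, log-OR per SD of exposure),
2. exposure → mediator (*direct effect A*, SD per SD),
3. mediator → outcome (*direct effect B*, log-OR per SD).

The mediated (indirect) effect is the product of coefficients `a * b`; the
proportion mediated is `100 * a * b / total`.

## Instruments

A variant qualifies as an instrument for a trait when it is strongly
associated with that trait (p ≤ 5×10⁻⁸ for proteins; p ≤ 1×10⁻⁵ for lipid
species, whose architecture is polygenic with many sub-genome-wide signals),
is approximately independent of other instruments (greedy clumping at
r² < 0.001 within 10,000 kb windows, smallest p first, ties broken by
position then id so the output is order-invariant), and is not weak:
per-variant F = (β/se)² ≥ 10, the squared-z form that needs no per-variant
R². The boundary F = 10 is retained — the filter excludes strictly below 10.

Harmonization aligns each shared variant to a common effect allele. Swapped
alleles negate the outcome beta and reflect its frequency. Palindromic
variants (A/T, C/G) carry no strand information in their allele labels, so
they are kept only when both studies report allele frequencies and both fall
outside the ambiguity window \[0.42, 0.58\]; frequencies on opposite sides
of 0.5 are interpreted as a strand flip. Indel alleles never enter
palindrome logic. Kept pairs whose frequencies still differ by more than 0.2
are dropped as discordant. All of these windows are configurable
(`medmr_config()`); the palindrome policy is this package's choice of the
common default, since reasonable software differs here.

## Estimators

With Wald ratios `r_i = beta_out/beta_exp` and first-order SEs
`se_out/|beta_exp|` (the second-order form that propagates the exposure SE
sits behind a flag):

- **IVW** is the weight-`1/se_i²` mean of the ratios, equivalently the
  zero-intercept weighted least-squares slope. The default mode is
  multiplicative random effects: the fixed-effects SE is scaled by
  `max(1, sqrt(Q/(k-1)))`, the usual floor-at-one overdispersion guard; the
  fixed-effects row is always reported alongside. Cochran's Q with k−1 df
  is the heterogeneity diagnostic.
- **MR-Egger** regresses outcome on exposure effects with a free intercept
  (weights `1/se_out²`) after orienting all exposure effects non-negative;
  the intercept estimates directional pleiotropy. SEs carry the same
  floor-at-one multiplicative scaling, and p-values use t with k−2 df. A
  consequence of the floor worth knowing: with *exactly* homoskedastic data
  the intercept test is mildly conservative (the test suite verifies type I
  at or below nominal there, and exact uniformity in the overdispersed
  regime the scaling assumes).
- **Weighted median** interpolates the sorted ratios at cumulative
  normalized weight 0.5; it is consistent while valid instruments hold at
  least half the weight. Its SE is the SD over 1000 parametric bootstrap
  replicates (`r_i* ~ N(r_i, se_i)`, weights fixed), run on a local seeded
  RNG stream (default seed 42, recorded in the fit) that never disturbs the
  caller's stream.
- **Maximum likelihood** models the observed effect pairs as independent
  normals around `(xi_i, theta * xi_i)`; profiling out the `xi_i`
  analytically leaves the one-dimensional objective
  `sum((by - theta*bx)^2 / (sy^2 + theta^2 sx^2))`, minimised by golden
  search to 1e-10 within a bracket centred on the IVW anchor. The SE comes
  from the numerical curvature of the profile log-likelihood; a
  non-positive curvature aborts with an error rather than reporting a bogus
  SE.

Single-instrument sets fall back to the Wald ratio. p-values are two-sided
normal except Egger's t.

## SMR and HEIDI

A proteome scan tests each protein through its top cis-pQTL (smallest p
within ±1000 kb of the gene, inclusive; ties broken by position). The SMR
statistic combines the QTL and GWAS z-scores,
`T = z1² z2² / (z1² + z2²)` against chi-square(1), with
`b_xy = beta_gwas/beta_qtl` and `se = |b_xy| sqrt(1/z1² + 1/z2²)`.

SMR cannot distinguish one shared causal variant from two distinct variants
in LD. HEIDI tests exactly that: for every eligible neighbour (QTL
p < 1.57×10⁻³, r² with the top variant in the open interval (0.05, 0.9),
capped at 20 by |z_qtl|, minimum 3 — the classical eligibility rules, all
configurable) it forms the deviation `d_i = b_xy(i) − b_xy(top)`, builds the
covariance of the d's by first-order propagation from the LD correlations
and per-variant SEs, and refers `T = Σ z_d²` to a Satterthwaite scaled
chi-square matching the mean and variance of the correlated quadratic form.
The two-moment tail approximation avoids eigen-decompositions and is
accurate at the 0.01 decision threshold used here (operating characteristics
are measured in the test suite: ≥ 90% pass under a shared causal variant,
≥ 80% rejection under linkage with distinct variants); it is an
approximation, and p-values deep in the tail should not be over-read.
Fewer than three eligible neighbours leaves HEIDI undefined — such proteins
are never *passed* (linkage cannot be excluded), and the reason is recorded.

Scan-level significance applies Benjamini–Hochberg FDR (via
`stats::p.adjust`) across proteins at 0.05, and a protein passes only with
BH-adjusted p < 0.05 **and** HEIDI p ≥ 0.01.

## Colocalization

For a cis region shared by protein and disease, each variant contributes a
Wakefield log approximate Bayes factor
`labf = ½ log(V/(V+W)) + z² W / (2(V+W))` with `V = se²` and `W` the prior
effect variance (SD 0.15 for quantitative traits, 0.2 on the log-OR scale —
the canonical defaults, since only the configuration priors are dictated by
the analysis design: p1 = p2 = 1×10⁻⁴, p12 = 1×10⁻⁵). Hypothesis sums are
accumulated entirely in log space with log-sum-exp; the H3 double sum is the
product of marginals minus the diagonal, computed in O(n) with a `log1p`
guard for the near-cancellation when one shared signal dominates. A
single-variant region has PPH3 exactly 0. PPH4 > 0.6 is labelled strong.
The implementation is verified against exhaustive enumeration of every
causal configuration on small regions at 1e-10.

## Mediation and error propagation

`mediation = a * b`, `se = sqrt(a² se_b² + b² se_a²)` (first-order/delta
propagation, exact symmetry in the two legs), p from the normal
approximation — adequate for the small per-leg effects this design targets,
though the product of two normals is not normal and the p-value is
approximate near the null. The mediated proportion is signed,
`100 * a * b / total`, with the independence delta-method SE
`100 |ab/total| sqrt((se_ab/ab)² + (se_tot/total)²)`; the analysis design
names error propagation but not a formula, so the formula choice is exposed
in the output rather than hidden. When the mediation and total effects
disagree in sign (or |proportion| exceeds 100%) the result is annotated as
violating the additive mediation assumption rather than suppressed — such
pathways are reported with their arithmetic intact. Rounding (3 dp for
betas, 2 significant figures for percents) happens only at report time.

## The synthetic-data generator

`simulation_scenario()` + `simulate_study()` emulate the statistical shape
of the real inputs: a reference panel with block LD, a causal chain, and
marginal summary statistics obtained by actually running the per-variant
regressions (simple linear for quantitative traits, Newton–Raphson logistic
for the binary outcome, with separation flagged and dropped) — so the
estimators are exercised against the same kind of noise and LD-induced
correlation among neighbouring betas that real cohorts produce. Design
choices worth stating:

- **LD blocks.** Haplotypes are thresholded block-equicorrelated latent
  Gaussians; dosage = sum of two haplotypes. The latent correlation is
  calibrated through the tetrachoric relationship so the *dosage*
  correlation matches the requested `rho`. Because variants in strong LD
  necessarily have near-equal allele frequencies, MAF is drawn per block
  and only jittered (±0.01) within a block; blocks live on separate
  chromosomes so clumping windows and cis regions never straddle blocks.
- **Valid instruments by construction.** Exposure and mediator causal
  variants are placed in disjoint block sets; otherwise exposure
  instruments would tag the mediator's own genetic effects through LD and
  the exclusion restriction would fail by design rather than by hypothesis.
- **The binary outcome** is Bernoulli-logistic with the intercept solved by
  root-finding to hit the target prevalence (default 0.047, the case
  fraction of a 7921-case / 159,201-control design).
- **Chain defaults** mirror the worked mediation pathway: a = −0.045,
  b = −0.062, c′ = 0.094 (total ≈ 0.097), 500 variants in 10 blocks,
  n = 20,000 — a desk-scale stand-in, not a claim about any real cohort.
  Presets: `null`, `shared_causal`, `linkage` (distinct causal variants,
  opposite signs, dosage r² ≈ 0.4), `mediation_chain`; each carries a fixed
  seed, and every preset parameter can be overridden.
- The region presets use n = 60,000 so the binary-outcome GWAS has
  realistic power (expected z ≈ 6 at the causal variant); at rare-disease
  prevalence a 20,000-person cohort would leave the shared-causal signal
  at z ≈ 3 and any single run uninformative.
- `simulate_region_stats()` draws marginal betas directly from their joint
  asymptotic normal given LD (`beta ~ N(R lambda, R/n)` on the standardized
  scale). Replicate-heavy calibrations (HEIDI/coloc operating
  characteristics, null uniformity) use this sampler; end-to-end behaviour
  always goes through the individual-level generator.

What passing tests on these data do **not** show: robustness to real human
LD structure (no recombination-map irregularity, no ancestry admixture), to
imputation error, to sample overlap between exposure and outcome GWAS, or
to winner's-curse bias at marginal instruments. The generator's marginal
betas within a block are honestly correlated, but between-block
independence is cleaner than reality.

## Numerical choices and degenerate inputs

- p-values are validated into (0, 1]; generated scans clamp extreme hits at
  1e-300 so genuinely enormous z-scores stay representable rather than
  underflowing to an invalid 0.
- A stated p-value disagreeing with |beta/se| by more than 10% on the z
  scale warns and is *kept* — provenance beats recomputation.
- Zero-variance panel columns, absent variants, zero exposure betas and
  non-positive SEs are hard errors naming the offending variant; an empty
  instrument set after selection is a typed condition (`no_instruments`),
  because a lipid with no instruments is a result, not a crash.
- Clumping and top-QTL ties break deterministically (position, then id);
  windows are inclusive in kb on both sides; positions are 1-based.
- The weighted-median bootstrap and every simulation restore the caller's
  RNG state; seeds are part of scenarios and echoed into report headers
  together with a config fingerprint and the package version.

## Problem sizes used by the test suite

Unit and property tests run at n = 300–10,000 individuals and 20–240
variants; the replicated calibrations use 150–500 region-level replicates
and 150–300 individual-level cohorts of n = 4000 with 80 variants. These
sizes are the package's choice of a desk scale at which every property
being asserted (coverage, type-I rates, majority-vote operating
characteristics) is comfortably identified; all scale up by changing the
scenario arguments.

## Known limitations

- No Steiger directionality filtering, proxy-variant lookup, MR-PRESSO,
  multivariable MR, SuSiE-style multi-signal colocalization, or multi-SNP
  SMR; variant matching is by id only.
- The HEIDI tail is two-moment approximate; the mediation p-value is
  normal-approximate; the mediated-proportion CI assumes independent legs
  (two-sample designs make this reasonable, overlapping samples do not).
- OR confidence intervals are symmetric on the log-OR scale by
  construction; printed ORs from other software whose CIs are symmetric on
  the OR scale will not back-convert exactly.
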