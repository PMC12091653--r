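# internal helpers shared across modules

Z95 <- 1.959964

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# run expr with a local RNG state; restores the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# polynomial rolling hash over the deparsed object; short stable fingerprint
# for report headers (not cryptographic)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

msg <- function(...) message("[medmr] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default analysis configuration
#'
#' Central place for the thresholds used across instrument selection,
#' SMR/HEIDI, colocalization and mediation. Values mirror common two-sample MR
#' practice: genome-wide significance for protein instruments, a relaxed
#' threshold for polygenic lipid species, stringent LD pruning, and an
#' instrument-strength floor of F = 10.
#'
#' @param ... named overrides for any default entry.
#' @return A named list of class `medmr_config`.
#' @examples
#' cfg <- medmr_config(p_threshold_lipid = 1e-6)
#' cfg$clump_r2
#' @export
medmr_config <- function(...) {
  cfg <- list(
    p_threshold_lipid   = 1e-5,
    p_threshold_protein = 5e-8,
    clump_r2            = 0.001,
    clump_window_kb     = 10000,
    f_min               = 10,
    palindrome_window   = c(0.42, 0.58),
    max_af_diff         = 0.2,
    cis_window_kb       = 1000,
    heidi_p_eligible    = 1.57e-3,
    heidi_r2_range      = c(0.05, 0.9),
    heidi_max_snps      = 20,
    heidi_min_snps      = 3,
    heidi_alpha         = 0.01,
    coloc_p1            = 1e-4,
    coloc_p2            = 1e-4,
    coloc_p12           = 1e-5,
    coloc_sd_quant      = 0.15,
    coloc_sd_binary     = 0.2,
    coloc_strong_pph4   = 0.6,
    fdr_alpha           = 0.05,
    n_boot              = 1000,
    boot_seed           = 42,
    ivw_mode            = "multiplicative_random"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$clump_r2 > 0, cfg$clump_window_kb > 0, cfg$f_min >= 0)
  class(cfg) <- "medmr_config"
  cfg
}
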