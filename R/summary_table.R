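#' GWAS summary-statistic tables
#'
#' A `summary_table` is a validated data frame of per-variant marginal GWAS
#' associations for one trait, the common currency of all estimators in this
#' package. Columns: `variant_id`, `chrom`, `pos` (1-based bp),
#' `effect_allele`, `other_allele`, `eaf` (effect-allele frequency, may be
#' `NA`), `beta` (log-OR for binary traits, SD units for quantitative), `se`,
#' `pval`, `n`.
#'
#' Validation drops (with a reported count, never silently) rows with
#' non-positive `se`, `pval` outside (0, 1], `eaf` outside [0, 1], identical
#' alleles, non-positive `n`, or a duplicated `variant_id`. Alleles are
#' uppercased; records are sorted by (`chrom`, `pos`). When both `beta`/`se`
#' and `pval` are present and the implied |z| disagrees with the stated p-value
#' by more than 10% (two-sided normal approximation), a warning is emitted and
#' the stated p-value is kept: provenance wins over recomputation.
#'
#' @param records data frame with the columns listed above (`eaf` optional).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_case,n_control case/control counts, binary traits only.
#' @param check_pz check p-value/z-score consistency (default `TRUE`).
#' @return An object of class `summary_table` (a data frame with trait
#'   metadata attributes).
#' @examples
#' df <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = 0.1, se = 0.02, pval = 5.7e-7, n = 10000)
#' summary_table(df, trait_id = "lipid_x", trait_type = "quantitative")
#' @seealso [read_summary_table()], [write_summary_table()]
#' @export
summary_table <- function(records, trait_id, trait_type = c("quantitative", "binary"),
                          n_case = NA_integer_, n_control = NA_integer_,
                          check_pz = TRUE) {
  trait_type <- match.arg(trait_type)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("summary table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  records <- records[c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pval", "n")]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])

  ok <- is.finite(records$beta) & is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    is.finite(records$n) & records$n > 0 &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
    records$effect_allele != records$other_allele &
    grepl("^[ACGT]+$", records$effect_allele) &
    grepl("^[ACGT]+$", records$other_allele) &
    !is.na(records$pos)
  ok[is.na(ok)] <- FALSE
  n_drop <- sum(!ok)
  if (n_drop > 0)
    msg("trait %s: dropped %d invalid record(s) during validation", trait_id, n_drop)
  records <- records[ok, , drop = FALSE]

  dup <- duplicated(records$variant_id)
  if (any(dup)) {
    msg("trait %s: dropped %d duplicated variant id(s)", trait_id, sum(dup))
    records <- records[!dup, , drop = FALSE]
  }
  if (check_pz && nrow(records)) {
    z_stated <- stats::qnorm(pmax(records$pval, 1e-300) / 2, lower.tail = FALSE)
    z_impl <- abs(records$beta / records$se)
    comparable <- records$pval > 1e-280 & z_impl > 0
    rel <- abs(z_stated - z_impl) / pmax(z_impl, 1e-12)
    n_bad <- sum(comparable & rel > 0.10)
    if (n_bad > 0)
      warning(sprintf("trait %s: %d record(s) have pval inconsistent with beta/se (>10%% on the z scale); stated pval kept",
                      trait_id, n_bad), call. = FALSE)
  }
  records <- records[order(records$chrom, records$pos, records$variant_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_type = trait_type,
            n_case = as.integer(n_case), n_control = as.integer(n_control),
            n_dropped = n_drop,
            class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  if (!is.na(attr(x, "n_case")))
    cat(sprintf("  cases/controls: %d / %d\n", attr(x, "n_case"), attr(x, "n_control")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a GWAS summary-statistic table from TSV
#'
#' Expects a tab-separated file whose header names at least the nine required
#' columns (`eaf` is optional, any column order). Rows failing validation are
#' dropped with a reported count.
#'
#' @inheritParams summary_table
#' @param path path to a TSV file.
#' @return A [summary_table()].
#' @export
read_summary_table <- function(path, trait_id = basename(path),
                               trait_type = c("quantitative", "binary"),
                               n_case = NA_integer_, n_control = NA_integer_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("format error: empty summary-statistic file ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (nrow(df) == 0) stop("format error: no data rows in ", path)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  summary_table(df, trait_id = trait_id, trait_type = trait_type,
                n_case = n_case, n_control = n_control)
}

#' Write a summary table (or any result data frame) as TSV
#'
#' Floats are written with 10 significant digits; a commented header line
#' records provenance so a written file can be re-read by
#' [read_summary_table()] bit-stably after one normalization pass.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param header optional named list written as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path, header = NULL) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- formatC(v, digits = 10, format = "g")
    out[is.na(v)] <- "NA"
    out
  })
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    for (k in names(header))
      writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis results as TSV and JSON
#'
#' Emits one TSV and one JSON file per result kind (element of a named list),
#' with stable column order and 10-significant-digit floats; re-reading
#' reproduces values to that precision.
#'
#' @param results a named list of data frames (one per result kind), or a
#'   single data frame.
#' @param dir output directory (created if needed).
#' @param stem filename stem used when `results` is a single data frame.
#' @param header optional named list of provenance lines (seed, config hash,
#'   package version) written into each TSV.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, stem = "results", header = NULL) {
  if (is.data.frame(results)) results <- stats::setNames(list(results), stem)
  if (!length(results)) stop("write_report: empty result collection")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("write_report: results must be a named list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (kind in names(results)) {
    df <- as.data.frame(results[[kind]])
    tsv <- file.path(dir, paste0(kind, ".tsv"))
    write_summary_table(df, tsv, header = header)
    js <- file.path(dir, paste0(kind, ".json"))
    jsonlite::write_json(df, js, digits = 10, na = "null")
    files <- c(files, tsv, js)
  }
  invisible(files)
}
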