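#' Reference genotype panels and LD matrices
#'
#' A `reference_panel` holds an individuals x variants dosage matrix (values
#' in \[0, 2\]) plus a variant map (`variant_id`, `chrom`, `pos`). It stands in
#' for the external LD reference used for clumping, HEIDI and colocalization.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns;
#'   column names are variant ids.
#' @param map data frame with `variant_id`, `chrom`, `pos` matching the
#'   columns; if `NULL` a trivial single-chromosome map is synthesised.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) stop("dosage matrix must have variant ids as column names")
  if (anyDuplicated(colnames(dosages))) stop("duplicated variant ids in panel")
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(map))
    map <- data.frame(variant_id = colnames(dosages), chrom = "1",
                      pos = seq_len(ncol(dosages)) * 10000L,
                      stringsAsFactors = FALSE)
  if (!all(c("variant_id", "chrom", "pos") %in% names(map)))
    stop("panel map needs variant_id, chrom, pos")
  if (nrow(map) != ncol(dosages) || !all(map$variant_id == colnames(dosages)))
    stop("panel map does not match dosage columns")
  structure(list(dosages = dosages, map = map), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read a reference panel from a TSV dosage matrix
#'
#' The file is a plain TSV with a header row of variant ids and one row per
#' individual. An optional map TSV (`variant_id`, `chrom`, `pos`) supplies
#' positions.
#'
#' @param path dosage TSV path.
#' @param map_path optional variant map TSV path.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path, map_path = NULL) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", header = TRUE,
                                   check.names = FALSE, comment.char = "#"))
  storage.mode(m) <- "double"
  map <- if (!is.null(map_path))
    utils::read.delim(map_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = "#")
  reference_panel(m, map)
}

#' Write a reference panel dosage matrix (and map) as TSV
#' @param panel a [reference_panel()].
#' @param path dosage TSV path.
#' @param map_path optional map TSV path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path, map_path = NULL) {
  utils::write.table(panel$dosages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(panel$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Compute a linkage-disequilibrium matrix from panel dosages
#'
#' Pairwise Pearson correlations of dosage columns; the square of an entry is
#' the familiar LD r-squared used by clumping and HEIDI.
#'
#' @param panel a [reference_panel()].
#' @param ids variant ids to include (default: all).
#' @return A symmetric correlation matrix of class `ld_matrix` with unit
#'   diagonal, dimnames = variant ids.
#' @examples
#' g <- matrix(rbinom(200, 2, 0.3), 100, 2, dimnames = list(NULL, c("v1", "v2")))
#' compute_ld(reference_panel(g))
#' @export
compute_ld <- function(panel, ids = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(ids)) ids <- colnames(panel$dosages)
  missing_ids <- setdiff(ids, colnames(panel$dosages))
  if (length(missing_ids))
    stop("variant(s) absent from panel: ", paste(missing_ids, collapse = ", "))
  g <- panel$dosages[, ids, drop = FALSE]
  v <- apply(g, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance dosage column(s): ",
         paste(ids[v == 0], collapse = ", "))
  r <- stats::cor(g)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Coerce a plain matrix to an `ld_matrix`, validating its invariants
#' @param r square correlation matrix with variant-id dimnames.
#' @return The validated `ld_matrix`.
#' @export
as_ld_matrix <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    stop("LD matrix needs matching row/column variant ids")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (any(abs(r) > 1 + 1e-8)) stop("LD entries must lie in [-1, 1]")
  r <- (r + t(r)) / 2; diag(r) <- 1
  class(r) <- c("ld_matrix", class(unclass(r)))
  r
}

#' Read a precomputed LD matrix from a square TSV
#' @param path TSV with variant-id header; rows in the same order.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", header = TRUE,
                                   check.names = FALSE, comment.char = "#"))
  storage.mode(m) <- "double"
  rownames(m) <- colnames(m)
  as_ld_matrix(m)
}

# resolve a panel-or-LD argument to an ld_matrix covering `ids`
resolve_ld <- function(ld, ids) {
  if (inherits(ld, "reference_panel")) return(compute_ld(ld, ids))
  missing_ids <- setdiff(ids, colnames(ld))
  if (length(missing_ids))
    stop("variant(s) absent from LD matrix: ", paste(missing_ids, collapse = ", "))
  as_ld_matrix(unclass(ld)[ids, ids, drop = FALSE])
}
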