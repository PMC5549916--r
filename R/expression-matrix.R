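#' Expression matrix container
#'
#' Wraps a features-by-samples numeric matrix of expression values together
#' with an omic kind per feature (\code{"miRNA"} or \code{"mRNA"}) and a
#' scale flag. Feature IDs are the rownames, sample (patient) IDs the
#' colnames; both must be unique. Raw-scale values must be non-negative
#' (relative expression levels); log2-scale values are unrestricted.
#'
#' @param values numeric matrix, features in rows and samples in columns,
#'   with rownames and colnames set (may have zero rows or columns).
#' @param kind character vector giving the omic kind of each feature,
#'   \code{"miRNA"} or \code{"mRNA"}; a single value is recycled.
#' @param scale \code{"raw"} or \code{"log2"}.
#' @return An object of class \code{"expression_matrix"}: the matrix with
#'   attributes \code{kind} and \code{scale}.
#' @examples
#' m <- matrix(2^rexp(6), 2, 3,
#'             dimnames = list(c("hsa-miR-21", "hsa-miR-10b"),
#'                             c("P1", "P2", "P3")))
#' expression_matrix(m, kind = "miRNA")
#' @export
expression_matrix <- function(values, kind, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("'values' must have rownames (feature IDs)")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("'values' must have colnames (sample IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs")
  if (length(kind) == 1L) kind <- rep(kind, nrow(values))
  if (length(kind) != nrow(values))
    stop("'kind' must have one entry per feature")
  if (nrow(values) > 0 && !all(kind %in% c("miRNA", "mRNA")))
    stop("'kind' entries must be \"miRNA\" or \"mRNA\"")
  if (scale == "raw" && length(values) && any(values < 0, na.rm = TRUE))
    stop("raw-scale expression values must be non-negative")
  structure(values, kind = as.character(kind), scale = scale,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  k <- table(factor(attr(x, "kind"), levels = c("miRNA", "mRNA")))
  cat(sprintf("expression_matrix: %d features (%d miRNA, %d mRNA) x %d samples [%s scale]\n",
              nrow(x), k[["miRNA"]], k[["mRNA"]], ncol(x), attr(x, "scale")))
  invisible(x)
}

# subset rows/columns preserving kind + scale
.em_subset <- function(x, i = seq_len(nrow(x)), j = seq_len(ncol(x))) {
  v <- unclass(x)
  attr(v, "kind") <- attr(v, "scale") <- NULL
  expression_matrix(v[i, j, drop = FALSE], attr(x, "kind")[i], attr(x, "scale"))
}

#' @rdname expression_matrix
#' @param x an \code{expression_matrix}.
#' @export
feature_kinds <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  stats::setNames(attr(x, "kind"), rownames(x))
}

#' Read an expression TSV
#'
#' Expects the layout written by [write_fixture()] and common to
#' series-matrix-style exports: a header row of sample IDs, a first column
#' named \code{feature_id}, and one row per feature with float values.
#'
#' @param path file path.
#' @param kind omic kind of every feature in the file (one file per layer).
#' @param scale scale flag to attach, default \code{"raw"}.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, kind, scale = "raw") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 1L || names(d)[1] != "feature_id")
    stop("expected first column 'feature_id' in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d$feature_id)
  expression_matrix(m, kind = kind, scale = scale)
}

#' Read a clinical table
#'
#' @param path TSV with columns \code{sample_id} and a categorical target.
#' @param target_column name of the target column, default \code{"target"}.
#' @return data.frame with columns \code{sample_id} and \code{target}.
#' @export
read_clinical_tsv <- function(path, target_column = "target") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("clinical table lacks 'sample_id'")
  if (!target_column %in% names(d))
    stop("clinical table lacks target column '", target_column, "'")
  data.frame(sample_id = as.character(d$sample_id),
             target = as.character(d[[target_column]]),
             stringsAsFactors = FALSE)
}
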