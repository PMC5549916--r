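#' Discrete dataset for Bayesian-network scoring
#'
#' Holds integer-coded predictors (samples x predictors, values in
#' 0..arity-1), their arities and omic kinds, and an integer-coded
#' categorical target. This is the unit of data every scoring and search
#' function operates on.
#'
#' @param codes integer matrix, samples in rows, predictors in columns;
#'   colnames are the predictor names.
#' @param arity integer vector of per-predictor state counts; every code
#'   must be < its predictor's arity.
#' @param kind character vector, \code{"miRNA"} or \code{"mRNA"} per
#'   predictor.
#' @param target integer vector of target codes in 0..(target_arity-1),
#'   one per sample.
#' @param target_levels character vector of class labels in code order;
#'   its length is the target arity.
#' @return An object of class \code{"discrete_dataset"}. A dataset with
#'   zero samples is allowed (every family score is then the empty
#'   product, 0); the search functions require at least one sample.
#' @export
discrete_dataset <- function(codes, arity, kind, target, target_levels) {
  if (!is.matrix(codes)) stop("'codes' must be a matrix")
  storage.mode(codes) <- "integer"
  p <- ncol(codes); n <- nrow(codes)
  arity <- as.integer(arity)
  if (length(arity) != p) stop("'arity' must have one entry per predictor")
  if (any(arity < 1L)) stop("arities must be >= 1")
  if (length(kind) == 1L) kind <- rep(kind, p)
  if (length(kind) != p || (p > 0 && !all(kind %in% c("miRNA", "mRNA"))))
    stop("'kind' must be \"miRNA\" or \"mRNA\" per predictor")
  target <- as.integer(target)
  if (length(target) != n) stop("'target' must have one code per sample")
  if (anyNA(codes) || anyNA(target)) stop("missing codes are not allowed")
  if (p > 0 && (any(codes < 0L) || any(t(codes) >= arity)))
    stop("predictor codes must lie in 0..(arity-1)")
  r_t <- length(target_levels)
  if (any(target < 0L | target >= r_t))
    stop("target codes must lie in 0..(target arity - 1)")
  structure(list(codes = codes, arity = arity, kind = as.character(kind),
                 names = colnames(codes), target = target,
                 target_arity = as.integer(r_t),
                 target_levels = as.character(target_levels),
                 n_samples = n),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf(
    "discrete_dataset: %d samples, %d predictors (%d miRNA, %d mRNA), target '%s' with %d classes\n",
    x$n_samples, ncol(x$codes), sum(x$kind == "miRNA"), sum(x$kind == "mRNA"),
    paste(x$target_levels, collapse = "/"), x$target_arity))
  invisible(x)
}

#' Number of predictors in a discrete dataset
#' @param data a [discrete_dataset()].
#' @export
n_predictors <- function(data) {
  stopifnot(inherits(data, "discrete_dataset"))
  ncol(data$codes)
}
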