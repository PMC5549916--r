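#' Merge miRNA and mRNA layers with the clinical table by patient ID
#'
#' Restricts all three inputs to the intersection of their sample-ID sets,
#' in sorted order, concatenates the features of the two layers (kind tags
#' preserved) and aligns the categorical target. Patients without a target
#' value are dropped before intersecting, mirroring the exclusion of
#' patients with missing clinical annotation.
#'
#' @param mirna,mrna [expression_matrix()] objects on the same scale.
#' @param clinical data.frame with columns \code{sample_id} and
#'   \code{target} (see [read_clinical_tsv()]).
#' @return list with \code{expr} (combined [expression_matrix()]) and
#'   \code{target} (factor, one level per observed class, named by sample).
#' @export
merge_by_patient <- function(mirna, mrna, clinical) {
  stopifnot(inherits(mirna, "expression_matrix"),
            inherits(mrna, "expression_matrix"))
  if (attr(mirna, "scale") != attr(mrna, "scale"))
    stop("miRNA and mRNA matrices are on different scales")
  clinical <- clinical[!is.na(clinical$target) & clinical$target != "", ,
                       drop = FALSE]
  sets <- list(miRNA = colnames(mirna), mRNA = colnames(mrna),
               clinical = clinical$sample_id)
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0L)
    stop(sprintf(
      "no common patients: %d miRNA samples, %d mRNA samples, %d clinical rows with a target",
      length(sets$miRNA), length(sets$mRNA), length(sets$clinical)))
  mi <- .em_subset(mirna, j = match(common, colnames(mirna)))
  mr <- .em_subset(mrna, j = match(common, colnames(mrna)))
  if (any(rownames(mi) %in% rownames(mr)))
    stop("feature IDs are shared between the miRNA and mRNA layers")
  values <- rbind(unclass(mi), unclass(mr))
  attr(values, "kind") <- attr(values, "scale") <- NULL
  expr <- expression_matrix(values,
                            kind = c(attr(mi, "kind"), attr(mr, "kind")),
                            scale = attr(mirna, "scale"))
  tgt <- clinical$target[match(common, clinical$sample_id)]
  list(expr = expr, target = stats::setNames(factor(tgt), common))
}

#' Drop features whose expression is zero in every patient
#'
#' @param matrix an [expression_matrix()] on the raw scale.
#' @return The matrix without all-zero features; row order otherwise kept.
#' @export
filter_all_zero <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (attr(matrix, "scale") != "raw")
    stop("all-zero filtering applies to the raw scale only")
  keep <- rowSums(unclass(matrix) != 0) > 0
  .em_subset(matrix, i = which(keep))
}

#' Convert relative expression values to the binary logarithm
#'
#' Applies \code{x -> log2(x + pseudocount)} entrywise. The pseudocount
#' keeps the transform total when individual measurements are zero (only
#' features that are zero across all patients get removed upstream).
#' Refuses to run on an already log2-scaled matrix, so an accidental second
#' pass errors instead of silently double-transforming.
#'
#' @param matrix raw-scale [expression_matrix()].
#' @param pseudocount non-negative offset, default 1.
#' @return log2-scale [expression_matrix()].
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (attr(matrix, "scale") == "log2")
    stop("matrix is already on the log2 scale")
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  v <- unclass(matrix)
  attr(v, "kind") <- attr(v, "scale") <- NULL
  if (length(v) && any(v < 0)) stop("negative values on the raw scale")
  expression_matrix(log2(v + pseudocount), attr(matrix, "kind"), "log2")
}

#' Equal-width discretization of one feature
#'
#' Splits the observed range \code{[min, max]} into \code{nbins} intervals
#' of equal width. Intervals are half-open \code{[lo, hi)} except the last,
#' which is closed so the maximum maps to the top code. A constant vector
#' maps entirely to code 0 with arity 1.
#'
#' @param values finite numeric vector.
#' @param nbins number of bins, >= 1.
#' @return list with \code{codes} (integer, 0-based), \code{edges}
#'   (numeric, length arity + 1) and \code{arity}.
#' @examples
#' discretize_equal_width(c(0, 1, 2, 3), 2)$codes  # 0 0 1 1
#' @export
discretize_equal_width <- function(values, nbins) {
  if (length(nbins) != 1L || is.na(nbins) || nbins < 1)
    stop("'nbins' must be >= 1")
  nbins <- as.integer(nbins)
  if (length(values) == 0L)
    return(list(codes = integer(), edges = numeric(), arity = 1L))
  if (!all(is.finite(values))) stop("non-finite values cannot be discretized")
  lo <- min(values); hi <- max(values)
  if (lo == hi || nbins == 1L)
    return(list(codes = integer(length(values)),
                edges = c(lo, hi), arity = 1L))
  width <- (hi - lo) / nbins
  codes <- pmin(as.integer(floor((values - lo) / width)), nbins - 1L)
  list(codes = codes, edges = lo + width * (0:nbins), arity = nbins)
}

#' Restrict a matrix to curated candidate features
#'
#' Keeps features named in a curated interaction list. miRNA names match
#' exactly, or — because expression platforms report mature-arm variants —
#' when the dataset name equals a curated name plus one of the suffixes
#' \code{*}, \code{-5p}, \code{-3p} (e.g. curated \code{hsa-miR-101}
#' matches dataset \code{hsa-miR-101-5p}). mRNAs match by exact gene symbol
#' only.
#'
#' @param matrix an [expression_matrix()].
#' @param curation a curation list as returned by [dedup_curation()] or
#'   [read_curation_csv()] (data.frame with \code{mirna}, \code{mrna}).
#' @param suffix_match set to \code{FALSE} for exact-only miRNA matching.
#' @return The matrix restricted to matching features.
#' @export
extract_candidates <- function(matrix, curation, suffix_match = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  cur <- if (is.list(curation) && !is.data.frame(curation)) curation$records else curation
  mirnas <- unique(as.character(cur$mirna))
  mrnas  <- unique(as.character(cur$mrna))
  ids <- rownames(matrix)
  kind <- attr(matrix, "kind")
  ok_mi <- ids %in% mirnas
  if (suffix_match && length(mirnas)) {
    variants <- c(outer(mirnas, c("*", "-5p", "-3p"), paste0))
    ok_mi <- ok_mi | ids %in% variants
  }
  keep <- (kind == "miRNA" & ok_mi) | (kind == "mRNA" & ids %in% mrnas)
  .em_subset(matrix, i = which(keep))
}

#' Deduplicate a curated miRNA-mRNA interaction list
#'
#' Removes interaction pairs that overlap between sources by exact,
#' case-sensitive \code{(miRNA, mRNA)} pair identity (the first occurrence
#' is kept, so its annotation and reference survive).
#'
#' @param records data.frame with at least columns \code{mirna} and
#'   \code{mrna}; optional annotation columns (\code{mirna_regulation},
#'   \code{role}, \code{reference}) pass through.
#' @return list with \code{records} (deduplicated), \code{n_pairs},
#'   \code{n_mirna}, \code{n_mrna}.
#' @examples
#' dedup_curation(data.frame(mirna = c("a", "a", "a"),
#'                           mrna  = c("X", "X", "Y")))$n_pairs  # 2
#' @export
dedup_curation <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(list(records = records, n_pairs = 0L, n_mirna = 0L, n_mrna = 0L))
  if (!all(c("mirna", "mrna") %in% names(records)))
    stop("curation records need 'mirna' and 'mrna' columns")
  bad <- which(is.na(records$mirna) | records$mirna == "" |
               is.na(records$mrna)  | records$mrna == "")
  if (length(bad))
    stop("malformed curation record (missing name) at row ", bad[1])
  key <- paste(records$mirna, records$mrna, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       n_pairs = nrow(out),
       n_mirna = length(unique(out$mirna)),
       n_mrna  = length(unique(out$mrna)))
}

#' Read a curated interaction list
#'
#' @param path CSV with columns
#'   \code{mirna,mrna,mirna_regulation,role,reference} (annotation columns
#'   optional).
#' @param dedup deduplicate pairs on read (default).
#' @return As [dedup_curation()]; with \code{dedup = FALSE}, the raw
#'   data.frame.
#' @export
read_curation_csv <- function(path, dedup = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dedup) dedup_curation(d) else d
}

#' Build a discrete dataset from a processed matrix and target
#'
#' Applies [discretize_equal_width()] to every feature of a log2-scale
#' matrix (bin edges from that feature's own observed range) and encodes
#' the target classes as 0..(r_T - 1) in sorted label order.
#'
#' @param matrix log2-scale [expression_matrix()].
#' @param target factor or character vector, one class label per sample, in
#'   the matrix's sample order.
#' @param nbins bins per feature, default 3 (low / medium / high).
#' @return A [discrete_dataset()].
#' @export
build_discrete_dataset <- function(matrix, target, nbins = 3) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (attr(matrix, "scale") != "log2")
    stop("discretization expects a log2-scale matrix")
  if (length(target) != ncol(matrix))
    stop("'target' length must equal the number of samples")
  p <- nrow(matrix)
  codes <- matrix(0L, nrow = ncol(matrix), ncol = p,
                  dimnames = list(colnames(matrix), rownames(matrix)))
  arity <- integer(p)
  for (i in seq_len(p)) {
    d <- discretize_equal_width(unclass(matrix)[i, ], nbins)
    codes[, i] <- d$codes
    arity[i] <- d$arity
  }
  levels <- sort(unique(as.character(target)))
  discrete_dataset(codes, arity, kind = attr(matrix, "kind"),
                   target = match(as.character(target), levels) - 1L,
                   target_levels = levels)
}
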