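# run one pipeline stage, tagging errors with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full interaction-discovery pipeline
#'
#' Preprocess (candidate extraction, patient merge, all-zero filter, log2,
#' equal-width discretization), Multiple Beam Search, miRNA-mRNA pair
#' filtering, and BNPP validation, in that order. The result mirrors the
#' reporting style of the analyses this package implements: how many DAG
#' models were checked, how many interaction models were discovered, and
#' how many exceeded the posterior threshold.
#'
#' @param mirna,mrna [expression_matrix()] objects (raw scale) or paths to
#'   expression TSVs.
#' @param clinical data.frame (\code{sample_id}, \code{target}) or path to
#'   a clinical TSV.
#' @param curation optional curation list ([dedup_curation()] result or
#'   data.frame) or path to a curation CSV; when given, each layer is
#'   restricted to curated candidates first.
#' @param nbins,pseudocount discretization bins and log2 pseudocount.
#' @param alpha BDeu prior equivalent sample size.
#' @param priors,threshold BNPP model priors and validation cutoff.
#' @param max_parents,top_k search caps (see [mbs_params()]).
#' @param suffix_match star-strand/-5p/-3p miRNA name matching for
#'   candidate extraction.
#' @param out_dir optional directory; when given, writes
#'   \code{interactions.tsv} and \code{trace.json} there.
#' @param verbose emit per-stage progress messages.
#' @return list of class \code{"mirbeam_run"}: \code{report} (see
#'   [validate_models()]), \code{trace}, \code{models}, \code{dataset},
#'   and \code{counts} (models_checked / models_found / validated).
#' @export
run_pipeline <- function(mirna, mrna, clinical, curation = NULL,
                         nbins = 3, pseudocount = 1, alpha = 54,
                         priors = rep(0.25, 4), threshold = 0.95,
                         max_parents = Inf, top_k = Inf,
                         suffix_match = TRUE, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(mirna)) mirna <- read_expression_tsv(mirna, "miRNA")
  if (is.character(mrna)) mrna <- read_expression_tsv(mrna, "mRNA")
  if (is.character(clinical)) clinical <- read_clinical_tsv(clinical)
  if (is.character(curation)) curation <- read_curation_csv(curation)

  if (!is.null(curation)) {
    mirna <- .stage("extract_candidates",
                    extract_candidates(mirna, curation, suffix_match))
    mrna <- .stage("extract_candidates",
                   extract_candidates(mrna, curation, suffix_match))
  }
  merged <- .stage("merge_by_patient", merge_by_patient(mirna, mrna, clinical))
  expr <- .stage("filter_all_zero", filter_all_zero(merged$expr))
  expr <- .stage("log2_transform", log2_transform(expr, pseudocount))
  ds <- .stage("discretize", build_discrete_dataset(expr, merged$target, nbins))
  say("preprocess: %d samples, %d predictors, target arity %d",
      ds$n_samples, ncol(ds$codes), ds$target_arity)

  params <- mbs_params(alpha = alpha, max_parents = max_parents, top_k = top_k)
  res <- .stage("mbs_search", mbs_search(ds, params))
  say("search: checked %d DAG models, %d model(s) after dedup",
      res$trace$models_checked, nrow(res$models))
  recs <- .stage("filter_pairs", filter_pairs(res, ds))
  report <- .stage("validate_models",
                   validate_models(recs, ds, score_config(alpha),
                                   bnpp_config(priors, threshold)))
  say("bnpp: %d interaction pair(s), %d validated at threshold %g",
      nrow(report), sum(report$validated), threshold)

  run <- structure(list(
    report = report, trace = res$trace, models = res$models, dataset = ds,
    counts = list(models_checked = res$trace$models_checked,
                  models_found = nrow(res$models),
                  pairs = nrow(report), validated = sum(report$validated)),
    params = list(nbins = nbins, pseudocount = pseudocount, alpha = alpha,
                  priors = priors, threshold = threshold,
                  max_parents = max_parents, top_k = top_k,
                  suffix_match = suffix_match)),
    class = "mirbeam_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "interactions.tsv"), run$params)
    jsonlite::write_json(list(models_checked = res$trace$models_checked,
                              models_found = nrow(res$models),
                              validated = sum(report$validated)),
                         file.path(out_dir, "trace.json"), auto_unbox = TRUE)
  }
  run
}

#' @export
print.mirbeam_run <- function(x, ...) {
  cat(sprintf(
    "mirbeam_run: checked %d DAG models, discovered %d, %d interaction pair(s), %d with BNPP > %g\n",
    x$counts$models_checked, x$counts$models_found, x$counts$pairs,
    x$counts$validated, x$params$threshold))
  if (nrow(x$report)) print(utils::head(x$report, 10))
  invisible(x)
}

#' Write the interaction report TSV
#'
#' Columns \code{rank, mirna, mrna, log_bdeu, bnpp, validated,
#' model_parents}, preceded by \code{#} comment lines stamping the package
#' version, the configuration and its hash, so a report is traceable to
#' the run that produced it.
#'
#' @param report a [validate_models()] data.frame.
#' @param path output file.
#' @param params optional named list of run parameters to stamp.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, params = NULL) {
  cfg <- if (is.null(params)) "" else
    paste(names(params), vapply(params, function(v)
      paste(format(v, digits = 15), collapse = ","), character(1)),
      sep = "=", collapse = " ")
  tf <- tempfile(); writeLines(cfg, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mirbeam %s", as.character(utils::packageVersion("mirbeam"))),
    sprintf("# config: %s", cfg),
    sprintf("# config_hash: %s", hash)), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an interaction report
#'
#' @param path a file written by [write_report()].
#' @return The report data.frame (comment lines skipped).
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Precision and recall of validated pairs against the planted truth
#'
#' Exact set arithmetic on (miRNA, mRNA) pairs. When nothing is validated,
#' precision is undefined; by convention it is reported as 1 with
#' \code{precision_defined = FALSE} (an empty call set makes no false
#' claims), and recall is 0 unless nothing was planted.
#'
#' @param report a [validate_models()] data.frame (or \code{mirbeam_run}).
#' @param truth a \code{synthetic_truth} (from [generate_dataset()] or
#'   [read_truth_json()]).
#' @return list: \code{precision}, \code{recall},
#'   \code{precision_defined}, \code{n_validated}, \code{n_planted},
#'   \code{true_positives}.
#' @export
evaluate_against_truth <- function(report, truth) {
  if (inherits(report, "mirbeam_run")) report <- report$report
  stopifnot(inherits(truth, "synthetic_truth"))
  val <- report[report$validated, , drop = FALSE]
  vkey <- paste(val$mirna, val$mrna, sep = "\r")
  pkey <- paste(truth$planted_pairs$mirna, truth$planted_pairs$mrna, sep = "\r")
  tp <- length(intersect(vkey, pkey))
  precision_defined <- length(vkey) > 0
  list(precision = if (precision_defined) tp / length(vkey) else 1,
       recall = if (length(pkey)) tp / length(pkey) else 1,
       precision_defined = precision_defined,
       n_validated = length(vkey), n_planted = length(pkey),
       true_positives = tp)
}
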