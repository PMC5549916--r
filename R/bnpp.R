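#' BNPP configuration
#'
#' @param priors prior probabilities of the four competing models, in the
#'   order (M_ij, M_0, M_i, M_j): the joint-interaction model, the model
#'   with neither predictor associated, and the two single-predictor
#'   models. Must be non-negative, not all zero, and sum to 1. Default is
#'   the non-informative prior, 0.25 each.
#' @param threshold posterior cutoff in (0, 1) above which (strictly) a
#'   pair counts as validated; default 0.95.
#' @return An object of class \code{"bnpp_config"}.
#' @export
bnpp_config <- function(priors = rep(0.25, 4), threshold = 0.95) {
  if (length(priors) != 4L || any(priors < 0) || all(priors == 0))
    stop("'priors' must be 4 non-negative numbers, not all zero")
  if (abs(sum(priors) - 1) > 1e-9) stop("'priors' must sum to 1")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  structure(list(priors = as.numeric(priors),
                 threshold = as.numeric(threshold)),
            class = "bnpp_config")
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior probability of the interaction model for one pair
#'
#' Computes the Bayesian network posterior probability (BNPP): the
#' posterior of the model in which the miRNA and mRNA together parent the
#' target, against three competitors — the empty model (neither predictor
#' associated with the target) and the two single-predictor models. Each
#' model's marginal likelihood is its BDeu score; because every predictor
#' is parentless in all four models, the predictor family factors cancel
#' in the posterior and only the target family is computed. All arithmetic
#' is in log space with a log-sum-exp normalization, which is what makes
#' the ratio computable at realistic sample sizes where the raw
#' likelihoods underflow.
#'
#' @param data a [discrete_dataset()].
#' @param mirna,mrna distinct predictor indices (or predictor names).
#' @param score_config a [score_config()].
#' @param bnpp_config a [bnpp_config()].
#' @return An object of class \code{"competing_model_set"}: data.frame-like
#'   list with model names, log-likelihoods, priors, posteriors, and
#'   \code{bnpp}, the posterior of the joint model.
#' @examples
#' # with equal likelihoods (no data beyond the prior), BNPP is the prior 0.25
#' @export
bnpp <- function(data, mirna, mrna, score_config = mirbeam::score_config(),
                 bnpp_config = mirbeam::bnpp_config()) {
  stopifnot(inherits(data, "discrete_dataset"),
            inherits(bnpp_config, "bnpp_config"))
  if (is.character(mirna)) mirna <- match(mirna, data$names)
  if (is.character(mrna)) mrna <- match(mrna, data$names)
  mirna <- as.integer(mirna); mrna <- as.integer(mrna)
  if (anyNA(c(mirna, mrna)) || length(mirna) != 1L || length(mrna) != 1L)
    stop("'mirna' and 'mrna' must each name one predictor")
  if (mirna == mrna) stop("'mirna' and 'mrna' must be distinct predictors")
  fam <- .fam_scorer(data, score_config$alpha)
  loglik <- c(M_ij = fam(c(mirna, mrna)), M_0 = fam(integer()),
              M_i = fam(mirna), M_j = fam(mrna))
  logpost <- loglik + log(bnpp_config$priors)
  posterior <- exp(logpost - .logsumexp(logpost))
  structure(list(models = names(loglik), loglik = loglik,
                 prior = stats::setNames(bnpp_config$priors, names(loglik)),
                 posterior = posterior, bnpp = unname(posterior[1]),
                 mirna = data$names[mirna], mrna = data$names[mrna],
                 alpha = score_config$alpha),
            class = "competing_model_set")
}

#' @export
print.competing_model_set <- function(x, ...) {
  cat(sprintf("BNPP(%s, %s) = %.4f  [alpha = %g]\n",
              x$mirna, x$mrna, x$bnpp, x$alpha))
  print(data.frame(model = x$models, loglik = x$loglik, prior = x$prior,
                   posterior = x$posterior, row.names = NULL))
  invisible(x)
}

#' Validate interaction records by BNPP
#'
#' Computes the BNPP of every (miRNA, mRNA) record against its three
#' competing models and flags the record validated when BNPP strictly
#' exceeds the threshold. For records emitted from models with more than
#' two parents, the posterior is computed on the pair alone — the
#' four-model comparison is defined for a pair. Output is sorted by
#' descending log-BDeu and re-ranked.
#'
#' @param records interaction records from [filter_pairs()].
#' @param data the [discrete_dataset()].
#' @param score_config a [score_config()].
#' @param bnpp_config a [bnpp_config()].
#' @return data.frame with columns \code{rank}, \code{mirna}, \code{mrna},
#'   \code{log_bdeu}, \code{bnpp}, \code{validated}, \code{model_parents}.
#' @export
validate_models <- function(records, data,
                            score_config = mirbeam::score_config(),
                            bnpp_config = mirbeam::bnpp_config()) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (nrow(records) == 0L)
    return(data.frame(rank = integer(), mirna = character(),
                      mrna = character(), log_bdeu = numeric(),
                      bnpp = numeric(), validated = logical(),
                      model_parents = character(), stringsAsFactors = FALSE))
  pp <- vapply(seq_len(nrow(records)), function(i)
    bnpp(data, records$mirna_idx[i], records$mrna_idx[i],
         score_config, bnpp_config)$bnpp, numeric(1))
  out <- data.frame(mirna = records$mirna, mrna = records$mrna,
                    log_bdeu = records$log_bdeu, bnpp = pp,
                    validated = pp > bnpp_config$threshold,
                    model_parents = records$model_parents,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log_bdeu, out$mirna, out$mrna), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
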