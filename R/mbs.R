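#' Parameters of the Multiple Beam Search
#'
#' @param alpha BDeu prior equivalent sample size (default 54).
#' @param max_parents optional cap on parent-set size; default unlimited.
#' @param top_k number of ranked models to report; default all.
#' @param pair_filter keep only models containing at least one miRNA and
#'   one mRNA when extracting interaction records (see [filter_pairs()]).
#' @return An object of class \code{"mbs_params"}.
#' @export
mbs_params <- function(alpha = 54, max_parents = Inf, top_k = Inf,
                       pair_filter = TRUE) {
  if (!is.numeric(top_k) || top_k < 1) stop("'top_k' must be >= 1")
  if (!is.numeric(max_parents) || max_parents < 1)
    stop("'max_parents' must be >= 1 when set")
  structure(list(score = score_config(alpha), max_parents = max_parents,
                 top_k = top_k, pair_filter = isTRUE(pair_filter)),
            class = "mbs_params")
}

# fast target-family scorer: closure over the dataset, skips revalidation
.fam_scorer <- function(data, alpha) {
  codes <- data$codes
  arity <- data$arity
  tcodes <- data$target
  r <- data$target_arity
  n <- data$n_samples
  empty <- {
    s <- tabulate(tcodes + 1L, nbins = r)
    a <- alpha; ak <- alpha / r
    lgamma(a) - lgamma(a + n) + sum(lgamma(ak + s) - lgamma(ak))
  }
  function(parents) {
    if (!length(parents)) return(empty)
    q <- prod(arity[parents])
    j0 <- integer(n)
    for (p in parents) j0 <- j0 * arity[p] + codes[, p]
    tab <- tabulate(j0 * r + tcodes + 1L, nbins = as.integer(q * r))
    s <- matrix(tab, nrow = r)           # columns are parent instantiations
    aj <- alpha / q; ajk <- alpha / (r * q)
    nj <- colSums(s)
    sum(lgamma(aj) - lgamma(aj + nj)) + sum(lgamma(ajk + tab) - lgamma(ajk))
  }
}

#' Multiple Beam Search over predictor parent sets
#'
#' Launches one beam from every predictor. Each beam starts at the model
#' with that single predictor parenting the target, then greedily adds the
#' predictor whose addition raises the log-BDeu score the most, as long as
#' some addition strictly improves it (ties broken by lowest predictor
#' index); it then greedily deletes parents in the same fashion while a
#' deletion strictly improves the score. Beams that shrink to the empty
#' parent set are discarded. Surviving models are deduplicated by parent
#' set and ranked by descending log-BDeu, then lexicographically by sorted
#' parent set. Every scored candidate model (including the initial beam
#' models) increments the \code{models_checked} counter of the trace.
#'
#' @param data a [discrete_dataset()] with at least one predictor and a
#'   target of arity >= 2.
#' @param params an [mbs_params()].
#' @return list of class \code{"mbs_result"} with
#'   \describe{
#'     \item{models}{data.frame: \code{rank}, \code{parents} (list of
#'       integer index vectors, sorted), \code{model_parents} (names,
#'       comma-joined), \code{log_bdeu} (full-network natural-log score),
#'       \code{log_family} (target-family part).}
#'     \item{trace}{list with \code{models_checked} and per-beam records
#'       (\code{start}, final \code{parents}, \code{score_path} of
#'       family scores along accepted moves, \code{discarded}).}
#'   }
#' @export
mbs_search <- function(data, params = mbs_params()) {
  stopifnot(inherits(data, "discrete_dataset"), inherits(params, "mbs_params"))
  np <- ncol(data$codes)
  if (np == 0L) stop("no predictors to search over")
  if (data$n_samples < 1L) stop("search needs at least one sample")
  if (data$target_arity < 2L)
    stop("target must have at least 2 classes (score differences vanish)")
  alpha <- params$score$alpha
  fam <- .fam_scorer(data, alpha)
  empty_score <- fam(integer())
  singles <- vapply(seq_len(np), function(i) fam(i), numeric(1))
  checked <- 0L
  beams <- vector("list", np)

  for (b in seq_len(np)) {
    S <- b
    cur <- singles[b]
    path <- cur
    checked <- checked + 1L          # the initial beam model
    # forward: greedy additions while the score strictly improves
    while (length(S) < params$max_parents) {
      cand <- setdiff(seq_len(np), S)
      if (!length(cand)) break
      sc <- vapply(cand, function(cc) fam(c(S, cc)), numeric(1))
      checked <- checked + length(cand)
      i <- which.max(sc)               # cand ascending => first max = lowest index
      if (sc[i] > cur) {
        S <- c(S, cand[i]); cur <- sc[i]; path <- c(path, cur)
      } else break
    }
    # backward: greedy deletions while the score strictly improves
    while (length(S) >= 1L) {
      del <- sort(S)
      sc <- vapply(del, function(d) fam(setdiff(S, d)), numeric(1))
      checked <- checked + length(del)
      i <- which.max(sc)
      if (sc[i] > cur) {
        S <- setdiff(S, del[i]); cur <- sc[i]; path <- c(path, cur)
      } else break
    }
    beams[[b]] <- list(start = b, parents = S, score = cur,
                       score_path = path, discarded = length(S) == 0L)
  }

  kept <- Filter(function(x) !x$discarded, beams)
  key <- vapply(kept, function(x)
    paste(sprintf("%09d", sort(x$parents)), collapse = ","), character(1))
  kept <- kept[!duplicated(key)]
  key <- key[!duplicated(key)]
  if (length(kept)) {
    scores <- vapply(kept, `[[`, numeric(1), "score")
    ord <- order(-scores, key)
    kept <- kept[ord]; scores <- scores[ord]
    if (is.finite(params$top_k) && length(kept) > params$top_k) {
      kept <- kept[seq_len(params$top_k)]
      scores <- scores[seq_len(params$top_k)]
    }
    baseline <- .predictor_baseline(data, params$score)
    parents <- lapply(kept, function(x) sort(x$parents))
    models <- data.frame(
      rank = seq_along(kept),
      model_parents = vapply(parents, function(p)
        paste(data$names[p], collapse = ","), character(1)),
      log_bdeu = scores + baseline,
      log_family = scores,
      stringsAsFactors = FALSE)
    models$parents <- parents
  } else {
    models <- data.frame(rank = integer(), model_parents = character(),
                         log_bdeu = numeric(), log_family = numeric(),
                         stringsAsFactors = FALSE)
    models$parents <- list()
  }
  structure(list(models = models,
                 trace = list(models_checked = checked, beams = beams)),
            class = "mbs_result")
}

#' @export
print.mbs_result <- function(x, ...) {
  cat(sprintf("mbs_result: %d model(s) after dedup, %d DAG models checked\n",
              nrow(x$models), x$trace$models_checked))
  if (nrow(x$models))
    print(utils::head(x$models[c("rank", "model_parents", "log_bdeu")], 10))
  invisible(x)
}

#' Extract miRNA-mRNA interaction records from ranked models
#'
#' Keeps models whose parent set contains at least one miRNA and at least
#' one mRNA, and emits one record per (miRNA, mRNA) cross pair within each
#' such model, tagged with the model's score. Models made of miRNAs only
#' or mRNAs only are dropped. A pair arising from several models is kept
#' once, at its best (first-ranked) score.
#'
#' @param models an [mbs_search()] result, or its \code{models} data.frame.
#' @param data the [discrete_dataset()] the models were learned from
#'   (supplies predictor kinds and names).
#' @return data.frame of interaction records: \code{mirna}, \code{mrna},
#'   \code{mirna_idx}, \code{mrna_idx}, \code{log_bdeu},
#'   \code{log_family}, \code{model_parents}.
#' @export
filter_pairs <- function(models, data) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (inherits(models, "mbs_result")) models <- models$models
  out <- list()
  for (i in seq_len(nrow(models))) {
    p <- models$parents[[i]]
    mi <- p[data$kind[p] == "miRNA"]
    mr <- p[data$kind[p] == "mRNA"]
    if (!length(mi) || !length(mr)) next
    g <- expand.grid(mirna_idx = mi, mrna_idx = mr)
    out[[length(out) + 1L]] <- data.frame(
      mirna = data$names[g$mirna_idx], mrna = data$names[g$mrna_idx],
      mirna_idx = g$mirna_idx, mrna_idx = g$mrna_idx,
      log_bdeu = models$log_bdeu[i], log_family = models$log_family[i],
      model_parents = models$model_parents[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna = character(), mrna = character(),
                      mirna_idx = integer(), mrna_idx = integer(),
                      log_bdeu = numeric(), log_family = numeric(),
                      model_parents = character(), stringsAsFactors = FALSE))
  recs <- do.call(rbind, out)
  recs <- recs[!duplicated(paste(recs$mirna_idx, recs$mrna_idx)), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}
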