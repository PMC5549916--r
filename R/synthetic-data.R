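#' Configuration of the synthetic expression generator
#'
#' Defines a study in which a small set of planted miRNA-mRNA pairs shifts
#' the probability of a clinical phenotype through their JOINT discretized
#' state (an XOR-style epistatic rule) while each member on its own is
#' statistically independent of the phenotype; additional features carry a
#' purely marginal effect, and the remainder are class-independent noise.
#'
#' @param n_samples number of patients.
#' @param n_mirna,n_mrna number of features per omic layer.
#' @param n_interacting_pairs planted epistatic pairs, at most
#'   \code{min(n_mirna, n_mrna)}.
#' @param n_marginal_features features with a marginal-only effect,
#'   assigned alternately to the two layers outside the planted pairs.
#' @param interaction_effect shift in [0, 0.5] applied to the affected
#'   class's probability by a pair's joint state.
#' @param marginal_effect shift in [0, 0.5] for marginal-only features.
#' @param target_arity number of phenotype classes, >= 2 (2 for
#'   tumor/normal or metastasis yes/no; 4 for molecular subtype).
#' @param noise_sd standard deviation of the log2-scale expression noise
#'   around each latent-state mean.
#' @param repression when TRUE, a planted miRNA's latent state
#'   anti-correlates with its mRNA partner's, so partner expression is
#'   negatively correlated — the direction expected from miRNA-mediated
#'   mRNA destabilization. The disagreement rate is symmetric in the two
#'   states, which preserves the exact marginal independence of each
#'   partner from the phenotype.
#' @param seed RNG seed; the same seed reproduces the dataset bit for bit.
#' @return An object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_samples, n_mirna, n_mrna,
                         n_interacting_pairs = 1, n_marginal_features = 0,
                         interaction_effect = 0.35, marginal_effect = 0.15,
                         target_arity = 2, noise_sd = 0.5,
                         repression = FALSE, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_interacting_pairs = as.integer(n_interacting_pairs),
              n_marginal_features = as.integer(n_marginal_features),
              interaction_effect = as.numeric(interaction_effect),
              marginal_effect = as.numeric(marginal_effect),
              target_arity = as.integer(target_arity),
              noise_sd = as.numeric(noise_sd),
              repression = isTRUE(repression), seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 1) stop("'n_samples' must be >= 1")
    if (n_mirna < 0 || n_mrna < 0 || n_interacting_pairs < 0 ||
        n_marginal_features < 0)
      stop("feature counts must be >= 0")
    if (n_interacting_pairs > min(n_mirna, n_mrna))
      stop("more planted pairs than features in a layer")
    if (interaction_effect < 0 || interaction_effect > 0.5 ||
        marginal_effect < 0 || marginal_effect > 0.5)
      stop("effects must lie in [0, 0.5]")
    if (target_arity < 2) stop("'target_arity' must be >= 2")
    if (noise_sd < 0) stop("'noise_sd' must be >= 0")
    if (n_marginal_features >
        (n_mirna - n_interacting_pairs) + (n_mrna - n_interacting_pairs))
      stop("not enough free features for the marginal-only set")
  })
  structure(cfg, class = "synth_config")
}

# log2-scale means of the latent low/high expression states; the gap is
# wide relative to noise_sd so a 3-bin equal-width discretization recovers
# the latent state almost surely
.MU_LOW <- 5
.MU_HIGH <- 8
# latent-state disagreement rate within a repressed pair (symmetric)
.REPRESSION_DISAGREE <- 0.8

#' Generate a synthetic paired-expression study
#'
#' Draws, per planted pair, a latent binary state for the miRNA and for
#' the mRNA; the phenotype's "affected" class probability is its baseline
#' 1/target_arity shifted up by \code{interaction_effect} when the two
#' states disagree (XOR = 1) and down when they agree. Because each
#' member's state is marginally uniform and the disagreement indicator is
#' independent of either member alone, each member is exactly independent
#' of the phenotype — only the pair carries signal. Marginal-only features
#' shift the affected-class probability by \code{marginal_effect} on their
#' own; all remaining features are noise. Raw expression is
#' \code{2^(mu_state + N(0, noise_sd))}, so the pipeline's log2 step
#' recovers a two-component Gaussian mixture per feature.
#'
#' @param config a [synth_config()].
#' @return list of class \code{"mirbeam_synthetic"} with raw-scale
#'   \code{mirna} and \code{mrna} [expression_matrix()] objects,
#'   \code{clinical} (data.frame \code{sample_id}, \code{target}) and
#'   \code{truth} (a \code{synthetic_truth}: \code{planted_pairs},
#'   \code{marginal_features}, and the generative \code{config}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_samples
  k <- config$n_interacting_pairs
  samples <- sprintf("S%04d", seq_len(n))
  mirna_ids <- if (config$n_mirna) sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirna)) else character()
  mrna_ids <- if (config$n_mrna) sprintf("GENE%03d", seq_len(config$n_mrna)) else character()

  # role assignment: pairs take the head of each layer; marginal-only
  # features alternate miRNA/mRNA over the remainder
  free_mi <- setdiff(seq_len(config$n_mirna), seq_len(k))
  free_mr <- setdiff(seq_len(config$n_mrna), seq_len(k))
  marg_mi <- integer(); marg_mr <- integer()
  take_mi <- TRUE
  for (m in seq_len(config$n_marginal_features)) {
    if ((take_mi && length(free_mi)) || !length(free_mr)) {
      marg_mi <- c(marg_mi, free_mi[1]); free_mi <- free_mi[-1]
    } else {
      marg_mr <- c(marg_mr, free_mr[1]); free_mr <- free_mr[-1]
    }
    take_mi <- !take_mi
  }

  # latent binary states, one column per feature and layer
  st_mi <- matrix(stats::rbinom(n * config$n_mirna, 1L, 0.5), n, config$n_mirna)
  st_mr <- matrix(stats::rbinom(n * config$n_mrna, 1L, 0.5), n, config$n_mrna)
  disagree_p <- if (config$repression) .REPRESSION_DISAGREE else 0.5
  xor_state <- matrix(0L, n, max(k, 1L))
  for (pr in seq_len(k)) {
    d <- stats::rbinom(n, 1L, disagree_p)
    st_mr[, pr] <- as.integer(xor(st_mi[, pr], d))
    xor_state[, pr] <- d
  }

  # phenotype: baseline 1/r for the affected class, shifted by the rules
  r <- config$target_arity
  shift <- numeric(n)
  for (pr in seq_len(k))
    shift <- shift + config$interaction_effect * (2 * xor_state[, pr] - 1)
  for (f in marg_mi) shift <- shift + config$marginal_effect * (2 * st_mi[, f] - 1)
  for (f in marg_mr) shift <- shift + config$marginal_effect * (2 * st_mr[, f] - 1)
  p_aff <- pmin(pmax(1 / r + shift, 0.001), 0.999)
  labels <- if (r == 2) c("normal", "tumor")
            else paste0("subtype_", LETTERS[seq_len(r)])
  affected <- if (r == 2) "tumor" else labels[1]
  others <- setdiff(labels, affected)
  u_aff <- stats::runif(n)
  u_cls <- stats::runif(n)
  target <- ifelse(u_aff < p_aff, affected,
                   others[1L + pmin(floor(u_cls * (r - 1)), r - 2)])

  expr_layer <- function(states, ids) {
    f <- ncol(states)
    mu <- ifelse(states == 1L, .MU_HIGH, .MU_LOW)
    vals <- 2^(mu + matrix(stats::rnorm(n * f, 0, config$noise_sd), n, f))
    m <- t(vals)
    dimnames(m) <- list(ids, samples)
    m
  }
  mirna <- expression_matrix(expr_layer(st_mi, mirna_ids), "miRNA")
  mrna <- expression_matrix(expr_layer(st_mr, mrna_ids), "mRNA")

  truth <- structure(list(
    planted_pairs = data.frame(mirna = mirna_ids[seq_len(k)],
                               mrna = mrna_ids[seq_len(k)],
                               stringsAsFactors = FALSE),
    marginal_features = c(mirna_ids[marg_mi], mrna_ids[marg_mr]),
    config = unclass(config)), class = "synthetic_truth")

  structure(list(mirna = mirna, mrna = mrna,
                 clinical = data.frame(sample_id = samples, target = target,
                                       stringsAsFactors = FALSE),
                 truth = truth),
            class = "mirbeam_synthetic")
}

.write_expr_tsv <- function(m, path) {
  ids <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Write a synthetic dataset as plain-text fixtures
#'
#' Writes \code{mirna.tsv}, \code{mrna.tsv} (first column
#' \code{feature_id}, one column per sample, full-precision floats, tab
#' delimited), \code{clinical.tsv} (\code{sample_id}, \code{target}) and
#' \code{truth.json} (planted pairs and generative parameters). The truth
#' file always sits next to the fixtures; the pipeline never reads it —
#' only evaluation code does.
#'
#' @param dataset a [generate_dataset()] result.
#' @param directory output directory (created if missing).
#' @return Named character vector of the four file paths.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "mirbeam_synthetic"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirna = file.path(directory, "mirna.tsv"),
             mrna = file.path(directory, "mrna.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             truth = file.path(directory, "truth.json"))
  .write_expr_tsv(unclass(dataset$mirna), paths["mirna"])
  .write_expr_tsv(unclass(dataset$mrna), paths["mrna"])
  utils::write.table(dataset$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted_pairs = dataset$truth$planted_pairs,
                            marginal_features = dataset$truth$marginal_features,
                            config = dataset$truth$config),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Read the truth file written by [write_fixture()]
#'
#' @param path path to \code{truth.json}.
#' @return A \code{synthetic_truth} object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- as.data.frame(x$planted_pairs, stringsAsFactors = FALSE)
  if (nrow(pp) == 0) pp <- data.frame(mirna = character(), mrna = character())
  structure(list(planted_pairs = pp,
                 marginal_features = as.character(unlist(x$marginal_features)),
                 config = x$config),
            class = "synthetic_truth")
}
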