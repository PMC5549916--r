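# Independent oracles and small fixture builders used across the suite.

# Build a discrete_dataset from 0-based code vectors.
make_ds <- function(..., target, arity = NULL, target_levels = NULL,
                    kind = NULL) {
  cols <- list(...)
  n <- length(target)
  codes <- if (length(cols))
    do.call(cbind, lapply(cols, as.integer)) else matrix(0L, n, 0)
  if (is.null(colnames(codes)) && length(cols))
    colnames(codes) <- sprintf("P%02d", seq_along(cols))
  if (is.null(arity))
    arity <- vapply(cols, function(x) max(as.integer(x), 0L) + 1L, integer(1))
  if (is.null(target_levels))
    target_levels <- paste0("c", seq_len(max(as.integer(target), 0L) + 1L))
  if (is.null(kind))
    kind <- rep(c("miRNA", "mRNA"), length.out = max(length(cols), 1L))[seq_along(cols)]
  discrete_dataset(codes, arity, kind, as.integer(target), target_levels)
}

# Dirichlet-multinomial marginal likelihood by the chain rule: one sample
# at a time, multiplying the posterior-predictive probability of its node
# state given the samples seen so far (within its parent instantiation).
# Deliberately takes a different route than the lgamma closed form.
seq_dm_oracle <- function(x, r, parent_codes = NULL, parent_arity = integer(),
                          alpha) {
  q <- if (length(parent_arity)) prod(parent_arity) else 1
  n <- length(x)
  j <- rep(1L, n)
  if (!is.null(parent_codes) && length(parent_arity)) {
    pc <- as.matrix(parent_codes)
    jj <- rep(0, n)
    for (m in seq_len(ncol(pc))) jj <- jj * parent_arity[m] + pc[, m]
    j <- as.integer(jj) + 1L
  }
  counts <- matrix(0, q, r)
  logp <- 0
  for (t in seq_len(n)) {
    k <- x[t] + 1L
    nj <- sum(counts[j[t], ])
    logp <- logp + log((alpha / (r * q) + counts[j[t], k]) /
                       (alpha / q + nj))
    counts[j[t], k] <- counts[j[t], k] + 1
  }
  logp
}

# Exhaustive enumeration of all 1- and 2-predictor target families.
exhaustive_best <- function(data, alpha) {
  np <- n_predictors(data)
  cfg <- score_config(alpha)
  best <- -Inf; best_set <- integer()
  for (i in seq_len(np)) {
    s <- bdeu_family_score(data, "target", i, cfg)
    if (s > best) { best <- s; best_set <- i }
    if (i < np) for (jj in (i + 1):np) {
      s2 <- bdeu_family_score(data, "target", c(i, jj), cfg)
      if (s2 > best) { best <- s2; best_set <- c(i, jj) }
    }
  }
  list(score = best, parents = best_set)
}

# Empirical mutual information (nats) between two discrete vectors.
mi_discrete <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  sum(ifelse(p > 0, p * log(p / e), 0))
}

# Binarize raw-scale expression at the midpoint between the two latent
# log2-scale component means (5 and 8).
latent_state <- function(raw) as.integer(log2(raw) > 6.5)

# Fuzzed dataset with a planted pair (predictors 1 and 2) whose XOR drives
# the target; used to compare the beam search against exhaustive
# enumeration.
fuzz_pair_dataset <- function(seed) {
  set.seed(seed)
  np <- sample(4:10, 1)
  n <- sample(40:90, 1)
  arity <- c(2L, 2L, sample(2:3, np - 2, replace = TRUE))
  codes <- sapply(seq_len(np), function(i)
    sample.int(arity[i], n, replace = TRUE) - 1L)
  flip <- rbinom(n, 1, 0.15)
  target <- as.integer(xor(xor(codes[, 1], codes[, 2]), flip))
  colnames(codes) <- sprintf("P%02d", seq_len(np))
  discrete_dataset(codes, arity,
                   kind = rep(c("miRNA", "mRNA"), length.out = np),
                   target = target, target_levels = c("normal", "tumor"))
}

# Enumerate every dataset of up to max_n samples over the 8 joint cells of
# (binary predictor 1, binary predictor 2, binary target), as cell-count
# vectors.
enumerate_cell_counts <- function(max_n, cells = 8L) {
  out <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 1L) {
      for (v in 0:remaining) out[[length(out) + 1L]] <<- c(prefix, v)
      return()
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v, slots - 1L)
  }
  rec(integer(), max_n, cells)
  out
}

# Expand an 8-cell count vector into a dataset (x1, x2, t per sample).
cells_to_dataset <- function(counts) {
  grid <- expand.grid(t = 0:1, x2 = 0:1, x1 = 0:1)[, 3:1]
  rows <- grid[rep(seq_len(8), counts), , drop = FALSE]
  discrete_dataset(cbind(P1 = rows$x1, P2 = rows$x2), c(2L, 2L),
                   kind = c("miRNA", "mRNA"), target = rows$t,
                   target_levels = c("a", "b"))
}
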