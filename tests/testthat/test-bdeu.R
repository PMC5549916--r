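test_that("sufficient statistics tally node states within parent instantiations", {
  ds <- make_ds(target = c(1L, 1L, 0L), target_levels = c("a", "b"))
  expect_equal(count_sufficient_stats(ds, "target"),
               matrix(c(1L, 2L), nrow = 1))

  ds2 <- make_ds(c(0L, 0L, 1L, 1L), target = c(0L, 1L, 0L, 0L),
                 arity = 2L, target_levels = c("a", "b"))
  expect_equal(count_sufficient_stats(ds2, "target", 1L),
               matrix(c(1L, 2L, 1L, 0L), nrow = 2))
})

test_that("counts sum to N and agree with a naive cross-tabulation (fuzz)", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    r1 <- sample(2:4, 1); r2 <- sample(2:4, 1); rt <- sample(2:3, 1)
    ds <- make_ds(sample.int(r1, n, TRUE) - 1L, sample.int(r2, n, TRUE) - 1L,
                  target = sample.int(rt, n, TRUE) - 1L,
                  arity = c(r1, r2), target_levels = paste0("c", 1:rt))
    s <- count_sufficient_stats(ds, "target", c(1L, 2L))
    expect_equal(sum(s), n)
    # naive tally: first parent most significant
    j <- ds$codes[, 1] * r2 + ds$codes[, 2] + 1L
    naive <- t(sapply(seq_len(r1 * r2), function(jj)
      tabulate(ds$target[j == jj] + 1L, rt)))
    expect_equal(s, matrix(as.integer(naive), nrow = r1 * r2))
  }
})

test_that("hand-derived gamma evaluations are reproduced exactly", {
  # binary node, no parents, counts (2,1), alpha = 2:
  # Gamma(2)/Gamma(5) * Gamma(1+2)Gamma(1+1)/Gamma(1)^2 = 1/12
  ds <- make_ds(target = c(0L, 0L, 1L), target_levels = c("a", "b"))
  expect_equal(bdeu_family_score(ds, "target", config = score_config(2)),
               log(1 / 12), tolerance = 1e-12)

  # binary node, one binary parent, per-instantiation counts (1,1) and
  # (2,0), alpha = 4: factors 1/6 and 1/3
  ds2 <- make_ds(c(0L, 0L, 1L, 1L), target = c(0L, 1L, 0L, 0L),
                 arity = 2L, target_levels = c("a", "b"))
  expect_equal(bdeu_family_score(ds2, "target", 1L, score_config(4)),
               log(1 / 18), tolerance = 1e-12)
})

test_that("an empty dataset scores 0 (empty product)", {
  ds <- discrete_dataset(matrix(integer(), 0, 2,
                                dimnames = list(NULL, c("P1", "P2"))),
                         c(2L, 2L), c("miRNA", "mRNA"),
                         integer(), c("a", "b"))
  expect_equal(bdeu_family_score(ds, "target", c(1L, 2L)), 0)
  expect_equal(bdeu_network_score(ds, dag_model(1L)), 0)
})

test_that("the network score decomposes into family scores", {
  set.seed(7)
  ds <- make_ds(sample(0:2, 30, TRUE), sample(0:1, 30, TRUE),
                sample(0:1, 30, TRUE), target = sample(0:1, 30, TRUE),
                arity = c(3L, 2L, 2L), target_levels = c("a", "b"))
  cfg <- score_config(5)
  pred_terms <- sum(vapply(1:3, function(i)
    bdeu_family_score(ds, i, config = cfg), numeric(1)))
  expect_equal(bdeu_network_score(ds, dag_model(), cfg),
               bdeu_family_score(ds, "target", config = cfg) + pred_terms)
  # predictor terms cancel in model differences
  d_net <- bdeu_network_score(ds, dag_model(c(1L, 2L)), cfg) -
    bdeu_network_score(ds, dag_model(), cfg)
  d_fam <- bdeu_family_score(ds, "target", c(1L, 2L), cfg) -
    bdeu_family_score(ds, "target", config = cfg)
  expect_equal(d_net, d_fam, tolerance = 1e-12)
})

test_that("the score matches a sequential Dirichlet-multinomial oracle (fuzz)", {
  set.seed(202)
  for (rep in 1:50) {
    n <- sample(1:25, 1)
    r1 <- sample(2:3, 1); r2 <- sample(2:3, 1); rt <- sample(2:4, 1)
    alpha <- sample(c(0.5, 1, 2, 54), 1)
    ds <- make_ds(sample.int(r1, n, TRUE) - 1L, sample.int(r2, n, TRUE) - 1L,
                  target = sample.int(rt, n, TRUE) - 1L,
                  arity = c(r1, r2), target_levels = paste0("c", 1:rt))
    expect_equal(
      bdeu_family_score(ds, "target", c(1L, 2L), score_config(alpha)),
      seq_dm_oracle(ds$target, rt, ds$codes[, 1:2], c(r1, r2), alpha),
      tolerance = 1e-10)
    expect_equal(
      bdeu_family_score(ds, "target", config = score_config(alpha)),
      seq_dm_oracle(ds$target, rt, NULL, integer(), alpha),
      tolerance = 1e-10)
  }
})

test_that("the score is invariant to row permutation and state relabeling", {
  set.seed(303)
  ds <- make_ds(sample(0:2, 40, TRUE), sample(0:1, 40, TRUE),
                target = sample(0:1, 40, TRUE),
                arity = c(3L, 2L), target_levels = c("a", "b"))
  cfg <- score_config(54)
  base <- bdeu_family_score(ds, "target", c(1L, 2L), cfg)

  perm <- sample(40)
  ds_p <- discrete_dataset(ds$codes[perm, ], ds$arity, ds$kind,
                           ds$target[perm], ds$target_levels)
  expect_equal(bdeu_family_score(ds_p, "target", c(1L, 2L), cfg), base,
               tolerance = 1e-12)

  relab <- c(2L, 0L, 1L)  # bijection on predictor 1's codes 0..2
  codes2 <- ds$codes
  codes2[, 1] <- relab[codes2[, 1] + 1L]
  ds_r <- discrete_dataset(codes2, ds$arity, ds$kind, ds$target,
                           ds$target_levels)
  expect_equal(bdeu_family_score(ds_r, "target", c(1L, 2L), cfg), base,
               tolerance = 1e-12)
  # parent order does not change the score either
  expect_equal(bdeu_family_score(ds, "target", c(2L, 1L), cfg), base,
               tolerance = 1e-12)
})

test_that("log-space evaluation stays finite at very large sample counts", {
  n <- 1e6
  codes <- cbind(P1 = rep(0:1, length.out = n))
  ds <- discrete_dataset(codes, 2L, "miRNA",
                         rep(c(0L, 0L, 1L), length.out = n), c("a", "b"))
  s <- bdeu_family_score(ds, "target", 1L, score_config(54))
  expect_true(is.finite(s))
  expect_lt(s, 0)
})

test_that("invalid scoring inputs are rejected", {
  expect_error(score_config(0), "positive")
  expect_error(score_config(-3), "positive")
  ds <- make_ds(c(0L, 1L), target = c(0L, 1L), arity = 2L,
                target_levels = c("a", "b"))
  expect_error(count_sufficient_stats(ds, "target", c(1L, 1L)), "duplicated")
  expect_error(count_sufficient_stats(ds, "target", 5L), "invalid")
  expect_error(dag_model(c(2, 2)), "duplicated")
})
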