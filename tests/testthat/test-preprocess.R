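em <- function(v, ids, samples, kind = "miRNA", scale = "raw") {
  m <- matrix(v, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, samples))
  expression_matrix(m, kind, scale)
}

test_that("merge_by_patient intersects the three sample-ID sets in sorted order", {
  mi <- em(1:6, c("m1", "m2"), c("A", "B", "C"))
  mr <- em(1:6, c("g1", "g2"), c("B", "C", "D"), kind = "mRNA")
  cl <- data.frame(sample_id = c("B", "C"), target = c("tumor", "normal"))
  out <- merge_by_patient(mi, mr, cl)
  expect_equal(colnames(out$expr), c("B", "C"))
  expect_equal(rownames(out$expr), c("m1", "m2", "g1", "g2"))
  expect_equal(feature_kinds(out$expr),
               c(m1 = "miRNA", m2 = "miRNA", g1 = "mRNA", g2 = "mRNA"))
  expect_equal(as.character(out$target), c("tumor", "normal"))

  # identical sets: everything retained, sample order independent of input order
  cl2 <- data.frame(sample_id = c("C", "A", "B"), target = "tumor")
  mi2 <- .subset <- em(1:6, c("m1", "m2"), c("C", "A", "B"))
  out2 <- merge_by_patient(mi2, em(1:6, c("g1", "g2"), c("A", "B", "C"), "mRNA"), cl2)
  expect_equal(colnames(out2$expr), c("A", "B", "C"))
  expect_equal(unname(unclass(out2$expr)["m1", ]), c(2, 3, 1))
})

test_that("patients lacking a target value are dropped, by exact count", {
  d <- generate_dataset(synth_config(100, 3, 3, seed = 2))
  cl <- d$clinical
  drop <- seq(1, 100, by = 20)   # 5% clinical dropout
  cl$target[drop] <- NA
  out <- merge_by_patient(d$mirna, d$mrna, cl)
  expect_equal(ncol(out$expr), 100 - length(drop))
  expect_false(any(cl$sample_id[drop] %in% colnames(out$expr)))
})

test_that("an empty patient intersection errors with the three set sizes", {
  mi <- em(1:2, "m1", c("A", "B"))
  mr <- em(1:2, "g1", c("C", "D"), kind = "mRNA")
  cl <- data.frame(sample_id = c("A", "C"), target = "tumor")
  expect_error(merge_by_patient(mi, mr, cl), "2 miRNA.*2 mRNA.*2 clinical")
})

test_that("filter_all_zero drops exactly the all-zero features", {
  m <- em(c(0, 0, 0, 1, 2, 3, 0, 0, 5), c("a", "b", "c"), c("s1", "s2", "s3"))
  out <- filter_all_zero(m)
  expect_equal(rownames(out), c("b", "c"))
  expect_equal(unclass(filter_all_zero(out)), unclass(out))  # identity when clean
  one <- em(c(0, 0, 1e-9), "x", c("s1", "s2", "s3"))
  expect_equal(nrow(filter_all_zero(one)), 1L)               # single nonzero kept
  expect_error(filter_all_zero(log2_transform(m)), "raw scale")
})

test_that("log2_transform applies log2(x + pseudocount) and flips the scale flag", {
  m <- em(c(3, 0, 1, 1), c("a", "b"), c("s1", "s2"))
  out <- log2_transform(m, pseudocount = 1)
  expect_equal(attr(out, "scale"), "log2")
  expect_equal(unclass(out)["a", "s1"], 2)
  expect_equal(unclass(out)["a", "s2"], 0)
  expect_true(all(unclass(out)[2, ] == 1))
  expect_error(log2_transform(out), "already")
})

test_that("equal-width discretization matches its contract", {
  d <- discretize_equal_width(c(0, 1, 2, 3), 2)
  expect_equal(d$codes, c(0L, 0L, 1L, 1L))
  expect_equal(d$edges, c(0, 1.5, 3))
  expect_equal(d$arity, 2L)

  const <- discretize_equal_width(c(5, 5, 5), 3)
  expect_equal(const$codes, c(0L, 0L, 0L))
  expect_equal(const$arity, 1L)

  # the maximum maps to the top (closed) bin
  expect_equal(max(discretize_equal_width(c(0, 10), 4)$codes), 3L)
  expect_error(discretize_equal_width(1:3, 0), "nbins")
  expect_error(discretize_equal_width(c(1, NA), 2), "finite")
})

test_that("discretization is monotone and near-uniform on uniform input", {
  set.seed(42)
  for (rep in 1:20) {
    v <- rnorm(50)
    cd <- discretize_equal_width(v, sample(2:5, 1))$codes
    o <- order(v)
    expect_true(all(diff(cd[o]) >= 0))
  }
  u <- runif(10000)
  tab <- tabulate(discretize_equal_width(u, 4)$codes + 1L, 4)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(tab - 2500) < 3 * sigma))
})

test_that("candidate extraction uses the mature-arm suffix rule for miRNAs only", {
  cur <- data.frame(mirna = c("hsa-miR-101", "hsa-miR-21"),
                    mrna = c("TP53", "ESR1"))
  m <- em(seq_len(7), c("hsa-miR-101-5p", "hsa-miR-101-3p", "hsa-miR-101*",
                        "hsa-miR-21", "hsa-miR-210", "hsa-miR-101a", "hsa-miR-9"),
          "s1")
  out <- extract_candidates(m, cur)
  expect_equal(rownames(out),
               c("hsa-miR-101-5p", "hsa-miR-101-3p", "hsa-miR-101*", "hsa-miR-21"))
  expect_equal(rownames(extract_candidates(m, cur, suffix_match = FALSE)),
               "hsa-miR-21")

  g <- em(1:3, c("TP53", "TP53BP1", "ESR1"), "s1", kind = "mRNA")
  expect_equal(rownames(extract_candidates(g, cur)), c("TP53", "ESR1"))

  empty <- data.frame(mirna = character(), mrna = character())
  expect_equal(nrow(extract_candidates(m, empty)), 0L)
})

test_that("curation deduplication counts unique pairs and names", {
  out <- dedup_curation(data.frame(mirna = c("a", "a", "a"),
                                   mrna = c("X", "X", "Y")))
  expect_equal(out$n_pairs, 2L)
  expect_equal(out$n_mirna, 1L)
  expect_equal(out$n_mrna, 2L)

  empty <- dedup_curation(data.frame(mirna = character(), mrna = character()))
  expect_equal(unlist(empty[c("n_pairs", "n_mirna", "n_mrna")]),
               c(n_pairs = 0L, n_mirna = 0L, n_mrna = 0L))

  expect_error(dedup_curation(data.frame(mirna = c("a", NA), mrna = "X")),
               "row 2")
})

test_that("the packaged synthetic curation fixture reads and dedups as recorded", {
  path <- system.file("extdata", "synthetic_curation.csv", package = "mirbeam")
  raw <- read_curation_csv(path, dedup = FALSE)
  out <- dedup_curation(raw)
  expect_gt(nrow(raw), out$n_pairs)          # the fixture contains duplicates
  expect_equal(out$n_pairs, 12L)
  expect_equal(out$n_mirna, 6L)
  expect_equal(out$n_mrna, 12L)
})

test_that("build_discrete_dataset composes discretization and target encoding", {
  d <- generate_dataset(synth_config(40, 2, 3, seed = 6))
  merged <- merge_by_patient(d$mirna, d$mrna, d$clinical)
  ds <- build_discrete_dataset(log2_transform(filter_all_zero(merged$expr)),
                               merged$target, nbins = 3)
  expect_s3_class(ds, "discrete_dataset")
  expect_equal(ds$n_samples, 40L)
  expect_equal(ncol(ds$codes), 5L)
  expect_true(all(ds$arity %in% c(1L, 3L)))
  expect_true(all(ds$codes >= 0L & t(t(ds$codes)) < rep(ds$arity, each = 40)))
  expect_equal(ds$target_levels, sort(unique(d$clinical$target)))
  expect_error(build_discrete_dataset(merged$expr, merged$target), "log2")

  # constant feature handled as arity 1
  m <- em(c(1, 1, 1, 0, 2, 4), c("f1", "f2"), c("A", "B", "C"), scale = "log2")
  ds2 <- build_discrete_dataset(m, c("x", "y", "x"), nbins = 3)
  expect_equal(ds2$arity, c(1L, 3L))
  expect_equal(ds2$target, c(0L, 1L, 0L))
})
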