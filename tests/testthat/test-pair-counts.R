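test_that("binarization maps zeros to absent and positive counts to present", {
  x <- matrix(c(0, 1, 37, 0), 1, dimnames = list("s1", paste0("t", 1:4)))
  expect_identical(unname(binarize_table(x)[1, ]), c(0L, 1L, 1L, 0L))
  expect_identical(unname(binarize_table(x, threshold = 5)[1, ]),
                   c(0L, 0L, 1L, 0L))
  zeros <- matrix(0, 3, 2)
  expect_true(all(binarize_table(zeros) == 0L))
  expect_error(binarize_table(matrix(-1, 1, 1)), "negative")
  expect_error(binarize_table(x, threshold = 0), "positive")
})

test_that("pair counts tabulate the four joint outcomes exactly", {
  b1 <- c(1, 1, 0, 0, 1)
  b2 <- c(1, 0, 1, 0, 1)
  cc <- pair_counts(b1, b2)
  expect_identical(unclass(cc)[1:4],
                   c(alpha = 1L, beta = 1L, gamma = 1L, delta = 2L))
  expect_identical(attr(cc, "n"), 5L)

  # identical vectors: no discordant cells
  cc <- pair_counts(b1, b1)
  expect_identical(unname(unclass(cc)[1:4]), c(2L, 0L, 0L, 3L))
  # complement: no concordant cells
  cc <- pair_counts(b1, 1 - b1)
  expect_identical(unname(unclass(cc)[1:4]), c(0L, 2L, 3L, 0L))

  expect_error(pair_counts(b1, b2[-1]), "length")
  expect_error(pair_counts(b1, c(1, 0, 2, 0, 1)), "binary")
})

test_that("marginal construction reproduces the gut-census worked example", {
  cc <- pair_counts_from_marginals(n = 822, ones_i = 112, ones_j = 132,
                                   overlap = 22)
  expect_identical(unclass(cc)[1:4],
                   c(alpha = 600L, beta = 110L, gamma = 90L, delta = 22L))
  # and it agrees with tabulating any pair of vectors with those marginals
  b1 <- c(rep(1, 112), rep(0, 710))
  b2 <- c(rep(1, 22), rep(0, 90), rep(1, 110), rep(0, 600))
  expect_identical(unclass(pair_counts(b1, b2)), unclass(cc))
  expect_error(pair_counts_from_marginals(10, 8, 8, 2), "incompatible")
})

test_that("boolean_combine applies truth tables elementwise", {
  b1 <- c(0, 0, 1, 1)
  b2 <- c(0, 1, 0, 1)
  expect_identical(boolean_combine(b1, b2, "AND"), c(0L, 0L, 0L, 1L))
  expect_identical(boolean_combine(b1, b2, "OR"), c(0L, 1L, 1L, 1L))
  expect_identical(boolean_combine(b1, b2, "XOR"), c(0L, 1L, 1L, 0L))
  expect_identical(boolean_combine(b1, b2, "NOR"), c(1L, 0L, 0L, 0L))
  expect_identical(boolean_combine(b1, b2, "GT"), c(0L, 0L, 1L, 0L))
  expect_identical(boolean_combine(b1, b2, "LE"), c(1L, 1L, 0L, 1L))
  x <- rbinom(30, 1, 0.5)
  expect_identical(boolean_combine(x, x, "XOR"), rep(0L, 30))
  expect_error(boolean_combine(b1, b2, "IMPLIES"), "unknown")
})

test_that("ones-counts after AND/OR follow the pair-count identities", {
  cc <- pair_counts_from_marginals(822, 112, 132, 22)
  b1 <- c(rep(1, 112), rep(0, 710))
  b2 <- c(rep(1, 22), rep(0, 90), rep(1, 110), rep(0, 600))
  expect_identical(sum(boolean_combine(b1, b2, "AND")), 22L)        # delta
  expect_identical(sum(boolean_combine(b1, b2, "OR")), 222L)        # beta+gamma+delta
  expect_identical(unclass(shifted_pair_counts(cc, "AND"))[1:4],
                   c(alpha = 690L, beta = 110L, gamma = 0L, delta = 22L))
  expect_identical(unclass(shifted_pair_counts(cc, "OR"))[1:4],
                   c(alpha = 600L, beta = 0L, gamma = 90L, delta = 132L))
})

test_that("shifted counts match direct tabulation for every operation (property)", {
  set.seed(99)
  for (trial in 1:25) {
    n <- sample(5:60, 1)
    b1 <- rbinom(n, 1, runif(1))
    b2 <- rbinom(n, 1, runif(1))
    cc <- pair_counts(b1, b2)
    for (op in boolean_ops()) {
      shifted <- shifted_pair_counts(cc, op)
      direct <- pair_counts(boolean_combine(b1, b2, op), b2)
      expect_identical(unclass(shifted), unclass(direct))
      # count conservation
      expect_identical(attr(shifted, "n"), attr(cc, "n"))
    }
    # monotonicity: AND never gains ones, OR never loses them
    expect_lte(sum(boolean_combine(b1, b2, "AND")), sum(b1))
    expect_gte(sum(boolean_combine(b1, b2, "OR")), sum(b1))
  }
})

test_that("count conservation and entropy bounds hold over random pair-count draws", {
  set.seed(7)
  m <- 10000L
  counts <- matrix(rpois(4L * m, lambda = 20), ncol = 4L)
  ops <- boolean_ops()
  for (r in seq_len(m)) {
    cc <- esabo:::new_pair_counts(counts[r, 1], counts[r, 2],
                                  counts[r, 3], counts[r, 4])
    op <- ops[1L + (r %% length(ops))]
    sh <- shifted_pair_counts(cc, op)
    if (sum(sh) != sum(cc)) fail(sprintf("conservation broken for %s", op))
    h <- counts_entropy(sh)
    if (h < 0 || h > log(2) + 1e-12) fail("entropy out of bounds")
  }
  succeed()
})

test_that("binary entropy has the right extremes, symmetry, and closed form", {
  expect_identical(binary_entropy(rep(1, 10)), 0)
  expect_identical(binary_entropy(rep(0, 7)), 0)
  expect_equal(binary_entropy(rep(c(0, 1), 10)), log(2))
  expect_equal(binary_entropy(c(1, 0, 0, 0), base = 2), entropy_from_p(0.25) / log(2))
  # H(p) = H(1-p)
  p <- runif(20)
  expect_equal(entropy_from_p(p), entropy_from_p(1 - p))
  expect_error(binary_entropy(numeric(0)), "empty")

  # closed form on the worked example: H before and after AND
  cc <- pair_counts_from_marginals(822, 112, 132, 22)
  expect_equal(counts_entropy(cc), entropy_from_p(112 / 822))
  expect_equal(round(counts_entropy(cc), 3), 0.398)
  after <- counts_entropy(shifted_pair_counts(cc, "AND"))
  expect_equal(after, entropy_from_p(22 / 822))
  expect_equal(round(after, 3), 0.123)
  expect_lt(after, counts_entropy(cc)) # the vector became simpler
})

test_that("entropy route equivalence: vectors vs shifted-count closed form", {
  set.seed(13)
  for (trial in 1:20) {
    n <- sample(10:80, 1)
    b1 <- rbinom(n, 1, runif(1))
    b2 <- rbinom(n, 1, runif(1))
    op <- sample(boolean_ops(), 1)
    h_vec <- binary_entropy(boolean_combine(b1, b2, op))
    h_cnt <- counts_entropy(shifted_pair_counts(pair_counts(b1, b2), op))
    expect_equal(h_vec, h_cnt)
  }
})

test_that("co-occurrence z-score reproduces the printed worked example", {
  cc <- pair_counts_from_marginals(822, 112, 132, 22)
  res <- cooccurrence_zscore(cc)
  expect_equal(res$expectation, 112 * 132 / 822)
  expect_equal(round(res$expectation, 2), 17.99)
  expect_equal(res$variance, 112 * 132 * 690 / 822^2)
  expect_equal(round(res$variance, 1), 15.1)
  # deviation normalized by the variance, as in the printed convention
  expect_equal(res$z, (22 - res$expectation) / res$variance)
  # conventional variant divides by the standard deviation
  alt <- cooccurrence_zscore_std(cc)
  expect_equal(alt$z, (22 - res$expectation) / sqrt(res$variance))
  expect_error(cooccurrence_zscore(esabo:::new_pair_counts(0, 0, 0, 0)),
               "empty")
})

test_that("Jaccard indices for presence and absence behave at the extremes", {
  b1 <- c(rep(1, 112), rep(0, 710))
  b2 <- c(rep(1, 22), rep(0, 90), rep(1, 110), rep(0, 600))
  j <- jaccard_scores(b1, b2)
  expect_equal(j$j11, 22 / 112)
  expect_equal(j$j00, 600 / 690)

  x <- c(1, 1, 0, 0)
  expect_equal(jaccard_scores(x, x), list(j11 = 1, j00 = 1))
  # disjoint supports
  expect_equal(jaccard_scores(c(1, 1, 0, 0), c(0, 0, 1, 1))$j11, 0)
  # degenerate marginals are flagged, not zeroed
  expect_true(is.na(jaccard_scores(c(1, 1, 1), c(1, 0, 1))$j00))
  expect_true(is.na(jaccard_scores(c(0, 0, 0), c(1, 0, 1))$j11))
})
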