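#' Binarize an abundance table
#'
#' Maps a sample-by-taxon table of non-negative abundances (counts or
#' relative abundances) to presence/absence: an entry becomes 1 exactly
#' when the abundance is at least `threshold`.  With count data the
#' default threshold of 1 maps zeros to absent and every positive count to
#' present.
#'
#' @param abundances numeric matrix or data frame, rows = samples,
#'   columns = taxa, entries non-negative.
#' @param threshold positive presence cutoff (default 1).
#' @return Binary integer matrix with the input dimnames.
#' @examples
#' binarize_table(matrix(c(0, 1, 37, 0), 1), threshold = 1)
#' @export
binarize_table <- function(abundances, threshold = 1) {
  if (is.data.frame(abundances)) abundances <- as.matrix(abundances)
  if (!is.numeric(abundances)) {
    stop("abundance table must be numeric", call. = FALSE)
  }
  if (anyNA(abundances)) stop("abundance table contains NA", call. = FALSE)
  if (any(abundances < 0)) {
    stop("abundance table contains negative values", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  out <- (abundances >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Joint presence/absence counts for a species pair
#'
#' Tabulates the four joint outcomes of two binary abundance vectors
#' across samples: `alpha` = #(0,0), `beta` = #(0,1), `gamma` = #(1,0),
#' `delta` = #(1,1).  These four counts carry all pairwise information
#' used by the co-occurrence and entropy statistics.
#'
#' @param b_i,b_j binary vectors of equal length (abundance vectors of the
#'   two species), or for `pair_counts_from_marginals` the marginal
#'   ones-counts and overlap.
#' @return Object of class `pair_counts`: named integer vector
#'   `(alpha, beta, gamma, delta)` with attribute `n` (total samples).
#' @examples
#' pair_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' pair_counts_from_marginals(n = 822, ones_i = 112, ones_j = 132,
#'                            overlap = 22)
#' @export
pair_counts <- function(b_i, b_j) {
  if (length(b_i) != length(b_j)) {
    stop("abundance vectors differ in length", call. = FALSE)
  }
  if (!is_binary_vector(b_i) || !is_binary_vector(b_j)) {
    stop("abundance vectors must be binary", call. = FALSE)
  }
  delta <- sum(b_i == 1 & b_j == 1)
  gamma <- sum(b_i == 1) - delta
  beta <- sum(b_j == 1) - delta
  alpha <- length(b_i) - delta - gamma - beta
  new_pair_counts(alpha, beta, gamma, delta)
}

new_pair_counts <- function(alpha, beta, gamma, delta) {
  x <- as.integer(c(alpha = alpha, beta = beta, gamma = gamma, delta = delta))
  names(x) <- c("alpha", "beta", "gamma", "delta")
  if (any(x < 0)) stop("pair counts must be non-negative", call. = FALSE)
  structure(x, n = sum(x), class = "pair_counts")
}

#' @rdname pair_counts
#' @param n total number of samples.
#' @param ones_i,ones_j ones-counts (presences) of the two species.
#' @param overlap number of samples where both are present (`delta`).
#' @export
pair_counts_from_marginals <- function(n, ones_i, ones_j, overlap) {
  if (overlap > min(ones_i, ones_j) || overlap < ones_i + ones_j - n ||
      overlap < 0) {
    stop("overlap incompatible with the marginals", call. = FALSE)
  }
  new_pair_counts(
    alpha = n - ones_i - ones_j + overlap,
    beta = ones_j - overlap,
    gamma = ones_i - overlap,
    delta = overlap
  )
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf(
    "pair_counts (n = %d): alpha=%d beta=%d gamma=%d delta=%d\n",
    attr(x, "n"), x[["alpha"]], x[["beta"]], x[["gamma"]], x[["delta"]]
  ))
  invisible(x)
}

# Truth tables of the ten informative two-input Boolean operations,
# as output bits for inputs (0,0), (0,1), (1,0), (1,1).  The six
# remaining operations (constants, identities and their complements)
# carry no pairwise information and are deliberately unsupported.
BOOLEAN_OPS <- list(
  AND  = c(0L, 0L, 0L, 1L),
  OR   = c(0L, 1L, 1L, 1L),
  XOR  = c(0L, 1L, 1L, 0L),
  NAND = c(1L, 1L, 1L, 0L),
  NOR  = c(1L, 0L, 0L, 0L),
  EQL  = c(1L, 0L, 0L, 1L),
  GT   = c(0L, 0L, 1L, 0L),
  GE   = c(1L, 0L, 1L, 1L),
  LT   = c(0L, 1L, 0L, 0L),
  LE   = c(1L, 1L, 0L, 1L)
)

#' Supported Boolean operations
#'
#' @return Character vector of the ten informative two-input operation
#'   labels: the symmetric `AND`, `OR`, `XOR`, `NAND`, `NOR`, `EQL`
#'   (equality test) and the asymmetric comparisons `GT`, `GE`, `LT`,
#'   `LE` (first argument compared to the second).
#' @export
boolean_ops <- function() names(BOOLEAN_OPS)

match_op <- function(op) {
  if (!is.character(op) || length(op) != 1L) {
    stop("op must be a single operation label", call. = FALSE)
  }
  op <- toupper(op)
  if (!op %in% names(BOOLEAN_OPS)) {
    stop(sprintf("unknown Boolean operation '%s'; supported: %s",
                 op, paste(names(BOOLEAN_OPS), collapse = ", ")),
         call. = FALSE)
  }
  op
}

#' Elementwise Boolean combination of two binary vectors
#'
#' @param b_i,b_j binary vectors of equal length.
#' @param op operation label, see [boolean_ops()].
#' @return Binary integer vector `op(b_i, b_j)` of the same length.
#' @examples
#' boolean_combine(c(1, 1, 0), c(1, 0, 1), "AND")
#' @export
boolean_combine <- function(b_i, b_j, op = "AND") {
  op <- match_op(op)
  if (length(b_i) != length(b_j)) {
    stop("vectors differ in length", call. = FALSE)
  }
  if (!is_binary_vector(b_i) || !is_binary_vector(b_j)) {
    stop("vectors must be binary", call. = FALSE)
  }
  tt <- BOOLEAN_OPS[[op]]
  tt[1L + 2L * as.integer(b_i) + as.integer(b_j)]
}

#' Pair counts after a Boolean operation
#'
#' Given the joint counts of `(b_i, b_j)`, returns the joint counts of
#' `(x, b_j)` where `x = op(b_i, b_j)`, by closed-form bookkeeping on the
#' operation's truth table — no vectors needed.  For `AND` the `gamma`
#' entries (present in `i` only) are shifted into the `alpha` field; for
#' `OR` the `beta` entries join `delta`.  The total count is conserved for
#' every operation.
#'
#' @param counts a [pair_counts()] object.
#' @param op operation label, see [boolean_ops()].
#' @return A `pair_counts` object for the pair `(op(b_i, b_j), b_j)`.
#' @examples
#' cc <- pair_counts_from_marginals(822, 112, 132, 22)
#' shifted_pair_counts(cc, "AND") # (690, 110, 0, 22)
#' @export
shifted_pair_counts <- function(counts, op = "AND") {
  stopifnot(inherits(counts, "pair_counts"))
  op <- match_op(op)
  tt <- BOOLEAN_OPS[[op]]
  # original cells (b_i, b_j): alpha=(0,0) beta=(0,1) gamma=(1,0) delta=(1,1)
  # land in cell (tt[cell], b_j) of the shifted table
  new <- c(alpha = 0L, beta = 0L, gamma = 0L, delta = 0L)
  dest <- function(x_bit, j_bit) {
    if (x_bit == 0L) {
      if (j_bit == 0L) "alpha" else "beta"
    } else {
      if (j_bit == 0L) "gamma" else "delta"
    }
  }
  j_bits <- c(0L, 1L, 0L, 1L) # b_j bit of cells alpha, beta, gamma, delta
  for (cell in 1:4) {
    d <- dest(tt[cell], j_bits[cell])
    new[d] <- new[d] + counts[[cell]]
  }
  new_pair_counts(new["alpha"], new["beta"], new["gamma"], new["delta"])
}

#' Shannon entropy of a binary vector
#'
#' `H = -(p log p + (1 - p) log(1 - p))` with `p` the fraction of ones,
#' using the convention `0 log 0 = 0`.  In natural-log units (the
#' default) `H` ranges from 0 (constant vector) to `log 2` (half ones);
#' with `base = 2` the maximum is 1 bit.  z-scores built from these
#' entropies are invariant under the choice of base.
#'
#' @param x binary vector, or for `entropy_from_p` the ones-fraction.
#' @param base logarithm base (`exp(1)` for nats, `2` for bits).
#' @return Entropy (non-negative scalar).
#' @examples
#' binary_entropy(c(1, 1, 0, 0)) # log(2)
#' @export
binary_entropy <- function(x, base = exp(1)) {
  if (length(x) == 0L) stop("empty vector", call. = FALSE)
  if (!is_binary_vector(x)) stop("vector must be binary", call. = FALSE)
  entropy_from_p(mean(x), base = base)
}

#' @rdname binary_entropy
#' @param p ones-fraction in `[0, 1]` (vectorized).
#' @export
entropy_from_p <- function(p, base = exp(1)) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  term <- function(q) ifelse(q == 0, 0, -q * log(q, base = base))
  term(p) + term(1 - p)
}

#' Entropy of the first species' abundance vector from pair counts
#'
#' The ones-fraction of `b_i` is `(gamma + delta) / n`, so its entropy is
#' a pure function of the pair counts; applying this to
#' [shifted_pair_counts()] gives the closed-form entropy after a Boolean
#' operation, bypassing the vectors entirely.
#'
#' @param counts a [pair_counts()] object.
#' @param base logarithm base.
#' @return Entropy of the (possibly shifted) abundance vector of species `i`.
#' @examples
#' cc <- pair_counts_from_marginals(822, 112, 132, 22)
#' counts_entropy(cc)                             # before AND
#' counts_entropy(shifted_pair_counts(cc, "AND")) # after AND: simpler
#' @export
counts_entropy <- function(counts, base = exp(1)) {
  stopifnot(inherits(counts, "pair_counts"))
  n <- attr(counts, "n")
  if (n == 0L) stop("empty pair counts", call. = FALSE)
  entropy_from_p((counts[["gamma"]] + counts[["delta"]]) / n, base = base)
}

#' Binomial co-occurrence z-score
#'
#' Under random placement of the `gamma + delta` presences of species `i`
#' among samples, the co-occurrence count `delta` has binomial expectation
#' `(gamma + delta)(beta + delta) / n` and variance
#' `(gamma + delta)(beta + delta)(alpha + gamma) / n^2`.
#' `cooccurrence_zscore` follows the worked-example convention of
#' normalizing the deviation by the *variance*; the statistically
#' conventional standard-deviation normalization is available as
#' `cooccurrence_zscore_std`.
#'
#' @param counts a [pair_counts()] object with `n > 0`.
#' @return List with elements `expectation`, `variance`, and `z`.
#' @examples
#' cc <- pair_counts_from_marginals(822, 112, 132, 22)
#' cooccurrence_zscore(cc) # expectation 17.99, variance 15.1, z 0.27
#' @export
cooccurrence_zscore <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  n <- attr(counts, "n")
  if (n == 0L) stop("empty pair counts", call. = FALSE)
  a <- counts[["alpha"]]; b <- counts[["beta"]]
  g <- counts[["gamma"]]; d <- counts[["delta"]]
  expectation <- (g + d) * (b + d) / n
  variance <- (g + d) * (b + d) * (a + g) / n^2
  z <- if (variance > 0) (d - expectation) / variance else NA_real_
  list(expectation = expectation, variance = variance, z = z)
}

#' @rdname cooccurrence_zscore
#' @export
cooccurrence_zscore_std <- function(counts) {
  res <- cooccurrence_zscore(counts)
  res$z <- if (res$variance > 0) {
    (counts[["delta"]] - res$expectation) / sqrt(res$variance)
  } else NA_real_
  res
}

#' Binary Jaccard indices for presence and absence
#'
#' `j11 = delta / min(gamma + delta, beta + delta)` normalizes the
#' co-presence count by the smaller marginal presence count; it is
#' sensitive to synergistic association.  `j00 = alpha / min(alpha + beta,
#' alpha + gamma)` does the same for co-absence and is sensitive to
#' competitive association.  Either index is `NA` when its normalizing
#' marginal is zero (a species present in no sample, or in every sample,
#' respectively).
#'
#' @param b_i,b_j binary vectors of equal length.
#' @return List with elements `j11` and `j00` (each in `[0, 1]` or `NA`).
#' @examples
#' jaccard_scores(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
jaccard_scores <- function(b_i, b_j) {
  counts <- pair_counts(b_i, b_j)
  jaccard_from_counts(counts)
}

jaccard_from_counts <- function(counts) {
  a <- counts[["alpha"]]; b <- counts[["beta"]]
  g <- counts[["gamma"]]; d <- counts[["delta"]]
  min1 <- min(g + d, b + d)
  min0 <- min(a + b, a + g)
  list(
    j11 = if (min1 > 0) d / min1 else NA_real_,
    j00 = if (min0 > 0) a / min0 else NA_real_
  )
}
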