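#' All-pairs ESABO scores of a binary abundance table
#'
#' Computes the ESABO z-score for every unordered pair of taxa in a
#' binarized sample-by-taxon table.  Because the permutation null shuffles
#' only the second vector, the two ordered scores of a pair differ
#' slightly; the reported score is their mean and the absolute
#' symmetrization residuals are returned for inspection.  Constant
#' columns (taxa present in every sample or in none) have a degenerate
#' null and yield `NA` rows/columns rather than being dropped silently.
#'
#' @param table binary matrix, rows = samples, columns = taxa (use
#'   [binarize_table()] on raw abundances first).
#' @param op Boolean operation (default `"AND"`).
#' @param n_shuffles permutations per ordered score (default 1000).
#' @param seed optional integer seed.
#' @return Object of class `esabo_scores`: a list with `z` (symmetric
#'   numeric matrix, `NA` on the diagonal and for unscorable pairs),
#'   `asymmetry` (matrix of `|z_ij - z_ji| / 2`), `unscorable` (labels of
#'   constant taxa), and the scoring parameters.
#' @examples
#' \donttest{
#' net <- example_interaction_network()
#' A <- sample_attractor_table(net, 300, seed = 1)
#' sc <- score_all_pairs(A, n_shuffles = 200, seed = 2)
#' sc$z["H", "M"] # synergistic pair: strongly positive
#' }
#' @export
score_all_pairs <- function(table, op = "AND", n_shuffles = 1000L,
                            seed = NULL) {
  assert_binary_matrix(table)
  op <- match_op(op)
  if (ncol(table) < 2L || nrow(table) < 2L) {
    stop("need at least 2 taxa and 2 samples", call. = FALSE)
  }
  labels <- colnames(table)
  if (is.null(labels)) labels <- paste0("t", seq_len(ncol(table)))
  p <- ncol(table)
  col_const <- apply(table, 2, function(x) all(x == x[1]))
  if (sum(!col_const) < 2L) {
    stop("fewer than 2 non-constant taxa: nothing to score", call. = FALSE)
  }
  z <- asym <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  with_seed(seed, {
    for (i in seq_len(p - 1L)) {
      for (j in seq((i + 1L), p)) {
        if (col_const[i] || col_const[j]) next
        r1 <- esabo_score(table[, i], table[, j], op = op,
                          n_shuffles = n_shuffles)
        r2 <- esabo_score(table[, j], table[, i], op = op,
                          n_shuffles = n_shuffles)
        zs <- c(r1$z, r2$z)
        if (all(is.na(zs))) next
        z[i, j] <- z[j, i] <- mean(zs, na.rm = TRUE)
        if (!anyNA(zs)) asym[i, j] <- asym[j, i] <- abs(zs[1] - zs[2]) / 2
      }
    }
  })
  structure(
    list(
      z = z,
      asymmetry = asym,
      unscorable = labels[col_const],
      operation = op,
      n_shuffles = n_shuffles,
      n_samples = nrow(table),
      seed = seed
    ),
    class = "esabo_scores"
  )
}

#' @export
print.esabo_scores <- function(x, ...) {
  cat(sprintf(
    "esabo_scores: %d taxa, %d samples, op %s, %d shuffles\n",
    ncol(x$z), x$n_samples, x$operation, x$n_shuffles
  ))
  if (length(x$unscorable)) {
    cat("  unscorable (constant) taxa:",
        paste(x$unscorable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Threshold an ESABO score matrix into a signed network
#'
#' Pairs scoring at or above `pos_threshold` become synergistic (+1)
#' edges, pairs at or below `neg_threshold` competitive (-1) edges;
#' scores strictly between the thresholds, and undefined scores, yield no
#' edge.  The default cutoffs of +1 / -1 standard deviation match the
#' score's interpretation as a distance from the permutation null; the
#' negative threshold often needs independent adjustment because
#' broad resource competition can depress many pair scores at once.
#'
#' @param scores an `esabo_scores` object from [score_all_pairs()], or a
#'   symmetric numeric score matrix.
#' @param pos_threshold minimum score of a synergistic edge (default 1).
#' @param neg_threshold maximum score of a competitive edge (default -1).
#' @return Object of class `inferred_network`: a list with `nodes`,
#'   `edges` (data frame `from`, `to`, `sign`, `score`), the thresholds,
#'   and provenance.  No multiple-testing correction is applied; the
#'   thresholds act on raw z-scores.
#' @examples
#' m <- matrix(c(NA, 2.3, -1.4, 2.3, NA, 0.2, -1.4, 0.2, NA), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' extract_signed_network(m)
#' @export
extract_signed_network <- function(scores, pos_threshold = 1.0,
                                   neg_threshold = -1.0) {
  provenance <- NULL
  if (inherits(scores, "esabo_scores")) {
    provenance <- list(operation = scores$operation,
                       n_shuffles = scores$n_shuffles,
                       n_samples = scores$n_samples,
                       seed = scores$seed)
    scores <- scores$z
  }
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop("scores must be a square matrix or an esabo_scores object",
         call. = FALSE)
  }
  if (pos_threshold <= neg_threshold) {
    stop("pos_threshold must exceed neg_threshold", call. = FALSE)
  }
  labels <- rownames(scores)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(scores)))
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  s <- scores[idx]
  sign <- ifelse(is.na(s), 0L,
                 ifelse(s >= pos_threshold, 1L,
                        ifelse(s <= neg_threshold, -1L, 0L)))
  keep <- sign != 0L
  edges <- data.frame(
    from = labels[idx[keep, 1]],
    to = labels[idx[keep, 2]],
    sign = sign[keep],
    score = s[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = labels,
      edges = edges,
      pos_threshold = pos_threshold,
      neg_threshold = neg_threshold,
      provenance = provenance
    ),
    class = "inferred_network"
  )
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf(
    "inferred_network: %d nodes, %d synergistic / %d competitive edges (thresholds +%g / %g)\n",
    length(x$nodes), sum(x$edges$sign == 1), sum(x$edges$sign == -1),
    x$pos_threshold, x$neg_threshold
  ))
  invisible(x)
}

#' Degrees and components of an inferred network
#'
#' Synergistic and competitive links typically organize differently —
#' e.g. a connected mutualistic backbone versus a few fragmented
#' competitive pairs — so degrees and connected components are reported
#' separately per sign.
#'
#' @param net an `inferred_network` from [extract_signed_network()].
#' @return List with `degrees` (data frame `node`, `k_pos`, `k_neg`) and
#'   `components`: for each sign, the number of connected components with
#'   at least one edge and the component membership of non-isolated
#'   nodes.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "inferred_network"))
  deg <- data.frame(node = net$nodes, k_pos = 0L, k_neg = 0L,
                    stringsAsFactors = FALSE)
  comp_summary <- list()
  for (cls in c("positive", "negative")) {
    sgn <- if (cls == "positive") 1L else -1L
    e <- net$edges[net$edges$sign == sgn, , drop = FALSE]
    tab <- table(factor(c(e$from, e$to), levels = net$nodes))
    if (cls == "positive") deg$k_pos <- as.integer(tab) else
      deg$k_neg <- as.integer(tab)
    if (nrow(e) == 0L) {
      comp_summary[[cls]] <- list(n_components = 0L, membership = integer(0))
      next
    }
    g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    comp_summary[[cls]] <- list(
      n_components = as.integer(comp$no),
      membership = comp$membership
    )
  }
  list(degrees = deg, components = comp_summary)
}
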