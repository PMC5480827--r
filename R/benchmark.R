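#' Prediction quality of ESABO z-scores for one sign class
#'
#' For synergistic (positive) links a z-score above +1 counts as correct
#' and below -1 as incorrect; for competitive (negative) links the roles
#' are reversed.  The quality is (correct - incorrect) / n and lies in
#' `[-1, 1]`; scores inside `[-1, 1]` contribute nothing.  A quality of
#' 0.5 means 50 percent more links classified correctly than incorrectly.
#'
#' @param z_values numeric vector of z-scores (no `NA`; exclude undefined
#'   scores upstream).
#' @param link_class `"positive"` or `"negative"`.
#' @return Quality in `[-1, 1]`.
#' @examples
#' prediction_quality_z(c(2, 0.5, -2, 3), "positive") # 0.25
#' @export
prediction_quality_z <- function(z_values, link_class = c("positive",
                                                          "negative")) {
  link_class <- match.arg(link_class)
  if (length(z_values) == 0L) stop("empty score list", call. = FALSE)
  if (anyNA(z_values)) {
    stop("z_values contains NA; drop undefined scores first", call. = FALSE)
  }
  hi <- sum(z_values > 1)
  lo <- sum(z_values < -1)
  n <- length(z_values)
  if (link_class == "positive") (hi - lo) / n else (lo - hi) / n
}

#' Prediction quality of binary Jaccard indices
#'
#' Counting rule for Jaccard-based classification: an index above 0.6
#' counts as correct, one in the intermediate band (0.4, 0.6] counts as
#' incorrect, and one below -0.4 (impossible for a non-negative index,
#' retained for fidelity to the rule as stated) also counts as incorrect.
#' For positive links the `j11` index is used upstream, for negative
#' links `j00`.  Unlike the z-score rule, the 0.6/0.4 cutoffs have no
#' interpretation as distances from a null distribution.
#'
#' @param j_values numeric vector of Jaccard indices (no `NA`).
#' @param link_class `"positive"` or `"negative"` (same rule for both;
#'   the class chooses which index is supplied).
#' @return Quality in `[-1, 1]`.
#' @examples
#' prediction_quality_jaccard(c(0.7, 0.3), "positive") # 0.5
#' @export
prediction_quality_jaccard <- function(j_values,
                                       link_class = c("positive",
                                                      "negative")) {
  match.arg(link_class)
  if (length(j_values) == 0L) stop("empty score list", call. = FALSE)
  if (anyNA(j_values)) {
    stop("j_values contains NA; drop undefined scores first", call. = FALSE)
  }
  n <- length(j_values)
  (sum(j_values > 0.6) - sum(j_values > 0.4 & j_values <= 0.6) -
      sum(j_values < -0.4)) / n
}

#' Score the edges of an ensemble of simulated networks
#'
#' The core calibration experiment: generates `n_networks` random
#' connected signed networks, samples a distinct-attractor table from
#' each (regenerating networks whose table has too few distinct steady
#' states), optionally corrupts the table with binary noise, and records
#' the symmetrized ESABO AND z-score and both Jaccard indices for every
#' true edge — and, optionally, for a random sample of absent pairs of
#' size `max(m_pos, m_neg)` per network.
#'
#' @param n_networks number of networks in the ensemble.
#' @param n_nodes,m_pos,m_neg network parameters (nodes, positive edges,
#'   negative edges).
#' @param n_initial random initial conditions per network.
#' @param n_shuffles permutations per ESABO score (default 200).
#' @param noise_level binary substitution noise applied to the table
#'   (default 0).
#' @param seed optional integer seed.
#' @param include_absent also score a random sample of non-edges.
#' @param weighting attractor sampling mode, see
#'   [sample_attractor_table()].
#' @param min_attractors minimum number of distinct steady states a
#'   network must produce to enter the ensemble (default 100; networks
#'   below it are regenerated).  Set to 0 to disable.
#' @param max_regen cap on regenerations per ensemble slot.
#' @return Data frame of class `edge_score_set` with one row per scored
#'   pair: `network_id`, `from`, `to`, `true_sign` (+1, -1, or 0 for
#'   absent pairs), `z`, `j11`, `j00`, `n_samples` (rows of that
#'   network's table).  Undefined z-scores appear as `NA`.  The attribute
#'   `config` records the full parameterization; `n_regenerated` counts
#'   networks that failed the attractor-count requirement.
#' @examples
#' \donttest{
#' es <- run_ensemble(3, 15, 10, 10, n_initial = 300, seed = 1)
#' tapply(es$z, es$true_sign, mean, na.rm = TRUE)
#' }
#' @export
run_ensemble <- function(n_networks, n_nodes, m_pos, m_neg,
                         n_initial = 500L, n_shuffles = 200L,
                         noise_level = 0, seed = NULL,
                         include_absent = FALSE,
                         weighting = c("distinct", "basin_weighted"),
                         min_attractors = 100L, max_regen = 200L) {
  weighting <- match.arg(weighting)
  with_seed(seed, {
    rows <- vector("list", n_networks)
    n_regen <- 0L
    for (w in seq_len(n_networks)) {
      net <- NULL
      tab <- NULL
      for (try in seq_len(max_regen)) {
        cand <- generate_random_signed_network(n_nodes, m_pos, m_neg)
        cand_tab <- sample_attractor_table(cand, n_initial,
                                           weighting = "distinct")
        if (nrow(cand_tab) > min_attractors) {
          net <- cand
          tab <- if (weighting == "distinct") cand_tab else
            sample_attractor_table(cand, n_initial,
                                   weighting = "basin_weighted")
          break
        }
        n_regen <- n_regen + 1L
      }
      if (is.null(net)) {
        stop(sprintf(
          "no network with more than %d distinct attractors found in %d tries",
          min_attractors, max_regen
        ), call. = FALSE)
      }
      if (noise_level > 0) tab <- add_binary_noise(tab, noise_level)
      edges <- network_edges(net)
      if (include_absent) {
        non <- network_non_edges(net)
        k <- min(nrow(non), max(m_pos, m_neg))
        non <- non[sample.int(nrow(non), k), , drop = FALSE]
        non$sign <- 0L
        edges <- rbind(edges, non)
      }
      rows[[w]] <- score_edge_table(tab, edges, n_shuffles,
                                    network_id = w)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "config") <- list(
      n_networks = n_networks, n_nodes = n_nodes, m_pos = m_pos,
      m_neg = m_neg, n_initial = n_initial, n_shuffles = n_shuffles,
      noise_level = noise_level, include_absent = include_absent,
      weighting = weighting, min_attractors = min_attractors, seed = seed
    )
    attr(out, "n_regenerated") <- n_regen
    class(out) <- c("edge_score_set", class(out))
    out
  })
}

# score a set of node pairs against a binary table (internal)
score_edge_table <- function(tab, edges, n_shuffles, network_id) {
  labels <- colnames(tab)
  z <- j11 <- j00 <- numeric(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    bi <- tab[, match(edges$from[r], labels)]
    bj <- tab[, match(edges$to[r], labels)]
    z[r] <- .esabo_z_sym(bi, bj, n_shuffles)
    jj <- jaccard_scores(bi, bj)
    j11[r] <- jj$j11
    j00[r] <- jj$j00
  }
  data.frame(
    network_id = network_id,
    from = edges$from,
    to = edges$to,
    true_sign = edges$sign,
    z = z,
    j11 = j11,
    j00 = j00,
    n_samples = nrow(tab),
    stringsAsFactors = FALSE
  )
}

#' Prediction-quality summary of an edge score set
#'
#' Condenses an [run_ensemble()] result into one quality value per sign
#' class and method.  Positive links are judged by the ESABO z rule and
#' by `j11`; negative links by the z rule (reversed) and by `j00`.
#' Undefined scores are dropped from the denominators and counted.
#'
#' @param scores an `edge_score_set` from [run_ensemble()].
#' @return Data frame with columns `class`, `method`, `quality`,
#'   `n_scored`, `n_undefined`.
#' @export
quality_report <- function(scores) {
  stopifnot(inherits(scores, "edge_score_set"))
  out <- list()
  for (cls in c("positive", "negative")) {
    sgn <- if (cls == "positive") 1L else -1L
    sub <- scores[scores$true_sign == sgn, , drop = FALSE]
    if (nrow(sub) == 0L) next
    jv <- if (cls == "positive") sub$j11 else sub$j00
    zok <- !is.na(sub$z)
    jok <- !is.na(jv)
    out[[length(out) + 1L]] <- data.frame(
      class = cls,
      method = c("esabo_z", "jaccard"),
      quality = c(
        if (any(zok)) prediction_quality_z(sub$z[zok], cls) else NA_real_,
        if (any(jok)) prediction_quality_jaccard(jv[jok], cls) else NA_real_
      ),
      n_scored = c(sum(zok), sum(jok)),
      n_undefined = c(sum(!zok), sum(!jok)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quality sweeps over connectivity or noise
#'
#' Runs [run_ensemble()] at each value of the swept parameter and returns
#' the tidy quality table: for a `"connectivity"` sweep the values are
#' edge counts applied as `m_pos = m_neg = value`; for a `"noise"` sweep
#' they are substitution probabilities at fixed connectivity.
#'
#' @param parameter `"connectivity"` or `"noise"`.
#' @param values numeric vector of swept values.
#' @param n_networks,n_nodes,m_pos,m_neg,n_initial,n_shuffles,min_attractors
#'   base configuration passed to [run_ensemble()] (`m_pos`/`m_neg` are
#'   ignored in a connectivity sweep).
#' @param seed optional integer seed (one child seed per sweep value).
#' @return Data frame with columns `parameter`, `value`, `class`,
#'   `method`, `quality`, `n_scored`, `n_undefined`.
#' @export
sweep_quality <- function(parameter = c("connectivity", "noise"), values,
                          n_networks = 20L, n_nodes = 15L,
                          m_pos = 10L, m_neg = 10L,
                          n_initial = 500L, n_shuffles = 200L,
                          min_attractors = 100L, seed = NULL) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("no sweep values given", call. = FALSE)
  if (parameter == "connectivity" && any(values < n_nodes - 1L)) {
    stop(sprintf(
      "connectivity values below n_nodes - 1 = %d give disconnected graphs",
      n_nodes - 1L
    ), call. = FALSE)
  }
  if (parameter == "noise" && any(values < 0 | values > 1)) {
    stop("noise values must lie in [0, 1]", call. = FALSE)
  }
  seeds <- with_seed(seed, child_seeds(length(values)))
  out <- list()
  for (v in seq_along(values)) {
    es <- if (parameter == "connectivity") {
      run_ensemble(n_networks, n_nodes, values[v], values[v],
                   n_initial = n_initial, n_shuffles = n_shuffles,
                   min_attractors = min_attractors, seed = seeds[v])
    } else {
      run_ensemble(n_networks, n_nodes, m_pos, m_neg,
                   n_initial = n_initial, n_shuffles = n_shuffles,
                   noise_level = values[v],
                   min_attractors = min_attractors, seed = seeds[v])
    }
    q <- quality_report(es)
    q <- cbind(parameter = parameter, value = values[v], q)
    out[[v]] <- q
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of synergistic links misclassified as strongly negative
#'
#' Network context occasionally drives the ESABO z-score of a true
#' synergistic edge far into the negative range ("outliers").  This
#' routine pools all positive edges over an ensemble of random networks
#' and reports the fraction with `z <= threshold`.
#'
#' @param n_networks number of networks (default 40).
#' @param n_nodes nodes per network (default 15).
#' @param m positive-edge and negative-edge count (`m_pos = m_neg = m`,
#'   default 15).
#' @param runs_per_network random initial conditions per network
#'   (default 500).
#' @param n_shuffles permutations per score (default 200).
#' @param threshold outlier cutoff on z (default -1).
#' @param seed optional integer seed.
#' @param min_attractors attractor-count requirement, see
#'   [run_ensemble()].
#' @return The pooled outlier fraction, with attributes `n_positive`
#'   (defined positive-edge scores pooled) and `n_undefined`.
#' @examples
#' \donttest{
#' estimate_outlier_fraction(n_networks = 5, seed = 1)
#' }
#' @export
estimate_outlier_fraction <- function(n_networks = 40L, n_nodes = 15L,
                                      m = 15L, runs_per_network = 500L,
                                      n_shuffles = 200L, threshold = -1,
                                      seed = NULL, min_attractors = 100L) {
  es <- run_ensemble(
    n_networks, n_nodes, m, m,
    n_initial = runs_per_network, n_shuffles = n_shuffles,
    seed = seed, min_attractors = min_attractors
  )
  pos <- es$z[es$true_sign == 1L]
  ok <- !is.na(pos)
  frac <- mean(pos[ok] <= threshold)
  structure(frac, n_positive = sum(ok), n_undefined = sum(!ok))
}
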