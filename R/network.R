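#' Signed species interaction networks
#'
#' An `interaction_network` is an undirected simple graph over `n_nodes`
#' species in which every edge carries a sign: `+1` for a synergistic
#' (mutualistic) interaction and `-1` for a competitive one.  It is stored
#' as a symmetric generalized adjacency matrix `G` with entries in
#' `{-1, 0, +1}` and a zero diagonal.
#'
#' @param adjacency symmetric numeric matrix with entries in `{-1, 0, 1}`
#'   and zero diagonal; row/column names become node labels (defaults to
#'   `LETTERS`-style labels when absent).
#' @return An object of class `interaction_network`: a list with elements
#'   `adjacency` (integer matrix), `n_nodes`, and `labels`.
#' @examples
#' G <- matrix(0, 3, 3)
#' G[1, 2] <- G[2, 1] <- 1
#' G[2, 3] <- G[3, 2] <- -1
#' net <- interaction_network(G)
#' edge_count(net)
#' @seealso [generate_random_signed_network()], [network_from_edges()]
#' @export
interaction_network <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (!all(adjacency %in% c(-1, 0, 1))) {
    stop("adjacency entries must be in {-1, 0, +1}", call. = FALSE)
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("self-interactions (non-zero diagonal) are not allowed", call. = FALSE)
  }
  n <- nrow(adjacency)
  labels <- rownames(adjacency)
  if (is.null(labels)) labels <- default_labels(n)
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  structure(
    list(adjacency = adjacency, n_nodes = n, labels = labels),
    class = "interaction_network"
  )
}

default_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else paste0("sp", seq_len(n))
}

#' @export
print.interaction_network <- function(x, ...) {
  e <- network_edges(x)
  cat(sprintf(
    "interaction_network: %d nodes, %d positive / %d negative edges\n",
    x$n_nodes, sum(e$sign == 1), sum(e$sign == -1)
  ))
  invisible(x)
}

#' Build a network from a signed edge list
#'
#' @param edges data frame (or matrix) with columns `from`, `to`, `sign`;
#'   `from`/`to` are node labels, `sign` is `+1` or `-1`.
#' @param labels character vector of all node labels (fixes the node set
#'   and ordering; defaults to the sorted labels appearing in `edges`).
#' @return An [interaction_network()].
#' @examples
#' net <- network_from_edges(
#'   data.frame(from = c("A", "B"), to = c("B", "C"), sign = c(1, -1))
#' )
#' @export
network_from_edges <- function(edges, labels = NULL) {
  edges <- as.data.frame(edges)
  need <- c("from", "to", "sign")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns 'from', 'to', 'sign'", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(labels)) labels <- sort(unique(c(edges$from, edges$to)))
  if (!all(c(edges$from, edges$to) %in% labels)) {
    stop("edge endpoints must be contained in 'labels'", call. = FALSE)
  }
  if (!all(edges$sign %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  n <- length(labels)
  G <- matrix(0L, n, n, dimnames = list(labels, labels))
  i <- match(edges$from, labels)
  j <- match(edges$to, labels)
  if (any(i == j)) stop("self-loops are not allowed", call. = FALSE)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) stop("duplicate edges in edge list", call. = FALSE)
  G[cbind(i, j)] <- as.integer(edges$sign)
  G[cbind(j, i)] <- as.integer(edges$sign)
  interaction_network(G)
}

#' Edge list of an interaction network
#'
#' @param network an [interaction_network()].
#' @return Data frame with columns `from`, `to`, `sign`, one row per
#'   undirected edge (`from` precedes `to` in node order).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  G <- network$adjacency
  idx <- which(upper.tri(G) & G != 0, arr.ind = TRUE)
  data.frame(
    from = network$labels[idx[, 1]],
    to = network$labels[idx[, 2]],
    sign = G[idx],
    stringsAsFactors = FALSE
  )
}

#' Number of edges by sign
#'
#' @param network an [interaction_network()].
#' @return Named integer vector with elements `positive`, `negative`, `total`.
#' @export
edge_count <- function(network) {
  e <- network_edges(network)
  c(
    positive = sum(e$sign == 1L),
    negative = sum(e$sign == -1L),
    total = nrow(e)
  )
}

#' Non-edges (absent interactions) of a network
#'
#' @param network an [interaction_network()].
#' @return Data frame with columns `from`, `to` listing all unordered node
#'   pairs that carry no edge of either sign.
#' @export
network_non_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  G <- network$adjacency
  idx <- which(upper.tri(G) & G == 0, arr.ind = TRUE)
  data.frame(
    from = network$labels[idx[, 1]],
    to = network$labels[idx[, 2]],
    stringsAsFactors = FALSE
  )
}

network_is_connected <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(
    abs(network$adjacency),
    mode = "undirected", diag = FALSE
  )
  igraph::is_connected(g)
}

#' Generate a random connected signed interaction network
#'
#' Draws a simple undirected graph on `n_nodes` nodes with exactly
#' `n_positive + n_negative` edges, uniformly over edge sets conditioned on
#' the graph (ignoring signs) being connected, by rejection sampling.
#' Signs are then assigned by a uniformly random partition of the accepted
#' edge set into `n_positive` synergistic and `n_negative` competitive
#' interactions.
#'
#' @param n_nodes number of species (nodes).
#' @param n_positive number of synergistic (`+1`) edges.
#' @param n_negative number of competitive (`-1`) edges.
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @param max_tries rejection-sampling cap on connectivity retries.
#' @return A connected [interaction_network()].
#' @examples
#' net <- generate_random_signed_network(15, 10, 10, seed = 1)
#' edge_count(net)
#' @export
generate_random_signed_network <- function(n_nodes, n_positive, n_negative,
                                           seed = NULL, max_tries = 10000L) {
  n_nodes <- as.integer(n_nodes)
  m <- as.integer(n_positive) + as.integer(n_negative)
  if (n_nodes < 2L) stop("n_nodes must be at least 2", call. = FALSE)
  if (n_positive < 0L || n_negative < 0L) {
    stop("edge counts must be non-negative", call. = FALSE)
  }
  max_edges <- n_nodes * (n_nodes - 1L) / 2L
  if (m > max_edges) {
    stop(sprintf(
      "requested %d edges but a simple graph on %d nodes holds at most %d",
      m, n_nodes, max_edges
    ), call. = FALSE)
  }
  if (m < n_nodes - 1L) {
    stop(sprintf(
      "connectivity requires at least %d edges on %d nodes (got %d)",
      n_nodes - 1L, n_nodes, m
    ), call. = FALSE)
  }
  with_seed(seed, {
    all_pairs <- which(upper.tri(diag(n_nodes)))
    for (try in seq_len(max_tries)) {
      chosen <- all_pairs[sample.int(length(all_pairs), m)]
      G <- matrix(0L, n_nodes, n_nodes)
      G[chosen] <- 1L
      G <- G + t(G)
      net <- interaction_network(G)
      if (network_is_connected(net)) {
        signs <- rep(-1L, m)
        signs[sample.int(m, n_positive)] <- 1L
        G[chosen] <- signs
        G[lower.tri(G)] <- 0L
        G <- G + t(G)
        return(interaction_network(G))
      }
    }
    stop(sprintf(
      "no connected graph found in %d rejection-sampling tries", max_tries
    ), call. = FALSE)
  })
}

#' A 15-species example interaction network
#'
#' The signed network used throughout the documentation and the
#' calibration study: 15 species (labelled `A` to `O`) connected by 10
#' synergistic and 10 competitive interactions.  Its synchronous Boolean
#' dynamics exhibit on the order of 130 distinct attractors when sampled
#' from 1000 random initial compositions, making it a convenient
#' ground-truth benchmark for the ESABO inference pipeline.
#'
#' @return An [interaction_network()] with 15 nodes and 20 signed edges.
#' @examples
#' net <- example_interaction_network()
#' edge_count(net)
#' @export
example_interaction_network <- function() {
  path <- system.file("extdata", "example_network_15.tsv", package = "esabo",
                      mustWork = TRUE)
  network_from_edges(read_edge_list(path), labels = LETTERS[1:15])
}
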