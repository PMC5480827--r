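#' Read a sample-by-taxon abundance table
#'
#' Reads a delimited text file (tab- or comma-separated, auto-detected
#' from the header line) with a header row of taxon labels and a first
#' column of sample labels, validates it, and returns a numeric matrix
#' oriented rows = samples.  Files stored taxa-by-samples are handled
#' with `transpose = TRUE`.
#'
#' @param path path to a TSV/CSV file.
#' @param transpose set `TRUE` when the file stores rows = taxa.
#' @return Numeric matrix, rows = samples, columns = taxa, with unique
#'   dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_abundance_table(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("taxA", "taxB"))), f)
#' read_abundance_table(f)
#' @export
read_abundance_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("table needs a label column plus at least one data column",
         call. = FALSE)
  }
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate row labels: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(names(body))) {
    stop(sprintf("duplicate column labels: %s",
                 paste(unique(names(body)[duplicated(names(body))]),
                       collapse = ", ")),
         call. = FALSE)
  }
  for (cn in names(body)) {
    col <- body[[cn]]
    if (!is.numeric(col)) {
      stop(sprintf("non-numeric entries in column '%s'", cn), call. = FALSE)
    }
  }
  m <- as.matrix(body)
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (anyNA(m)) stop("table contains missing values", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at row '%s', column '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]),
         call. = FALSE)
  }
  if (transpose) m <- t(m)
  m
}

#' Write a sample-by-taxon table as TSV
#'
#' Tab-delimited, UTF-8, `.` decimal; first column holds the sample
#' labels under the header `sample`.  [read_abundance_table()] reads the
#' result back unchanged.
#'
#' @param table numeric matrix with dimnames (rows = samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("table must be a numeric matrix", call. = FALSE)
  }
  rn <- rownames(table)
  if (is.null(rn)) rn <- paste0("s", seq_len(nrow(table)))
  cn <- colnames(table)
  if (is.null(cn)) cn <- paste0("t", seq_len(ncol(table)))
  df <- data.frame(sample = rn, table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write signed edge lists
#'
#' Three-column tab-separated format: `from`, `to`, `sign` with sign
#' `+1`/`-1`, one row per undirected edge.
#'
#' @param path path to the edge-list TSV.
#' @return `read_edge_list`: data frame with columns `from`, `to`,
#'   `sign`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("from", "to", "sign")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns 'from', 'to', 'sign'", call. = FALSE)
  }
  if (!is.numeric(df$sign) || !all(df$sign %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  df[, need]
}

#' @rdname read_edge_list
#' @param edges data frame with columns `from`, `to`, `sign`, or an
#'   [interaction_network()] / `inferred_network` (their edge tables are
#'   written; inferred networks keep their `score` column).
#' @return `write_edge_list`: `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "interaction_network")) edges <- network_edges(edges)
  if (inherits(edges, "inferred_network")) edges <- edges$edges
  edges <- as.data.frame(edges)
  need <- c("from", "to", "sign")
  if (!all(need %in% names(edges))) {
    stop("edge list must have columns 'from', 'to', 'sign'", call. = FALSE)
  }
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signed network to GraphML
#'
#' Writes the network with a `sign` edge attribute (and `score`, for
#' inferred networks) via igraph, for use in external graph viewers.
#'
#' @param network an [interaction_network()] or `inferred_network`.
#' @param path output path (`.graphml`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  if (inherits(network, "interaction_network")) {
    edges <- network_edges(network)
    nodes <- network$labels
  } else if (inherits(network, "inferred_network")) {
    edges <- network$edges
    nodes <- network$nodes
  } else {
    stop("network must be an interaction_network or inferred_network",
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Generate a synthetic abundance fixture with known ground truth
#'
#' Builds a random connected signed interaction network, samples its
#' attractors into a binary table of `n_samples` rows, optionally
#' corrupts it with binary noise, and (in `pseudo_counts` mode) maps
#' presences to heavy-tailed pseudo-counts so the table resembles a real
#' census matrix: each taxon gets a characteristic magnitude drawn
#' log-uniformly between 1 and 1000 (a few high-abundance taxa, many
#' low-abundance ones), and present entries scatter around it with
#' Poisson noise, clamped to at least 1 so that binarization at
#' threshold 1 recovers the binary matrix exactly.
#'
#' Distinct attractors are collected from batches of random initial
#' conditions; if the dynamics cannot supply `n_samples` distinct
#' attractors the remaining rows are filled by basin-weighted sampling
#' (duplicate attractors retained), so the requested table size is always
#' delivered.
#'
#' @param n_samples rows of the output table.
#' @param n_taxa,m_pos,m_neg parameters of the generating network.
#' @param noise_level binary substitution noise (default 0).
#' @param abundance_mapping `"binary"` (0/1 table) or `"pseudo_counts"`.
#' @param seed optional integer seed.
#' @param magnitude_range pseudo-count magnitude range (default
#'   `c(1, 1000)`).
#' @return List with `abundances` (numeric matrix, rows = samples),
#'   `binary` (the underlying binary table), `network` (the ground-truth
#'   [interaction_network()]), and `basin_filled` (rows supplied by the
#'   basin-weighted fallback).
#' @examples
#' fx <- generate_fixture(50, 12, 8, 8, seed = 1)
#' identical(binarize_table(fx$abundances), fx$binary)
#' @export
generate_fixture <- function(n_samples, n_taxa, m_pos, m_neg,
                             noise_level = 0,
                             abundance_mapping = c("binary",
                                                   "pseudo_counts"),
                             seed = NULL,
                             magnitude_range = c(1, 1000)) {
  abundance_mapping <- match.arg(abundance_mapping)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be at least 1", call. = FALSE)
  with_seed(seed, {
    net <- generate_random_signed_network(n_taxa, m_pos, m_neg)
    # grow a distinct-attractor pool in batches
    batch <- max(1000L, 4L * n_samples)
    tab <- sample_attractor_table(net, batch, weighting = "distinct")
    if (nrow(tab) < n_samples) {
      tab2 <- sample_attractor_table(net, 4L * batch,
                                     weighting = "distinct")
      if (nrow(tab2) > nrow(tab)) tab <- tab2
    }
    basin_filled <- 0L
    if (nrow(tab) >= n_samples) {
      tab <- tab[seq_len(n_samples), , drop = FALSE]
    } else {
      extra <- sample_attractor_table(net, n_samples - nrow(tab),
                                      weighting = "basin_weighted")
      basin_filled <- nrow(extra)
      tab <- rbind(tab, extra)
    }
    rownames(tab) <- paste0("s", seq_len(nrow(tab)))
    if (noise_level > 0) tab <- add_binary_noise(tab, noise_level)
    abundances <- tab
    if (abundance_mapping == "pseudo_counts") {
      lo <- log(magnitude_range[1L])
      hi <- log(magnitude_range[2L])
      magnitude <- exp(runif(n_taxa, lo, hi))
      counts <- tab
      for (i in seq_len(n_taxa)) {
        pres <- tab[, i] == 1L
        counts[pres, i] <- pmax(1L, rpois(sum(pres), magnitude[i]))
      }
      abundances <- counts
    }
    storage.mode(abundances) <- if (abundance_mapping == "binary")
      "integer" else "double"
    list(
      abundances = abundances,
      binary = tab,
      network = net,
      basin_filled = basin_filled
    )
  })
}
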