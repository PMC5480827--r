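#' Synchronous threshold update of a binary community state
#'
#' One step of the signed-threshold Boolean dynamics.  Every species `i`
#' receives the weighted input `sum_j G_ij s_j` from the *current* state
#' (all species update simultaneously); it becomes present if the input is
#' positive, absent if negative, and keeps its state when the input is
#' exactly zero.
#'
#' @param network an [interaction_network()].
#' @param state binary vector of length `n_nodes` (1 = present).
#' @return The successor state, a binary integer vector of the same length.
#' @examples
#' net <- network_from_edges(data.frame(from = "A", to = "B", sign = 1))
#' update_state(net, c(1, 0)) # activation spreads: (1, 1)
#' @export
update_state <- function(network, state) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(state) != network$n_nodes) {
    stop("state length does not match the number of nodes", call. = FALSE)
  }
  if (!is_binary_vector(state)) {
    stop("state entries must be 0 or 1", call. = FALSE)
  }
  .update(network$adjacency, as.integer(state))
}

# core update on the raw adjacency matrix (no class checks)
.update <- function(G, s) {
  inp <- as.vector(G %*% s)
  out <- s
  out[inp > 0] <- 1L
  out[inp < 0] <- 0L
  out
}

#' Iterate the dynamics to an attractor
#'
#' Repeatedly applies [update_state()] until a previously visited state
#' recurs, then reports the attractor: a fixed point (`cycle_length` 1) or
#' a cycle.  Because the state space is finite the dynamics always reaches
#' an attractor within `2^n_nodes` steps.  The reported `representative`
#' is the lexicographically smallest state on the cycle, which makes
#' deduplication of attractors deterministic.
#'
#' @param network an [interaction_network()].
#' @param initial binary initial state.
#' @param max_steps cap on update steps; the default `2^n_nodes + 1`
#'   guarantees termination for up to 20 nodes, beyond which a cap must be
#'   supplied explicitly.
#' @return A list of class `attractor_record` with elements `kind`
#'   (`"fixed_point"` or `"cycle"`), `representative` (binary vector),
#'   `cycle_length`, and `transient_length` (steps before entering the
#'   cycle).
#' @examples
#' net <- network_from_edges(data.frame(from = "A", to = "B", sign = -1))
#' run_to_attractor(net, c(1, 1)) # mutual exclusion collapses to (0, 0)
#' @export
run_to_attractor <- function(network, initial, max_steps = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  n <- network$n_nodes
  if (is.null(max_steps)) {
    if (n > 20L) {
      stop("supply max_steps explicitly for networks with more than 20 nodes",
           call. = FALSE)
    }
    max_steps <- 2L^n + 1L
  }
  if (max_steps < 1L) stop("max_steps must be at least 1", call. = FALSE)
  if (length(initial) != n) {
    stop("initial state length does not match the number of nodes",
         call. = FALSE)
  }
  if (!is_binary_vector(initial)) {
    stop("initial state entries must be 0 or 1", call. = FALSE)
  }
  G <- network$adjacency
  s <- as.integer(initial)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  traj <- vector("list", 64L)
  step <- 0L
  repeat {
    key <- state_key(s)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      cycle_states <- traj[seq(prev, step)]
      keys <- vapply(cycle_states, state_key, character(1))
      rep_state <- cycle_states[[which.min(keys)]]
      len <- step - prev + 1L
      return(structure(
        list(
          kind = if (len == 1L) "fixed_point" else "cycle",
          representative = setNames(rep_state, network$labels),
          cycle_length = len,
          transient_length = prev - 1L
        ),
        class = "attractor_record"
      ))
    }
    step <- step + 1L
    if (step > max_steps) {
      stop(sprintf("no attractor found within max_steps = %d", max_steps),
           call. = FALSE)
    }
    if (step > length(traj)) traj <- c(traj, vector("list", length(traj)))
    seen[[key]] <- step
    traj[[step]] <- s
    s <- .update(G, s)
  }
}

#' @export
print.attractor_record <- function(x, ...) {
  cat(sprintf(
    "attractor_record: %s (cycle length %d, transient %d)\n  state: %s\n",
    x$kind, x$cycle_length, x$transient_length, state_key(x$representative)
  ))
  invisible(x)
}

#' Exhaustive attractor enumeration
#'
#' Enumerates all `2^n_nodes` states, builds the successor map of the
#' synchronous dynamics in one vectorized pass, and extracts every
#' attractor (the cycles of the functional successor graph) together with
#' exact basin sizes.  Feasible up to about 18 nodes.
#'
#' @param network an [interaction_network()] with at most `max_nodes` nodes.
#' @param max_nodes safety cap on the enumeration size (default 18).
#' @return Data frame with one row per attractor: columns `kind`,
#'   `cycle_length`, `basin_size` (number of initial states converging to
#'   it), `representative` (key string of the lexicographically smallest
#'   cycle state), plus a `states` attribute holding the representative
#'   states as a binary matrix.
#' @examples
#' net <- network_from_edges(data.frame(from = "A", to = "B", sign = 1))
#' enumerate_attractors(net)
#' @export
enumerate_attractors <- function(network, max_nodes = 18L) {
  stopifnot(inherits(network, "interaction_network"))
  n <- network$n_nodes
  if (n > max_nodes) {
    stop(sprintf("exhaustive enumeration limited to %d nodes", max_nodes),
         call. = FALSE)
  }
  n_states <- 2L^n
  # all states as rows, state index = 1 + sum_i s_i 2^(i-1)
  S <- matrix(0L, n_states, n)
  for (i in seq_len(n)) {
    S[, i] <- rep(rep(c(0L, 1L), each = 2L^(i - 1L)), length.out = n_states)
  }
  inp <- S %*% network$adjacency
  S2 <- S
  S2[inp > 0] <- 1L
  S2[inp < 0] <- 0L
  pow <- 2L^(seq_len(n) - 1L)
  succ <- as.integer(S2 %*% pow) + 1L
  # iterate succ to its 2^n-fold composition: every state lands on its cycle
  land <- succ
  for (k in seq_len(n)) land <- land[land]
  cycle_idx <- sort(unique(land))
  # group cycle states into attractors by walking each cycle once
  attr_id <- integer(n_states)
  reps <- list()
  kinds <- character()
  lens <- integer()
  for (i in cycle_idx) {
    if (attr_id[i] != 0L) next
    cyc <- i
    j <- succ[i]
    while (j != i) {
      cyc <- c(cyc, j)
      j <- succ[j]
    }
    keys <- vapply(cyc, function(ix) state_key(S[ix, ]), character(1))
    id <- length(reps) + 1L
    reps[[id]] <- S[cyc[which.min(keys)], ]
    kinds[id] <- if (length(cyc) == 1L) "fixed_point" else "cycle"
    lens[id] <- length(cyc)
    attr_id[cyc] <- id
  }
  basin <- tabulate(attr_id[land], nbins = length(reps))
  rep_mat <- do.call(rbind, reps)
  colnames(rep_mat) <- network$labels
  out <- data.frame(
    kind = kinds,
    cycle_length = lens,
    basin_size = basin,
    representative = vapply(reps, state_key, character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "states") <- rep_mat
  out
}

#' Sample an attractor table from random initial compositions
#'
#' Draws `n_initial` initial states with species-wise i.i.d. equiprobable
#' presence/absence, runs each to its attractor, and assembles the binary
#' sample-by-species table used as synthetic abundance data.  In
#' `"distinct"` mode (the default) the table holds one row per distinct
#' attractor observed, so every steady state enters the analysis with
#' equal weight regardless of its basin size; in `"basin_weighted"` mode
#' one row is kept per initial condition, so large-basin attractors appear
#' proportionally more often.
#'
#' @param network an [interaction_network()].
#' @param n_initial number of random initial conditions.
#' @param seed optional integer seed.
#' @param weighting `"distinct"` or `"basin_weighted"`.
#' @param max_steps passed to the attractor runs (same default as
#'   [run_to_attractor()]).
#' @return Binary matrix (rows = samples, columns = species labels).
#'   Rows are named `s1, s2, ...`; in distinct mode rows are ordered by
#'   first observation.
#' @examples
#' net <- example_interaction_network()
#' A <- sample_attractor_table(net, 200, seed = 1)
#' dim(A)
#' @export
sample_attractor_table <- function(network, n_initial, seed = NULL,
                                   weighting = c("distinct", "basin_weighted"),
                                   max_steps = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  weighting <- match.arg(weighting)
  n_initial <- as.integer(n_initial)
  if (n_initial < 1L) stop("n_initial must be at least 1", call. = FALSE)
  n <- network$n_nodes
  if (is.null(max_steps)) {
    if (n > 20L) {
      stop("supply max_steps explicitly for networks with more than 20 nodes",
           call. = FALSE)
    }
    max_steps <- 2L^n + 1L
  }
  G <- network$adjacency
  inits <- with_seed(seed, {
    matrix(rbinom(n_initial * n, 1L, 0.5), nrow = n_initial, ncol = n)
  })
  # memoize state -> attractor representative across runs: trajectories
  # that merge are resolved without re-simulation
  rep_of <- new.env(hash = TRUE, parent = emptyenv())
  rep_states <- new.env(hash = TRUE, parent = emptyenv())
  rep_keys <- character(n_initial)
  for (r in seq_len(n_initial)) {
    s <- as.integer(inits[r, ])
    traj_keys <- character(0)
    pos <- new.env(hash = TRUE, parent = emptyenv())
    rep_key <- NULL
    step <- 0L
    repeat {
      key <- state_key(s)
      known <- rep_of[[key]]
      if (!is.null(known)) {
        rep_key <- known
        break
      }
      prev <- pos[[key]]
      if (!is.null(prev)) {
        cyc <- traj_keys[seq(prev, step)]
        rep_key <- min(cyc)
        if (is.null(rep_states[[rep_key]])) {
          # reconstruct the representative state from its key
          rep_states[[rep_key]] <-
            as.integer(strsplit(rep_key, "", fixed = TRUE)[[1]])
        }
        break
      }
      step <- step + 1L
      if (step > max_steps) {
        stop(sprintf("no attractor found within max_steps = %d", max_steps),
             call. = FALSE)
      }
      pos[[key]] <- step
      traj_keys[step] <- key
      s <- .update(G, s)
    }
    for (k in traj_keys) rep_of[[k]] <- rep_key
    rep_keys[r] <- rep_key
  }
  keep <- if (weighting == "distinct") !duplicated(rep_keys) else
    rep(TRUE, n_initial)
  rows <- lapply(rep_keys[keep], function(k) rep_states[[k]])
  A <- do.call(rbind, rows)
  dimnames(A) <- list(paste0("s", seq_len(nrow(A))), network$labels)
  A
}

#' Substitute binary entries with random values
#'
#' Models detection noise in presence/absence data: each entry of the
#' table is independently selected with probability `noise_level` and, if
#' selected, *substituted* by a fresh uniform draw from `{0, 1}`.  Since
#' half of the substitutions reproduce the original value, the expected
#' fraction of flipped entries is `noise_level / 2`.
#'
#' @param table binary matrix (rows = samples, columns = species).
#' @param noise_level substitution probability `p` in `[0, 1]`.
#' @param seed optional integer seed.
#' @return Binary matrix of the same shape and dimnames.
#' @examples
#' A <- matrix(rbinom(50, 1, 0.5), 10, 5)
#' B <- add_binary_noise(A, 0.2, seed = 1)
#' mean(A != B) # about 0.1
#' @export
add_binary_noise <- function(table, noise_level, seed = NULL) {
  assert_binary_matrix(table)
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      is.na(noise_level) || noise_level < 0 || noise_level > 1) {
    stop("noise_level must be a single value in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    out <- table
    hit <- runif(length(out)) < noise_level
    out[hit] <- rbinom(sum(hit), 1L, 0.5)
    storage.mode(out) <- "integer"
    out
  })
}
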