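# Shared fixtures: tiny networks and an independent brute-force oracle
# for the AND permutation null.

two_node_net <- function(sign) {
  network_from_edges(data.frame(from = "A", to = "B", sign = sign))
}

empty_net <- function(n) {
  interaction_network(matrix(0L, n, n))
}

# Brute-force permutation null for the AND entropy: enumerate every
# placement of the ones of b_j (all permutations collapse onto placements
# of the ones), weight by multiplicity (equal for all placements), and
# return mean/sd of the entropy and the z of the observed entropy.
# Independent of the package's hypergeometric route.
brute_force_and_null <- function(b_i, b_j) {
  n <- length(b_i)
  k2 <- sum(b_j)
  placements <- utils::combn(n, k2)
  h <- apply(placements, 2, function(pos) {
    bj <- integer(n)
    bj[pos] <- 1L
    binary_entropy(as.integer(b_i & bj))
  })
  obs <- binary_entropy(as.integer(b_i & b_j))
  m <- mean(h)
  s <- sqrt(mean((h - m)^2)) # population sd: every placement equally likely
  list(mean = m, sd = s, z = if (s > 0) (obs - m) / s else NA_real_)
}

# All binary states of length n, one per row.
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}
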