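test_that("synchronous update follows the signed-threshold rule", {
  # no edges: zero input everywhere, state is preserved
  net <- empty_net(3)
  s <- c(1, 0, 1)
  expect_identical(update_state(net, s), as.integer(s))

  # one positive edge: activation spreads and (1,1) is fixed
  pos <- two_node_net(1)
  expect_identical(update_state(pos, c(1, 0)), c(1L, 1L))
  expect_identical(update_state(pos, c(1, 1)), c(1L, 1L))

  # one negative edge: mutual presence annihilates, (0,0) is fixed
  neg <- two_node_net(-1)
  expect_identical(update_state(neg, c(1, 1)), c(0L, 0L))
  expect_identical(update_state(neg, c(0, 0)), c(0L, 0L))

  expect_error(update_state(pos, c(1, 0, 1)), "length")
  expect_error(update_state(pos, c(1, 2)), "0 or 1")
})

test_that("update is a pure function: repeated trajectories are identical", {
  net <- generate_random_signed_network(10, 8, 8, seed = 5)
  s <- rep(c(1L, 0L), 5)
  t1 <- Reduce(function(x, .) update_state(net, x), 1:6, accumulate = TRUE,
               init = s)
  t2 <- Reduce(function(x, .) update_state(net, x), 1:6, accumulate = TRUE,
               init = s)
  expect_identical(t1, t2)
})

test_that("run_to_attractor finds fixed points and cycles with canonical representatives", {
  net <- empty_net(3)
  rec <- run_to_attractor(net, c(1, 0, 1))
  expect_identical(rec$kind, "fixed_point")
  expect_identical(rec$cycle_length, 1L)
  expect_identical(unname(rec$representative), c(1L, 0L, 1L))

  pos <- two_node_net(1)
  rec <- run_to_attractor(pos, c(0, 1))
  expect_identical(rec$kind, "fixed_point")
  expect_identical(unname(rec$representative), c(1L, 1L))

  # fixed-point representatives are invariant under one update
  net <- generate_random_signed_network(8, 6, 6, seed = 11)
  for (r in 1:20) {
    s <- rbinom(8, 1, 0.5)
    rec <- run_to_attractor(net, s)
    if (rec$kind == "fixed_point") {
      expect_identical(update_state(net, rec$representative),
                       unname(rec$representative))
    } else {
      # the representative is the lexicographic minimum of its own cycle
      cyc <- list(st <- unname(rec$representative))
      for (k in seq_len(rec$cycle_length - 1L)) {
        st <- update_state(net, st)
        cyc <- c(cyc, list(st))
      }
      keys <- vapply(cyc, paste, character(1), collapse = "")
      expect_identical(keys[1], min(keys))
      # and the cycle closes
      expect_identical(update_state(net, cyc[[rec$cycle_length]]),
                       unname(rec$representative))
    }
  }

  expect_error(run_to_attractor(two_node_net(1), c(0, 1), max_steps = 0),
               "max_steps")
})

test_that("dynamics terminate from every initial state (exhaustive, small n)", {
  set.seed(20)
  for (n in c(4, 6)) {
    net <- generate_random_signed_network(n, n - 1, 2)
    states <- all_states(n)
    for (r in seq_len(nrow(states))) {
      rec <- run_to_attractor(net, states[r, ])
      expect_lte(rec$transient_length + rec$cycle_length, 2^n)
    }
  }
})

test_that("exhaustive enumeration agrees with per-state attractor runs", {
  set.seed(31)
  for (trial in 1:3) {
    n <- 8
    net <- generate_random_signed_network(n, 7, 5)
    ea <- enumerate_attractors(net)
    states <- all_states(n)
    reps <- vapply(seq_len(nrow(states)), function(r) {
      paste(run_to_attractor(net, states[r, ])$representative, collapse = "")
    }, character(1))
    # same attractor set ...
    expect_setequal(unique(reps), ea$representative)
    # ... and identical basin sizes
    expect_identical(
      as.integer(table(reps)[ea$representative]),
      ea$basin_size
    )
    expect_identical(sum(ea$basin_size), as.integer(2^n))
  }
})

test_that("sampled distinct attractors are a subset of the exhaustive set and saturate", {
  net <- generate_random_signed_network(9, 8, 4, seed = 17)
  ea <- enumerate_attractors(net)
  tab <- sample_attractor_table(net, 3000, seed = 1)
  keys <- apply(tab, 1, paste, collapse = "")
  expect_true(all(keys %in% ea$representative))
  expect_false(anyDuplicated(keys) > 0)
  # 3000 draws over 512 states reach every attractor with basin >= 6
  big <- ea$representative[ea$basin_size >= 6]
  expect_true(all(big %in% keys))
})

test_that("basin-weighted sampling keeps duplicates and matches distinct support", {
  net <- generate_random_signed_network(8, 6, 4, seed = 23)
  bw <- sample_attractor_table(net, 400, seed = 9,
                               weighting = "basin_weighted")
  di <- sample_attractor_table(net, 400, seed = 9, weighting = "distinct")
  expect_identical(nrow(bw), 400L)
  k_bw <- unique(apply(bw, 1, paste, collapse = ""))
  k_di <- apply(di, 1, paste, collapse = "")
  expect_setequal(k_bw, k_di)
})

test_that("attractor count declines as connectivity grows", {
  set.seed(41)
  mean_na <- sapply(c(5, 10, 15), function(m) {
    mean(sapply(1:6, function(i) {
      net <- generate_random_signed_network(10, m, m)
      nrow(enumerate_attractors(net))
    }))
  })
  expect_gt(mean_na[1], mean_na[2])
  expect_gt(mean_na[2], mean_na[3])
})

test_that("binary noise substitutes, not flips", {
  A <- matrix(rbinom(4000, 1, 0.5), 100, 40,
              dimnames = list(paste0("s", 1:100), paste0("t", 1:40)))
  expect_identical(add_binary_noise(A, 0, seed = 1), A)

  # p = 1: every entry redrawn uniformly; about half differ
  B <- add_binary_noise(A, 1, seed = 2)
  expect_true(abs(mean(A != B) - 0.5) < 0.05)

  # p = 0.2: flipped fraction concentrates near p/2
  C <- add_binary_noise(A, 0.2, seed = 3)
  expect_true(abs(mean(A != C) - 0.1) < 0.02)
  expect_identical(dimnames(C), dimnames(A))

  expect_error(add_binary_noise(A, 1.2), "noise_level")
  expect_error(add_binary_noise(A, -0.1), "noise_level")
})
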