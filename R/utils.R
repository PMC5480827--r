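# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream; seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draw k child seeds from the current stream (all < 2^31).
child_seeds <- function(k) {
  sample.int(.Machine$integer.max - 1L, k)
}

is_binary_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == 0 | x == 1)
}

assert_binary_matrix <- function(m, what = "table") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(m) || !all(m == 0 | m == 1)) {
    stop(sprintf("%s must contain only 0/1 entries", what), call. = FALSE)
  }
  invisible(m)
}

state_key <- function(state) paste(state, collapse = "")
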