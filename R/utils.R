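# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so package internals never perturb user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# deterministic pseudo-random permutation of 1..n that does not touch the
# global RNG (used by the minimum-enclosing-circle routine)
lcg_permutation <- function(n, seed = 12345L) {
  if (n <= 1L) return(seq_len(n))
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  keys <- numeric(n)
  for (i in seq_len(n)) {
    state <- (16807 * state) %% 2147483647  # Park-Miller
    keys[i] <- state
  }
  order(keys)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

# largest-remainder apportionment of n into round(n * p) integer counts
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}
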