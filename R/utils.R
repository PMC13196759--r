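#' Derive a reproducible sub-seed from a top-level seed and a stream name
#'
#' All generators in the package draw their randomness from one top-level
#' seed split into named substreams, so that e.g. adding fish to one
#' population does not perturb another. The derivation is a small integer
#' hash of the stream name folded into the seed; it is stable across
#' platforms and sessions.
#'
#' @param seed Integer top-level seed.
#' @param name Character stream name (e.g. `"surface_007"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "surface_001")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (seed %% m)
  for (k in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# Seed the RNG when a seed is supplied; NULL leaves the current stream alone.
use_seed <- function(seed) {
  if (!is.null(seed)) {
    check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
               "`seed` must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Shorthand for argument validation errors.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "photokin_invalid_argument")
  invisible(TRUE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to relabeling), 0 is the expectation
#' under independent random partitions. Used to score recovery of
#' planted neuron clusters.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in `[-1, 1]` (1 = identical partitions).
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  check_that(length(a) == length(b) && length(a) > 0,
             "`a` and `b` must be non-empty and of equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1) # both partitions trivial (all-one-cluster or all-singletons)
  }
  (sum_ij - expected) / (max_index - expected)
}
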