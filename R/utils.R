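# internal helpers shared across modules

bp_msg <- function(...) {
  if (isTRUE(getOption("blockprs.verbose", TRUE))) message(sprintf(...))
}

#' Derive a reproducible child seed
#'
#' Maps a (global seed, index) pair to a deterministic 32-bit seed. Used to
#' give every block its own RNG stream so that Step-1 fits are identical
#' whether blocks run sequentially or across workers.
#'
#' @param seed integer global seed.
#' @param index non-negative integer stream index (e.g. block number).
#' @return a single integer in `[1, 2^31 - 19)`.
#' @export
derive_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  i <- as.numeric(index) %% 2147483647
  as.integer((s * 48271 + i * 104729 + 12345) %% 2147483629 + 1)
}

# log density of Inv-Gamma(shape a, scale b) at x
ldinvgamma <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

# log density of a zero-mean MVN with covariance S at x (small dimensions)
ldmvnorm0 <- function(x, S) {
  R <- chol(S)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) -
    0.5 * sum(backsolve(R, x, transpose = TRUE)^2)
}

# reflect a scalar into [lo, hi] (symmetric proposal on a bounded support)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  if (x > w) x <- 2 * w - x
  x + lo
}

`%||%` <- function(a, b) if (is.null(a)) b else a
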