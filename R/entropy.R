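# Signal-complexity measures: sample entropy and fuzzy entropy.

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) where B counts pairs of length-`m` templates whose
#' Chebyshev distance is within the tolerance and A counts the corresponding
#' length-`m+1` matches; self-matches are excluded and both template sets
#' range over the same indices. The tolerance is `r * sd(x)`. Larger values
#' mean a more irregular (noisier) signal.
#'
#' @param x Numeric signal, length > `m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of `sd(x)` (default 0.2).
#'
#' @return Nonnegative scalar; 0 for a constant signal (zero-variance
#'   convention); `Inf` when no length-`m+1` matches exist.
#' @export
#' @examples
#' sample_entropy(sin(seq(0, 8 * pi, length.out = 200)))
sample_entropy <- function(x, m = 2L, r = 0.2) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop_param("signal length must exceed m + 1")
  sdx <- sd(x)
  if (sdx < .Machine$double.eps) return(0)
  .sampen_cpp(x, as.integer(m), r * sdx)
}

#' Fuzzy-entropy parameters
#'
#' @param m Embedding dimension (>= 1).
#' @param n Gradient (steepness) of the fuzzy similarity boundary (> 0).
#' @param r Boundary width as a fraction of `sd(x)` (> 0).
#' @return A `fuzzyen_params` list.
#' @export
fuzzyen_params <- function(m = 2L, n = 2, r = 0.2) {
  if (m < 1) stop_param("m must be >= 1")
  if (n <= 0) stop_param("n must be positive")
  if (r <= 0) stop_param("r must be positive")
  structure(list(m = as.integer(m), n = n, r = r), class = "fuzzyen_params")
}

#' Fuzzy entropy
#'
#' Replaces sample entropy's hard match threshold with the smooth similarity
#' `exp(-d^n / r)`: the signal is standardized to unit SD, embedding vectors
#' are baseline-subtracted (each vector minus its own mean), distances are
#' Chebyshev, and `FuzzyEn = ln(phi_m) - ln(phi_m1)` where `phi` averages
#' the pairwise similarities over all ordered pairs excluding self-matches.
#' Standardizing makes the width `r` act relative to `sd(x)` for every
#' boundary gradient `n`, so the measure is invariant to amplitude scaling;
#' the baseline subtraction makes it invariant to constant offsets.
#'
#' @param x Numeric signal, length > `params$m + 2`.
#' @param params A [fuzzyen_params()].
#'
#' @return Nonnegative scalar; 0 for a constant signal.
#' @export
#' @examples
#' fuzzy_entropy(rnorm(200), fuzzyen_params(m = 2, n = 2, r = 0.2))
fuzzy_entropy <- function(x, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  x <- as.numeric(x)
  if (length(x) <= params$m + 2) stop_param("signal length must exceed m + 2")
  sdx <- sd(x)
  if (sdx < .Machine$double.eps) return(0)
  .fuzzyen_cpp(x / sdx, params$m, params$n, params$r)
}
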