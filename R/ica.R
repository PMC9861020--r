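# Fixed-point (FastICA-style) independent component analysis.
#
# Symmetric decorrelation, logcosh nonlinearity. Input rows are centered and
# whitened by eigendecomposition of the covariance; near-zero eigenvalues
# (below rank_tol * largest) are dropped, reducing the dimensionality to the
# numerical rank. Sources come out decorrelated with unit variance, and
# mixing %*% sources + row means reconstructs the input (exactly when the
# input has full rank).

#' Independent component analysis by fixed-point iteration
#'
#' @param m Numeric matrix, components in rows (>= 2 rows, not all
#'   collinear).
#' @param seed Integer seed for the random orthonormal initialization.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the rotation update (default 1e-8).
#' @param rank_tol Relative eigenvalue cutoff for rank reduction
#'   (default 1e-10).
#'
#' @return An `ic_decomposition`: `sources` (rank x samples, unit variance),
#'   `mixing` (nrow(m) x rank), `means` (row means of the input),
#'   `component_entropy` (sample entropy of each source), `rank`,
#'   `converged` (FALSE means the iteration cap was hit and the best iterate
#'   is returned, with a warning).
#' @export
#' @examples
#' s <- rbind(sin(seq(0, 20, length.out = 500)), runif(500) - 0.5)
#' x <- matrix(c(1, 0.4, 0.3, 1), 2, 2) %*% s
#' dec <- ica_decompose(x, seed = 1)
#' dec$rank
ica_decompose <- function(m, seed = 1L, max_iter = 200L, tol = 1e-8,
                          rank_tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) < 2) stop_param("need a matrix with >= 2 rows")
  if (any(!is.finite(m))) stop_param("input must be finite")
  n <- ncol(m)
  means <- rowMeans(m)
  xc <- m - means

  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * rank_tol & eg$values > 0
  rank <- sum(pos)
  if (rank < 1) stop_param("input has numerical rank 0")
  E <- eg$vectors[, pos, drop = FALSE]
  D <- eg$values[pos]
  K <- diag(1 / sqrt(D), rank) %*% t(E)       # whitening: K %*% xc is white
  Kinv <- E %*% diag(sqrt(D), rank)           # exact right-inverse of K
  z <- K %*% xc

  W <- with_seed(seed, {
    w0 <- matrix(rnorm(rank * rank), rank, rank)
    sv <- svd(w0)
    sv$u %*% t(sv$v)
  })
  converged <- FALSE
  if (rank >= 2) {
    for (it in seq_len(max_iter)) {
      wz <- W %*% z
      g <- tanh(wz)
      gp <- 1 - g^2
      W1 <- (g %*% t(z)) / n - diag(rowMeans(gp), rank) %*% W
      sv <- svd(W1)
      W1 <- sv$u %*% t(sv$v)                  # symmetric decorrelation
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("ICA did not converge in ", max_iter,
              " iterations; returning last iterate", call. = FALSE)
  } else {
    converged <- TRUE                         # rank 1: nothing to rotate
  }

  sources <- W %*% z
  mixing <- Kinv %*% t(W)
  ent <- apply(sources, 1, function(s) {
    if (sd(s) < .Machine$double.eps) 0 else sample_entropy(s)
  })
  structure(list(sources = sources, mixing = mixing, means = means,
                 component_entropy = ent, rank = rank,
                 converged = converged),
            class = "ic_decomposition")
}

#' Reconstruct the input of an ICA decomposition
#'
#' @param dec An `ic_decomposition`.
#' @param zero Indices of sources to zero out before mixing (default none).
#' @return Reconstructed matrix (same shape as the ICA input).
#' @export
ica_reconstruct <- function(dec, zero = integer(0)) {
  s <- dec$sources
  if (length(zero)) s[zero, ] <- 0
  dec$mixing %*% s + dec$means
}
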