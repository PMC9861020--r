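# Periodized discrete wavelet transform with the db4 filter bank.
#
# Orthonormal Daubechies-4 (8-tap) analysis/synthesis filters; circular
# convolution with dyadic downsampling. Odd-length inputs at any level are
# padded by repeating the last sample and trimmed after reconstruction, so
# arbitrary lengths >= the filter support are accepted (power-of-two lengths
# reconstruct exactly).

DB4_LO <- c(-0.010597401785069032, 0.032883011666885206, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.63088076792985890,
            0.71484657055291570, 0.23037781330889650)
DB4_HI <- c(-0.23037781330889650, 0.71484657055291570, -0.63088076792985890,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.032883011666885206, -0.010597401785069032)

dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  L <- length(DB4_LO)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    a[k] <- sum(DB4_LO * x[idx])
    d[k] <- sum(DB4_HI * x[idx])
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, n_out) {
  half <- length(a)
  n <- 2 * half
  L <- length(DB4_LO)
  x <- numeric(n)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    x[idx] <- x[idx] + DB4_LO * a[k] + DB4_HI * d[k]
  }
  x[seq_len(n_out)]
}

wavelet_decompose <- function(x, levels = 4L) {
  if (length(x) < 2 * length(DB4_LO))
    stop_param("signal shorter than the wavelet filter support")
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(a)
    st <- dwt_step(a)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, lens = lens)
}

wavelet_reconstruct <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], dec$lens[j])
  }
  a
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# db4 soft-threshold denoising with the fixed universal threshold.
wavelet_denoise <- function(x, levels = 4L) {
  dec <- wavelet_decompose(x, levels)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  wavelet_reconstruct(dec)
}
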