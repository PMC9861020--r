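# Welch power spectral density and relative band power.

#' EEG band definitions
#'
#' The four classical bands used for relative band power: delta 0-3 Hz,
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz. Band membership is decided on
#' PSD bin centre frequencies with inclusive edges; bins falling in the gaps
#' between bands (e.g. 3.5 Hz at sub-hertz resolution) contribute to the
#' denominator of relative band power only.
#'
#' @return Data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             f_lo = c(0, 4, 8, 14),
             f_hi = c(3, 7, 13, 30))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into `nperseg`-sample
#' windows overlapping by `overlap`, each window is mean-subtracted,
#' Hann-tapered and Fourier transformed, and the squared magnitudes are
#' averaged and scaled to a one-sided density (integral over frequency
#' approximates the signal variance).
#'
#' @param x Numeric signal (length >= `nperseg`).
#' @param fs Sampling rate, Hz.
#' @param nperseg Window length in samples (default: 1 s of data, capped at
#'   the signal length).
#' @param overlap Window overlap fraction in `[0, 1)` (default 0.5).
#'
#' @return A `psd_estimate`: `freqs` (Hz, from 0 to fs/2), `power`
#'   (microvolts^2/Hz), `params`.
#' @export
#' @examples
#' p <- welch_psd(rnorm(1024), fs = 128)
#' sum(p$power) * (p$freqs[2] - p$freqs[1])
welch_psd <- function(x, fs, nperseg = min(length(x), round(fs)),
                      overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  nperseg <- as.integer(nperseg)
  if (nperseg < 8) stop_param("nperseg must be >= 8")
  if (nperseg > n) stop_param("nperseg exceeds signal length")
  if (overlap < 0 || overlap >= 1) stop_param("overlap must be in [0, 1)")

  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)

  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nperseg))
  ff <- stats::mvfft(segs)

  nf <- nperseg %/% 2 + 1L
  pw <- if (length(starts) > 1) rowMeans(Mod(ff)^2) else Mod(ff[, 1])^2
  pw <- pw[seq_len(nf)] / (fs * sum(w^2))
  if (nperseg %% 2 == 0) {
    if (nf > 2) pw[2:(nf - 1)] <- 2 * pw[2:(nf - 1)]
  } else if (nf > 1) {
    pw[2:nf] <- 2 * pw[2:nf]
  }
  structure(list(freqs = (seq_len(nf) - 1) * fs / nperseg,
                 power = pw,
                 params = list(nperseg = nperseg, overlap = overlap,
                               window = "hann", fs = fs)),
            class = "psd_estimate")
}

#' Relative band power
#'
#' Power in one band divided by the power over the total analysis range:
#' `sum(P[f] : f_lo <= f <= f_hi) / sum(P[f] : total_lo <= f <= total_hi)`,
#' with membership decided on bin centre frequencies (inclusive edges). The
#' DC bin is excluded by default.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param band One row of [eeg_bands()] (or any list with `f_lo`, `f_hi`).
#' @param total_lo,total_hi Total analysis range in Hz (defaults 0-30, the
#'   band-limited range the denoising targets).
#' @param exclude_dc Drop the 0 Hz bin from numerator and denominator
#'   (default TRUE).
#'
#' @return Fraction in `[0, 1]`. Errors when the total power is zero.
#' @export
relative_band_power <- function(psd, band, total_lo = 0, total_hi = 30,
                                exclude_dc = TRUE) {
  stopifnot(inherits(psd, "psd_estimate"))
  f_lo <- band$f_lo; f_hi <- band$f_hi
  if (f_lo < total_lo || f_hi > total_hi)
    stop_param("band must lie within the total range")
  f <- psd$freqs
  ok <- if (exclude_dc) f > 0 else rep(TRUE, length(f))
  den_idx <- ok & f >= total_lo & f <= total_hi
  num_idx <- den_idx & f >= f_lo & f <= f_hi
  den <- sum(psd$power[den_idx])
  if (den <= 0) stop_param("total power in the analysis range is zero")
  sum(psd$power[num_idx]) / den
}
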