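# CEEMD+ICA denoising and the baseline preprocessing methods.
#
# Per channel: CEEMD splits the signal into IMFs; sample entropy identifies
# the noise-carrying (high-entropy) modes -- empirically the leading ones;
# ICA on those modes separates the noise into a small number of sources; the
# single highest-entropy source is zeroed; inverse ICA and summation with
# the untouched modes and the residual gives the denoised signal.

#' Select the noisiest IMFs by sample entropy
#'
#' Returns the indices of the `k` IMFs with the highest sample entropy (ties
#' broken toward the lowest index). Since IMF entropy typically decreases
#' with mode index, these are normally the leading modes. When fewer than
#' `k` IMFs exist, all are selected.
#'
#' @param imfset An `imf_set`.
#' @param k Number of modes to flag as noisy (default 6).
#' @param m,r Sample-entropy parameters (defaults m = 2, r = 0.2).
#' @return Integer vector of IMF indices, ordered by decreasing entropy.
#' @export
select_noisy_imfs <- function(imfset, k = 6L, m = 2L, r = 0.2) {
  stopifnot(inherits(imfset, "imf_set"))
  n_imf <- nrow(imfset$imfs)
  if (n_imf == 0) return(integer(0))
  ent <- apply(imfset$imfs, 1, function(z) {
    v <- if (sd(z) < .Machine$double.eps) 0 else sample_entropy(z, m, r)
    if (is.infinite(v)) .Machine$double.xmax else v
  })
  ord <- order(-ent, seq_len(n_imf))          # ties: lowest index first
  sort(ord[seq_len(min(k, n_imf))])
}

#' Denoise one channel with CEEMD + ICA
#'
#' Full single-channel pipeline: [ceemd()], sample entropy per IMF,
#' [select_noisy_imfs()] (top `k`), [ica_decompose()] on the selected modes
#' stacked as rows, zeroing of exactly one source (the one with the highest
#' sample entropy, ties toward the lowest index), inverse ICA, and
#' reconstruction with the untouched modes and the residual. When fewer than
#' two noisy modes are available ICA is skipped and the plain reconstruction
#' is returned with a warning.
#'
#' @param x Numeric signal.
#' @param k Number of noisy IMFs passed to ICA (default 6).
#' @param seed Integer seed (drives both the CEEMD ensemble and the ICA
#'   initialization).
#' @param n_pairs,noise_std_ratio CEEMD ensemble parameters.
#' @param details Return diagnostics alongside the signal.
#'
#' @return Denoised signal of the same length; with `details = TRUE`, a list
#'   `list(signal, n_imf, noisy, zeroed_ic, ic_entropy)`.
#' @export
denoise_channel <- function(x, k = 6L, seed = 1L, n_pairs = 50L,
                            noise_std_ratio = 0.2, details = FALSE) {
  x <- as.numeric(x)
  dec <- ceemd(x, n_pairs = n_pairs, noise_std_ratio = noise_std_ratio,
               seed = derive_seed(seed, "ceemd"))
  noisy <- select_noisy_imfs(dec, k = k)
  info <- list(n_imf = nrow(dec$imfs), noisy = noisy,
               zeroed_ic = NA_integer_, ic_entropy = numeric(0))

  if (length(noisy) < 2) {
    warning("fewer than 2 noisy IMFs; skipping ICA, signal unchanged",
            call. = FALSE)
    out <- imf_reconstruct(dec)
  } else {
    ica <- ica_decompose(dec$imfs[noisy, , drop = FALSE],
                         seed = derive_seed(seed, "ica"))
    worst <- which.max(ica$component_entropy)  # which.max: first max on ties
    cleaned <- ica_reconstruct(ica, zero = worst)
    info$zeroed_ic <- worst
    info$ic_entropy <- ica$component_entropy
    rest <- setdiff(seq_len(nrow(dec$imfs)), noisy)
    out <- colSums(cleaned) + imf_reconstruct(dec, which = rest)
  }
  if (details) c(list(signal = out), info) else out
}

#' Denoise a segment channel by channel
#'
#' Applies [denoise_channel()] independently to each channel of a segment;
#' all metadata is preserved. The same seed drives every channel, so the
#' result is equivariant under channel permutation. All-zero (flat) channels
#' are returned unchanged.
#'
#' @param seg An `eeg_segment`.
#' @param seed Integer seed.
#' @param ... Passed to [denoise_channel()].
#' @return The denoised `eeg_segment`.
#' @export
denoise_segment <- function(seg, seed = 1L, ...) {
  stopifnot(inherits(seg, "eeg_segment"))
  out <- seg
  for (ch in seq_len(nrow(seg$data))) {
    x <- seg$data[ch, ]
    if (sd(x) < .Machine$double.eps) next
    out$data[ch, ] <- denoise_channel(x, seed = seed, ...)
  }
  out
}

#' Low-pass filter baseline
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass at `cutoff`,
#' applied per channel. The traditional rough EEG cleanup: everything above
#' the cutoff is attenuated, in-band content passes without phase
#' distortion.
#'
#' @param seg An `eeg_segment`.
#' @param cutoff Cutoff frequency in Hz (< fs/2; default 30).
#' @return Filtered `eeg_segment`.
#' @export
lowpass_baseline <- function(seg, cutoff = 30) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (cutoff >= seg$fs / 2) stop_param("cutoff must be below fs/2")
  bf <- signal::butter(4, cutoff / (seg$fs / 2), type = "low")
  out <- seg
  for (ch in seq_len(nrow(seg$data))) {
    out$data[ch, ] <- filtfilt_padded(bf, seg$data[ch, ])
  }
  out
}

# Forward-backward filtering with odd-reflection edge padding, which
# suppresses the boundary transients of plain filtfilt.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  npad <- min(n - 1, 3 * 2 * (length(bf$b) - 1))
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(npad + 1):(npad + n)]
}

#' Wavelet soft-threshold baseline
#'
#' Per channel: 4-level db4 discrete wavelet transform, soft thresholding of
#' all detail coefficients with the fixed universal threshold
#' `sigma * sqrt(2 log N)` where `sigma = median(|d1|) / 0.6745` (noise SD
#' estimated from the finest detail level), inverse transform.
#'
#' @param seg An `eeg_segment`.
#' @param levels Decomposition depth (default 4).
#' @return Denoised `eeg_segment`.
#' @export
wavelet_baseline <- function(seg, levels = 4L) {
  stopifnot(inherits(seg, "eeg_segment"))
  out <- seg
  for (ch in seq_len(nrow(seg$data))) {
    out$data[ch, ] <- wavelet_denoise(seg$data[ch, ], levels = levels)
  }
  out
}

#' CEEMD discard baseline
#'
#' Conventional mode-rejection cleanup: per channel, CEEMD, drop the first
#' `k` (highest-frequency) IMFs entirely, and reconstruct from the remaining
#' modes plus the residual. Discards noise and any signal content living in
#' the leading modes alike -- the behaviour the ICA step is designed to
#' improve on.
#'
#' @param seg An `eeg_segment`.
#' @param k Number of leading IMFs to discard (default 6).
#' @param seed Integer seed for the CEEMD ensemble.
#' @param ... Passed to [ceemd()].
#' @return Denoised `eeg_segment`.
#' @export
ceemd_discard_baseline <- function(seg, k = 6L, seed = 1L, ...) {
  stopifnot(inherits(seg, "eeg_segment"))
  out <- seg
  for (ch in seq_len(nrow(seg$data))) {
    x <- seg$data[ch, ]
    if (sd(x) < .Machine$double.eps) next
    dec <- ceemd(x, seed = seed, ...)
    keep <- setdiff(seq_len(nrow(dec$imfs)), seq_len(min(k, nrow(dec$imfs))))
    out$data[ch, ] <- imf_reconstruct(dec, which = keep)
  }
  out
}

#' Apply a named preprocessing method to a segment
#'
#' Dispatcher used by the pipeline: `"ceemd-ica"` ([denoise_segment()]),
#' `"lowpass"`, `"wavelet"`, `"ceemd-discard"`, or `"none"` (identity).
#'
#' @param seg An `eeg_segment`.
#' @param method Method name.
#' @param seed Integer seed (ignored by the deterministic methods).
#' @param k,n_pairs,noise_std_ratio Parameters of the CEEMD-based methods.
#' @param cutoff Low-pass cutoff, Hz.
#' @param levels Wavelet decomposition depth.
#' @return Preprocessed `eeg_segment`.
#' @export
preprocess_segment <- function(seg,
                               method = c("ceemd-ica", "lowpass", "wavelet",
                                          "ceemd-discard", "none"),
                               seed = 1L, k = 6L, n_pairs = 50L,
                               noise_std_ratio = 0.2, cutoff = 30,
                               levels = 4L) {
  method <- match.arg(method)
  switch(method,
         "ceemd-ica" = denoise_segment(seg, seed = seed, k = k,
                                       n_pairs = n_pairs,
                                       noise_std_ratio = noise_std_ratio),
         "lowpass" = lowpass_baseline(seg, cutoff = cutoff),
         "wavelet" = wavelet_baseline(seg, levels = levels),
         "ceemd-discard" = ceemd_discard_baseline(seg, k = k, seed = seed,
                                                  n_pairs = n_pairs,
                                                  noise_std_ratio = noise_std_ratio),
         "none" = seg)
}
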