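# Per-segment feature extraction: 5 features x channels.
#
# Each channel contributes relative band power in delta, theta, alpha, beta
# (from a Welch PSD of the full-rate window) and fuzzy entropy. With the
# 19-channel montage this gives the 95-value feature vector per segment.

#' Extract the feature vector of one segment
#'
#' Per channel, in fixed order: relative band power for delta, theta, alpha
#' and beta, then fuzzy entropy. Band powers come from a Welch PSD with 1-s
#' Hann windows and 50% overlap; fuzzy entropy is computed on a decimated
#' copy of the channel (at most `entropy_samples` evenly strided samples, an
#' O(N^2) cost control -- the sub-30-Hz content the complexity measure
#' targets is fully represented at the resulting effective rate).
#'
#' @param seg An `eeg_segment`.
#' @param bands Band table, see [eeg_bands()].
#' @param fe Fuzzy-entropy parameters, see [fuzzyen_params()].
#' @param total_band Length-2 numeric: denominator range of relative band
#'   power, Hz (default `c(0, 30)`).
#' @param entropy_samples Cap on samples entering fuzzy entropy
#'   (default 512; `Inf` disables decimation).
#' @param nperseg Welch window length in samples (default 1 s).
#'
#' @return Named numeric vector of `5 * n_channels` features
#'   (`<channel>_<feature>`).
#' @export
#' @examples
#' rec <- generate_recording(default_profiles()[[1]], duration = 8,
#'                           fs = 128, n_channels = 2, seed = 1)
#' seg <- segment_recording(rec, train_duration = 4)[[1]]
#' extract_features(seg)
extract_features <- function(seg, bands = eeg_bands(), fe = fuzzyen_params(),
                             total_band = c(0, 30), entropy_samples = 512,
                             nperseg = round(seg$fs)) {
  stopifnot(inherits(seg, "eeg_segment"))
  nch <- nrow(seg$data)
  out <- numeric(0)
  for (ch in seq_len(nch)) {
    x <- seg$data[ch, ]
    psd <- welch_psd(x, seg$fs, nperseg = min(nperseg, length(x)))
    rbp <- vapply(seq_len(nrow(bands)), function(b) {
      relative_band_power(psd, bands[b, ], total_band[1], total_band[2])
    }, 0)
    xe <- x
    if (is.finite(entropy_samples) && length(x) > entropy_samples) {
      stride <- ceiling(length(x) / entropy_samples)
      xe <- x[seq(1, length(x), by = stride)]
    }
    fz <- fuzzy_entropy(xe, fe)
    out <- c(out, rbp, fz)
  }
  names(out) <- feature_names(rownames(seg$data) %||%
                                paste0("ch", seq_len(nch)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a feature table from segments
#'
#' Applies [extract_features()] to every segment and assembles the rows into
#' a feature table (one row per segment) with `subject_id`, `state_id` and
#' `role` metadata columns.
#'
#' @param segments List of `eeg_segment` objects.
#' @param ... Passed to [extract_features()].
#' @return Feature table data frame (see [validate_feature_table()]).
#' @export
features_from_segments <- function(segments, ...) {
  if (!length(segments)) stop_param("no segments supplied")
  rows <- lapply(segments, extract_features, ...)
  tab <- as.data.frame(do.call(rbind, rows))
  tab$subject_id <- vapply(segments, `[[`, "", "subject_id")
  tab$state_id <- vapply(segments, function(s) as.integer(s$state_id), 0L)
  tab$role <- vapply(segments, `[[`, "", "role")
  validate_feature_table(tab)
  tab
}
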