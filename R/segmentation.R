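# Leakage-free sliding-window segmentation.
#
# Each recording is split into train windows tiling [0, train_duration] and
# test windows tiling [train_duration, duration], both half-open [t, t+window)
# in sample units with starts at exact multiples of the step. A trailing
# remainder shorter than the window is discarded. No train window crosses the
# train/test boundary, so train and test segments never share samples.

#' Segment a recording into train/test windows
#'
#' With the defaults (4-s windows, 2-s step, 240 s of training data) a
#' 300-s recording yields 119 train and 29 test segments per recording.
#'
#' @param rec An `eeg_recording`.
#' @param window Window length in seconds.
#' @param step Step between window starts in seconds (`window >= step > 0`
#'   gives the overlapping scheme; `step == window` gives disjoint windows).
#' @param train_duration Seconds of the recording used for training windows;
#'   everything after it is test territory.
#'
#' @return List of `eeg_segment` objects, train windows first, each with
#'   `data` (channels x samples), `fs`, `subject_id`, `state_id`, `role`
#'   (`"train"`/`"test"`), `start_time` (seconds).
#' @export
#' @examples
#' rec <- generate_recording(default_profiles()[[1]], duration = 20,
#'                           fs = 128, n_channels = 2, seed = 1)
#' segs <- segment_recording(rec, window = 4, step = 2, train_duration = 12)
#' table(vapply(segs, `[[`, "", "role"))
segment_recording <- function(rec, window = 4, step = 2, train_duration = 240) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (step <= 0) stop_param("step must be positive")
  if (window < step) stop_param("window must be >= step")
  if (rec$duration < train_duration + window)
    stop_param("recording too short: need duration >= train_duration + window")

  n_train <- floor((train_duration - window) / step) + 1
  n_test <- floor((rec$duration - train_duration - window) / step) + 1
  starts <- c((seq_len(n_train) - 1) * step,
              train_duration + (seq_len(n_test) - 1) * step)
  roles <- rep(c("train", "test"), c(n_train, n_test))
  wlen <- round(window * rec$fs)

  mapply(function(st, role) {
    i0 <- round(st * rec$fs)
    structure(list(data = rec$data[, (i0 + 1):(i0 + wlen), drop = FALSE],
                   fs = rec$fs,
                   subject_id = rec$subject_id,
                   state_id = rec$state_id,
                   role = role,
                   start_time = st),
              class = "eeg_segment")
  }, starts, roles, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s state=%d %s @ %gs: %d ch x %d samples\n",
              x$subject_id, x$state_id, x$role, x$start_time,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}
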