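# Synthetic multichannel EEG generator.
#
# Emulates the statistical structure the recognition pipeline assumes: each
# fatigue state has its own relative band-power profile (delta/theta/alpha/
# beta), a 1/f background, a broadband (<30 Hz) stochastic component whose
# amplitude controls signal complexity (hence fuzzy entropy), and additive
# high-frequency (>30 Hz) artifact noise that the denoising stage targets.

#' Fatigue-state generation profile
#'
#' Bundles the parameters that shape one synthetic fatigue state: the
#' relative oscillatory power of the four classical EEG bands, the 1/f
#' background amplitude, the amplitude of the broadband sub-30-Hz component
#' (which controls complexity and therefore fuzzy entropy), and the amplitude
#' of >30 Hz artifact noise.
#'
#' @param state_id Fatigue degree, one of 0 (alert), 1, 2 (fatigued).
#' @param band_weights Named numeric vector `c(delta=, theta=, alpha=, beta=)`
#'   of nonnegative relative band powers summing to 1.
#' @param pink_noise_scale RMS amplitude of the 1/f background, in microvolts.
#' @param complexity_scale RMS amplitude of the broadband (<30 Hz) stochastic
#'   component, in microvolts. Higher values raise fuzzy entropy.
#' @param artifact_scale RMS amplitude of >30 Hz artifact noise, microvolts.
#' @param osc_rms Total RMS of the band-limited oscillations, microvolts.
#'
#' @return An object of class `state_profile`.
#' @export
state_profile <- function(state_id,
                          band_weights,
                          pink_noise_scale = 3,
                          complexity_scale = 2.5,
                          artifact_scale = 3,
                          osc_rms = 19) {
  if (!state_id %in% 0:2) stop_param("state_id must be 0, 1 or 2")
  bw <- band_weights[c("delta", "theta", "alpha", "beta")]
  if (anyNA(bw)) stop_param("band_weights needs delta, theta, alpha, beta")
  if (any(bw < 0)) stop_param("band_weights must be nonnegative")
  if (abs(sum(bw) - 1) > 1e-9) stop_param("band_weights must sum to 1")
  structure(list(state_id = as.integer(state_id),
                 band_weights = bw,
                 pink_noise_scale = pink_noise_scale,
                 complexity_scale = complexity_scale,
                 artifact_scale = artifact_scale,
                 osc_rms = osc_rms),
            class = "state_profile")
}

#' Default fatigue-state profiles
#'
#' Three profiles encoding the direction of change reported across the
#' fatigue literature: relative theta and alpha power rise with fatigue while
#' beta power and attention-linked signal complexity fall. State 0 is
#' beta-dominant with high complexity, state 2 theta/alpha-dominant with low
#' complexity, state 1 intermediate.
#'
#' @param separation Scales how far the three states sit from their common
#'   mean profile: 1 (default) gives the full, well-separated study
#'   conditions; 0 collapses all states onto one profile (classes become
#'   unlearnable). Used for parameter-recovery studies.
#'
#' @return List of three `state_profile` objects (states 0, 1, 2).
#' @export
#' @examples
#' p <- default_profiles()
#' sapply(p, function(x) x$band_weights["alpha"])
default_profiles <- function(separation = 1) {
  if (separation < 0 || separation > 1) stop_param("separation must be in [0, 1]")
  w <- rbind(c(0.15, 0.15, 0.20, 0.50),   # state 0: alert
             c(0.20, 0.25, 0.30, 0.25),   # state 1
             c(0.21, 0.31, 0.40, 0.08))   # state 2: fatigued
  colnames(w) <- c("delta", "theta", "alpha", "beta")
  centre <- colMeans(w)
  cx <- c(4, 2.5, 1)                      # complexity falls with fatigue
  cx_c <- mean(cx)
  lapply(0:2, function(s) {
    bw <- centre + separation * (w[s + 1, ] - centre)
    bw <- bw / sum(bw)
    state_profile(s, bw,
                  complexity_scale = cx_c + separation * (cx[s + 1] - cx_c))
  })
}

# Band-limited noise via FFT masking: white Gaussian noise whose spectrum is
# zeroed outside [f_lo, f_hi], rescaled to unit RMS.
band_noise <- function(n, fs, f_lo, f_hi, shape = c("flat", "pink")) {
  shape <- match.arg(shape)
  z <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # two-sided frequency magnitude
  keep <- f >= f_lo & f <= f_hi
  if (shape == "pink") {
    g <- ifelse(f > 0, 1 / sqrt(pmax(f, f_lo)), 0)
  } else {
    g <- 1
  }
  z <- z * keep * g
  x <- Re(fft(z, inverse = TRUE)) / n
  s <- sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  (x - mean(x)) / s
}

BAND_EDGES <- list(delta = c(1, 2.5), theta = c(4.5, 6.5),
                   alpha = c(8.5, 12.5), beta = c(14.5, 28))

# Oscillator traits for each channel: one centre frequency and one slow
# amplitude-modulation rate per band, drawn with a small interior margin so
# Hann-window leakage keeps each oscillator's power inside its own band.
# Kept separate from the per-recording noise draws so they can be fixed per
# subject: a subject's peak frequencies are stable traits, and recordings of
# different states must not be distinguishable by them.
draw_osc_params <- function(n_channels) {
  lapply(seq_len(n_channels), function(ch) {
    list(f0 = vapply(BAND_EDGES, function(e) runif(1, e[1], e[2]), 0),
         fm = stats::setNames(runif(4, 0.05, 0.2), names(BAND_EDGES)))
  })
}

# One channel's signal content for a profile (without common-mode mixing).
synth_channel <- function(profile, n, fs, osc) {
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  p_osc <- profile$osc_rms^2
  for (b in names(BAND_EDGES)) {
    wgt <- profile$band_weights[[b]]
    if (wgt <= 0) next
    ph <- runif(1, 0, 2 * pi)
    pm <- runif(1, 0, 2 * pi)
    amp <- sqrt(2 * p_osc * wgt)
    mod <- 1 + 0.3 * sin(2 * pi * osc$fm[[b]] * tt + pm)
    x <- x + amp * mod / sqrt(1 + 0.045) * sin(2 * pi * osc$f0[[b]] * tt + ph)
  }
  x <- x + profile$pink_noise_scale * band_noise(n, fs, 0.5, 30, "pink")
  x <- x + profile$complexity_scale * band_noise(n, fs, 0.5, 30, "flat")
  if (fs / 2 > 30 && profile$artifact_scale > 0) {
    x <- x + profile$artifact_scale * band_noise(n, fs, 30, fs / 2, "flat")
  }
  x
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes a multichannel recording for one fatigue state: per channel, a
#' sum of band-limited oscillations (one amplitude-modulated sinusoid per
#' band, centre frequency drawn inside the band edges), 1/f background,
#' broadband sub-30-Hz stochastic content scaled by the profile's
#' `complexity_scale`, and >30 Hz artifact noise scaled by `artifact_scale`.
#' Channels are drawn independently and then mixed with a shared common-mode
#' channel so that cross-channel structure exists. Deterministic given `seed`.
#'
#' @param profile A [state_profile()].
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 128).
#' @param n_channels Number of channels (>= 1).
#' @param seed Integer seed.
#' @param subject_id Subject identifier stored in the recording.
#' @param common_mode Mixing weight of the shared common-mode component,
#'   in `[0, 1)`; default 0.3.
#' @param channel_labels Channel names; defaults to the 19-channel 10-20
#'   montage (recycled/truncated for other channel counts).
#' @param osc_params Per-channel oscillator traits (centre frequency and
#'   modulation rate per band), `n_channels + 1` entries (the last drives
#'   the common-mode channel). Defaults to a fresh draw from `seed`;
#'   [generate_subject()] fixes them per subject so recordings of different
#'   states share the subject's spectral traits.
#'
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `fs`, `channel_labels`, `subject_id`, `state_id`,
#'   `duration`.
#' @export
#' @examples
#' rec <- generate_recording(default_profiles()[[1]], duration = 10,
#'                           fs = 128, n_channels = 4, seed = 1)
#' dim(rec$data)
generate_recording <- function(profile, duration = 300, fs = 512,
                               n_channels = 19, seed = 1,
                               subject_id = "S01", common_mode = 0.3,
                               channel_labels = NULL, osc_params = NULL) {
  if (!inherits(profile, "state_profile")) stop_param("profile must be a state_profile")
  if (duration <= 0) stop_param("duration must be positive")
  if (fs < 128) stop_param("fs must be >= 128 Hz")
  if (n_channels < 1) stop_param("n_channels must be >= 1")
  if (common_mode < 0 || common_mode >= 1) stop_param("common_mode must be in [0, 1)")
  n <- round(fs * duration)
  if (is.null(channel_labels)) {
    base <- montage_1020()
    channel_labels <- if (n_channels <= length(base)) base[seq_len(n_channels)]
                      else c(base, paste0("X", seq_len(n_channels - length(base))))
  }
  stopifnot(length(channel_labels) == n_channels)

  data <- with_seed(seed, {
    if (is.null(osc_params)) osc_params <- draw_osc_params(n_channels + 1)
    stopifnot(length(osc_params) >= n_channels + 1)
    shared <- synth_channel(profile, n, fs, osc_params[[n_channels + 1]])
    # weights normalized so mixing preserves per-channel variance
    nrm <- sqrt((1 - common_mode)^2 + common_mode^2)
    m <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      own <- synth_channel(profile, n, fs, osc_params[[ch]])
      m[ch, ] <- ((1 - common_mode) * own + common_mode * shared) / nrm
    }
    m - rowMeans(m)
  })
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id,
                 state_id = profile$state_id,
                 duration = duration),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s state=%d: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$state_id, nrow(x$data), ncol(x$data),
              x$fs, x$duration))
  invisible(x)
}

#' Generate all three recordings of one synthetic subject
#'
#' Produces the three 5-minute recordings (fatigue states 0, 1, 2) of one
#' subject. The subject's profiles are a random perturbation of the defaults
#' -- one band-weight shift and one log-scale amplitude factor drawn per
#' subject and applied to all three states alike, so between-state contrasts
#' are preserved while subjects differ. Oscillator centre frequencies and
#' modulation rates are likewise drawn once per subject and shared by the
#' three recordings: they are stable traits, not state markers, so the
#' classifier cannot tell states apart by recording-specific frequencies.
#'
#' @param subject_id Subject identifier, e.g. `"S01"`.
#' @param seed Integer seed.
#' @param duration,fs,n_channels As in [generate_recording()].
#' @param separation Between-state profile separation, see
#'   [default_profiles()].
#' @param subject_jitter SD of the additive band-weight perturbation.
#'
#' @return List of three `eeg_recording`s (states 0, 1, 2).
#' @export
generate_subject <- function(subject_id, seed, duration = 300, fs = 512,
                             n_channels = 19, separation = 1,
                             subject_jitter = 0.02) {
  profiles <- default_profiles(separation)
  pert <- with_seed(derive_seed(seed, subject_id, "profile"), {
    dw <- rnorm(4, 0, subject_jitter)
    cx_factor <- exp(rnorm(1, 0, 0.1))
    pk_factor <- exp(rnorm(1, 0, 0.1))
    lapply(profiles, function(p) {
      bw <- pmax(p$band_weights + dw, 0.01)
      p$band_weights <- bw / sum(bw)
      p$complexity_scale <- p$complexity_scale * cx_factor
      p$pink_noise_scale <- p$pink_noise_scale * pk_factor
      p
    })
  })
  osc <- with_seed(derive_seed(seed, subject_id, "osc"),
                   draw_osc_params(n_channels + 1))
  lapply(pert, function(p) {
    generate_recording(p, duration = duration, fs = fs,
                       n_channels = n_channels,
                       seed = derive_seed(seed, subject_id, "rec", p$state_id),
                       subject_id = subject_id, osc_params = osc)
  })
}

#' Generate a synthetic multi-subject study
#'
#' Three recordings (one per fatigue state) for each of `n_subjects`
#' synthetic subjects, mirroring a protocol of three 5-minute stages per
#' subject.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param ... Passed to [generate_subject()].
#'
#' @return Flat list of `3 * n_subjects` recordings, grouped by subject.
#' @export
#' @examples
#' study <- generate_study(2, seed = 7, duration = 10, fs = 128,
#'                         n_channels = 3)
#' length(study)
generate_study <- function(n_subjects, seed, ...) {
  if (n_subjects < 1) stop_param("n_subjects must be >= 1")
  ids <- sprintf("S%02d", seq_len(n_subjects))
  recs <- lapply(ids, function(sid) generate_subject(sid, seed, ...))
  do.call(c, recs)
}
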