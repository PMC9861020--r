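# Welch PSD, relative band power, fuzzy entropy, feature assembly.

test_that("Welch PSD satisfies Parseval and locates spectral peaks", {
  set.seed(1)
  x <- rnorm(8192)
  p <- welch_psd(x, fs = 128)
  expect_equal(sum(p$power) * (p$freqs[2] - p$freqs[1]), 1, tolerance = 0.1)
  expect_true(all(p$power >= 0))
  expect_equal(p$freqs[1], 0)

  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ps <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_lte(abs(ps$freqs[which.max(ps$power)] - 10),
             ps$freqs[2] - ps$freqs[1])

  pz <- welch_psd(numeric(512), fs = 128)
  expect_true(all(pz$power == 0))
  expect_error(welch_psd(rnorm(100), fs = 128, nperseg = 200), "exceeds")
})

test_that("relative band power behaves on pure tones and flat spectra", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  bands <- eeg_bands()
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_gte(relative_band_power(psd, bands[bands$name == "alpha", ]), 0.95)

  # flat noise: beta share of [0,30] is proportional to bin count
  set.seed(2)
  pn <- welch_psd(rnorm(65536), fs)
  rbp_beta <- relative_band_power(pn, bands[bands$name == "beta", ])
  expect_equal(rbp_beta, 16 / 30, tolerance = 0.1)

  whole <- list(f_lo = 0, f_hi = 30)
  expect_identical(relative_band_power(psd, whole), 1)

  expect_error(relative_band_power(psd, list(f_lo = 10, f_hi = 40)),
               "within the total range")
  expect_error(relative_band_power(welch_psd(numeric(512), fs), whole),
               "zero")
})

test_that("band powers over disjoint bands sum to at most one", {
  fs <- 256
  bands <- eeg_bands()
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(2048) + sin(2 * pi * runif(1, 1, 40) * seq_len(2048) / fs)
    psd <- welch_psd(x, fs)
    tot <- sum(vapply(seq_len(4), function(b) {
      relative_band_power(psd, bands[b, ], 0, fs / 2)
    }, 0))
    expect_lte(tot, 1 + 1e-9)
  }
})

test_that("fuzzy entropy matches the brute-force oracle", {
  series <- list(
    c(2, 4, 6, 8, 10, 8, 6, 4, 2, 4, 6, 8),
    sin(seq(0, 6 * pi, length.out = 100)),
    local({ set.seed(4); rnorm(120) }),
    local({ set.seed(5); ar1_series(90) })
  )
  for (x in series) {
    got <- fuzzy_entropy(x, fuzzyen_params(m = 2, n = 2, r = 0.2))
    want <- fuzzyen_oracle(x, m = 2, nexp = 2, r_frac = 0.2)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # non-default parameters hit the general pow() path
  x <- series[[3]]
  expect_equal(fuzzy_entropy(x, fuzzyen_params(m = 3, n = 1.5, r = 0.15)),
               fuzzyen_oracle(x, m = 3, nexp = 1.5, r_frac = 0.15),
               tolerance = 1e-9)
  expect_equal(fuzzy_entropy(rep(1, 50)), 0)
  expect_error(fuzzy_entropy(c(1, 2, 3, 4), fuzzyen_params(m = 2)), "length")
})

test_that("fuzzy entropy is scale- and offset-invariant and ranks complexity", {
  set.seed(6)
  x <- rnorm(150)
  fe <- fuzzyen_params()
  base <- fuzzy_entropy(x, fe)
  expect_equal(fuzzy_entropy(5 * x, fe), base, tolerance = 1e-9)
  expect_equal(fuzzy_entropy(x + 100, fe), base, tolerance = 1e-9)

  wins <- 0
  for (i in 1:100) {
    n <- 120
    s <- sin(seq(0, 8 * pi, length.out = n) + runif(1, 0, 2 * pi))
    w <- rnorm(n) * sd(s)
    if (fuzzy_entropy(w, fe) > fuzzy_entropy(s, fe)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("fuzzy and sample entropy rank sine < AR(1) < white noise alike", {
  set.seed(7)
  fe <- fuzzyen_params()
  ranks_agree <- 0
  for (i in 1:20) {
    n <- 150
    sine <- sin(seq(0, 10 * pi, length.out = n) + runif(1, 0, 2 * pi))
    ar <- ar1_series(n)
    wn <- rnorm(n)
    fz <- c(fuzzy_entropy(sine, fe), fuzzy_entropy(ar, fe),
            fuzzy_entropy(wn, fe))
    se <- c(sample_entropy(sine), sample_entropy(ar), sample_entropy(wn))
    if (!is.unsorted(fz) && !is.unsorted(se)) ranks_agree <- ranks_agree + 1
  }
  expect_gte(ranks_agree, 16)
})

test_that("feature vectors have 5 values per channel in fixed order", {
  rec19 <- generate_recording(default_profiles()[[1]], duration = 10,
                              fs = 128, n_channels = 19, seed = 8)
  seg <- segment_recording(rec19, train_duration = 6)[[1]]
  f <- extract_features(seg)
  expect_length(f, 95)
  expect_equal(names(f), feature_names(rec19$channel_labels))

  rec1 <- generate_recording(default_profiles()[[1]], duration = 10,
                             fs = 128, n_channels = 1, seed = 8)
  seg1 <- segment_recording(rec1, train_duration = 6)[[1]]
  expect_length(extract_features(seg1), 5)

  # identical channels give identical feature blocks
  dup <- make_segment(rbind(a = seg1$data[1, ], b = seg1$data[1, ]), 128)
  fd <- extract_features(dup)
  expect_equal(unname(fd[1:5]), unname(fd[6:10]))
})

test_that("extract_features equals manually composed per-operation calls", {
  rec <- generate_recording(default_profiles()[[2]], duration = 10,
                            fs = 128, n_channels = 2, seed = 9)
  seg <- segment_recording(rec, train_duration = 6)[[1]]
  f <- extract_features(seg)
  bands <- eeg_bands()
  for (ch in 1:2) {
    x <- seg$data[ch, ]
    psd <- welch_psd(x, 128, nperseg = 128)
    for (b in seq_len(4)) {
      expect_equal(unname(f[(ch - 1) * 5 + b]),
                   relative_band_power(psd, bands[b, ]))
    }
    expect_equal(unname(f[(ch - 1) * 5 + 5]),
                 fuzzy_entropy(x, fuzzyen_params()))
  }
})
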