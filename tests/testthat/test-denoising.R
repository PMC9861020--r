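# EMD / CEEMD / sample entropy / ICA / CEEMD-ICA denoising and baselines.

test_that("EMD handles monotone input and isolates a pure tone", {
  ramp <- seq(0, 1, length.out = 128)
  dec <- emd(ramp)
  expect_equal(nrow(dec$imfs), 0)
  expect_equal(dec$residual, ramp)

  t <- seq(0, 2, length.out = 1024)
  x <- sin(2 * pi * 10 * t)
  dec <- emd(x)
  expect_gt(cor(dec$imfs[1, ], x), 0.99)
  expect_lt(sum(dec$residual^2) / sum(x^2), 0.01)
})

test_that("EMD reconstruction identity holds on random mixtures", {
  set.seed(7)
  for (i in 1:20) {
    t <- seq(0, 2, length.out = 256)
    x <- rnorm(256) + 3 * sin(2 * pi * runif(1, 2, 20) * t) + 2 * t
    dec <- emd(x)
    rec <- imf_reconstruct(dec)
    expect_lt(sqrt(sum((rec - x)^2)) / sqrt(sum(x^2)), 1e-6)
  }
  expect_error(emd(rnorm(32)), "64")
  expect_error(emd(c(rnorm(100), NA)), "finite")
})

test_that("CEEMD agrees with EMD in the zero-noise limit and is deterministic", {
  set.seed(3)
  t <- seq(0, 2, length.out = 512)
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 40 * t) + 0.1 * rnorm(512)
  ref <- emd(x)
  lim <- ceemd(x, n_pairs = 1, noise_std_ratio = 1e-8, seed = 4)
  expect_equal(nrow(lim$imfs), nrow(ref$imfs))
  for (k in seq_len(nrow(ref$imfs))) {
    expect_lt(sqrt(sum((lim$imfs[k, ] - ref$imfs[k, ])^2)) /
                sqrt(sum(ref$imfs[k, ]^2)), 1e-3)
  }

  a <- ceemd(x, n_pairs = 4, noise_std_ratio = 0.2, seed = 5)
  b <- ceemd(x, n_pairs = 4, noise_std_ratio = 0.2, seed = 5)
  expect_identical(a$imfs, b$imfs)
  # exact reconstruction by construction
  expect_lt(sqrt(sum((imf_reconstruct(a) - x)^2)) / sqrt(sum(x^2)), 1e-12)
  expect_error(ceemd(x, n_pairs = 0), "n_pairs")
  expect_error(ceemd(x, noise_std_ratio = 1.5), "noise_std_ratio")
})

test_that("sample entropy matches the brute-force oracle", {
  series <- list(
    rep(c(1, 2, 3), 4),
    sin(seq(0, 6 * pi, length.out = 120)),
    local({ set.seed(1); rnorm(150) }),
    local({ set.seed(2); ar1_series(100) }),
    local({ set.seed(3); cumsum(rnorm(80)) })
  )
  for (x in series) {
    got <- sample_entropy(x, m = 2, r = 0.2)
    want <- sampen_oracle(x, m = 2, r_frac = 0.2)
    if (is.infinite(want)) expect_true(is.infinite(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
  expect_equal(sample_entropy(rep(5, 50)), 0)   # zero-variance convention
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
})

test_that("white noise is more entropic than a sine of equal variance", {
  set.seed(11)
  wins <- 0
  for (i in 1:100) {
    n <- 150
    s <- sin(seq(0, 8 * pi, length.out = n) + runif(1, 0, 2 * pi))
    w <- rnorm(n) * sd(s)
    if (sample_entropy(w) > sample_entropy(s)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("noisy-IMF selection ranks by entropy with documented tie-breaks", {
  set.seed(21)
  t <- seq(0, 4, length.out = 600)
  rows <- rbind(rnorm(600),                      # high entropy
                sin(2 * pi * 25 * t) + 0.3 * rnorm(600),
                sin(2 * pi * 10 * t),
                sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 2 * t),
                sin(2 * pi * 0.5 * t))
  fake <- structure(list(imfs = rows, residual = numeric(600),
                         source_length = 600), class = "imf_set")
  expect_equal(select_noisy_imfs(fake, k = 2), c(1L, 2L))
  expect_equal(select_noisy_imfs(fake, k = 6), 1:5)    # clamp to available

  same <- structure(list(imfs = rows[c(3, 3, 3), ], residual = numeric(600),
                         source_length = 600), class = "imf_set")
  expect_equal(select_noisy_imfs(same, k = 2), c(1L, 2L))  # ties: low index
})

test_that("fixed-point ICA unmixes, reconstructs, and is deterministic", {
  set.seed(31)
  n <- 800
  s <- rbind(sin(seq(0, 31, length.out = n)), runif(n) - 0.5)
  A <- matrix(c(1, 0.6, 0.4, 1), 2, 2)
  x <- A %*% s
  dec <- ica_decompose(x, seed = 2)
  cors <- abs(cor(t(dec$sources), t(s)))
  expect_true(all(apply(cors, 2, max) > 0.95))
  expect_lt(max(abs(ica_reconstruct(dec) - x)), 1e-6)
  expect_equal(apply(dec$sources, 1, var) * (n - 1) / n, c(1, 1),
               tolerance = 1e-6)

  dec2 <- ica_decompose(x, seed = 2)
  expect_identical(dec$sources, dec2$sources)

  # rank-deficient input: third row collinear
  x3 <- rbind(x, 2 * x[1, ])
  dec3 <- suppressWarnings(ica_decompose(x3, seed = 2))
  expect_equal(dec3$rank, 2)
  expect_error(ica_decompose(x[1, , drop = FALSE]), "2 rows")
})

test_that("CEEMD-ICA denoising suppresses >30 Hz noise and keeps length", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  set.seed(41)
  improved <- 0
  for (i in 1:5) {
    clean <- 30 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
    noisy <- clean + 10 * sin(2 * pi * 45 * t) + 3 * rnorm(length(t))
    den <- suppressWarnings(denoise_channel(noisy, seed = i, n_pairs = 10))
    expect_length(den, length(noisy))
    expect_lt(hf_fraction(den, fs), 0.5 * hf_fraction(noisy, fs))
    if (cor(den, clean) > cor(noisy, clean)) improved <- improved + 1
  }
  expect_gte(improved, 4)
})

test_that("denoising details record the pipeline decisions", {
  fs <- 256
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  set.seed(43)
  x <- 20 * sin(2 * pi * 8 * t) + 5 * rnorm(length(t))
  d <- suppressWarnings(denoise_channel(x, seed = 1, n_pairs = 5,
                                        details = TRUE))
  expect_true(d$n_imf >= length(d$noisy))
  expect_true(d$zeroed_ic %in% seq_along(d$ic_entropy))
  expect_equal(d$zeroed_ic, which.max(d$ic_entropy))
})

test_that("segment denoising preserves shape, metadata and channel independence", {
  fs <- 256
  rec <- generate_recording(default_profiles()[[1]], duration = 10, fs = fs,
                            n_channels = 3, seed = 51)
  seg <- segment_recording(rec, train_duration = 4)[[1]]
  seg$data[3, ] <- 0                       # degenerate flat channel
  den <- suppressWarnings(denoise_segment(seg, seed = 1, n_pairs = 5))
  expect_equal(dim(den$data), dim(seg$data))
  expect_equal(den$subject_id, seg$subject_id)
  expect_equal(den$role, seg$role)
  expect_equal(den$data[3, ], seg$data[3, ])   # flat channel untouched

  # permuting channels permutes the output identically
  perm <- c(2, 1, 3)
  segp <- seg; segp$data <- seg$data[perm, ]
  denp <- suppressWarnings(denoise_segment(segp, seed = 1, n_pairs = 5))
  expect_equal(denp$data, den$data[perm, ], tolerance = 1e-12)
})

test_that("low-pass baseline passes 10 Hz, stops 45 Hz, keeps DC", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mk <- function(x) make_segment(matrix(x, 1), fs)
  hi <- lowpass_baseline(mk(sin(2 * pi * 45 * t)))
  expect_lt(sqrt(mean(hi$data^2)), 0.05)
  lo <- lowpass_baseline(mk(sin(2 * pi * 10 * t)))
  expect_equal(sqrt(mean(lo$data^2)), sqrt(0.5), tolerance = 0.05)
  dc <- lowpass_baseline(mk(rep(2, length(t))))
  expect_equal(as.numeric(dc$data), rep(2, length(t)), tolerance = 1e-4)
  expect_error(lowpass_baseline(mk(rnorm(1024)), cutoff = 128), "fs/2")
})

test_that("db4 wavelet transform reconstructs exactly and denoises", {
  set.seed(61)
  x <- rnorm(256)
  dec <- eegfatigue:::wavelet_decompose(x, 4)
  expect_equal(eegfatigue:::wavelet_reconstruct(dec), x, tolerance = 1e-10)

  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  smooth <- 10 * sin(2 * pi * 3 * t)
  out <- wavelet_baseline(make_segment(matrix(smooth, 1), fs))
  expect_lt(sqrt(sum((out$data - smooth)^2)) / sqrt(sum(smooth^2)), 0.05)

  clean <- 10 * sin(2 * pi * 5 * t)
  noisy <- clean + 2 * rnorm(length(t))
  den <- wavelet_baseline(make_segment(matrix(noisy, 1), fs))
  expect_lt(mean((den$data - clean)^2), mean((noisy - clean)^2))

  z <- wavelet_baseline(make_segment(matrix(0, 1, 256), fs))
  expect_equal(as.numeric(z$data), rep(0, 256))
})

test_that("CEEMD-discard baseline partitions energy as documented", {
  fs <- 256
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  set.seed(71)
  x <- 10 * sin(2 * pi * 2 * t) + 5 * rnorm(length(t))
  seg <- make_segment(matrix(x, 1), fs)
  k <- 3
  out <- ceemd_discard_baseline(seg, k = k, seed = 9, n_pairs = 5)
  dec <- ceemd(x, n_pairs = 5, seed = 9)
  discarded <- imf_reconstruct(dec, which = seq_len(min(k, nrow(dec$imfs))),
                               residual = FALSE)
  expect_equal(as.numeric(out$data) + discarded, x, tolerance = 1e-9)

  # high-frequency-only signal loses nearly all its power
  hf <- sin(2 * pi * 60 * t)
  outhf <- ceemd_discard_baseline(make_segment(matrix(hf, 1), fs),
                                  k = 6, seed = 1, n_pairs = 5)
  expect_lt(sum(outhf$data^2), 0.05 * sum(hf^2))
})
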