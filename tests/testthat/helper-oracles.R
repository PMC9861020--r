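# Brute-force reference implementations and small fixtures used across the
# suite. The oracles enumerate every template/pair explicitly and are kept
# independent of the package's compiled code paths.

# Sample entropy by exhaustive template counting. Both template lengths use
# i = 1..N-m so the conditional probability is well defined.
sampen_oracle <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(dm, abs(x[i + m] - x[j + m]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# Fuzzy entropy by exhaustive double loop: unit-SD standardization,
# mean-subtracted embeddings, Chebyshev distances, similarity
# exp(-d^nexp / r).
fuzzyen_oracle <- function(x, m = 2, nexp = 2, r_frac = 0.2) {
  x <- x / sd(x)
  n <- length(x)
  r <- r_frac
  phi <- function(mm) {
    nt <- n - m                      # same template count for m and m+1
    vecs <- lapply(seq_len(nt), function(i) {
      v <- x[i:(i + mm - 1)]
      v - mean(v)
    })
    tot <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        d <- max(abs(vecs[[i]] - vecs[[j]]))
        tot <- tot + exp(-d^nexp / r)
      }
    }
    tot / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

# Fraction of Welch power above `cut` Hz.
hf_fraction <- function(x, fs, cut = 30) {
  p <- welch_psd(x, fs)
  sum(p$power[p$freqs > cut]) / sum(p$power)
}

# Wrap a plain matrix as an eeg_segment.
make_segment <- function(data, fs, subject_id = "SX", state_id = 0L,
                         role = "train", start_time = 0) {
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 state_id = state_id, role = role, start_time = start_time),
            class = "eeg_segment")
}

# AR(1) series used for complexity-ranking checks.
ar1_series <- function(n, phi = 0.95) {
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
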