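# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use naive loops over the defining formulas,
# not the package's FFT/vectorized code paths.

# Explicit time-domain scattering: reflection padding by index arithmetic,
# direct convolution sums, modulus, non-overlapping block means.
scatter_oracle <- function(sig, bank) {
  x <- sig$values
  n <- length(x)
  refl <- function(i) {            # reflect any integer indices into 1..n
    p <- 2L * n - 2L
    m <- (i - 1L) %% p
    ifelse(m < n, m + 1L, 2L * n - 1L - m)
  }
  lp <- round(bank$pooling_seconds * sig$fs)
  n_frames <- floor(n / lp)
  S <- matrix(0, length(bank$wavelets), n_frames)
  for (w in seq_along(bank$wavelets)) {
    taps <- bank$wavelets[[w]]$taps
    m <- (length(taps) - 1L) %/% 2L
    shifts <- seq_along(taps) - m - 1L   # tap k sits at lag k - M - 1
    env <- numeric(n)
    for (i in seq_len(n)) {
      # y[i] = sum_k taps[k] * x_reflected[i - (k - M - 1)]
      env[i] <- Mod(sum(taps * x[refl(i - shifts)]))
    }
    for (f in seq_len(n_frames)) {
      S[w, f] <- mean(env[((f - 1L) * lp + 1L):(f * lp)])
    }
  }
  S
}

# AMPD from the scalogram definition, double loops throughout.
ampd_oracle <- function(values, fs, max_scale_s = 1.5) {
  x <- values
  n <- length(x)
  idx <- seq_len(n)
  fit <- stats::lm(x ~ idx)
  x <- stats::residuals(fit)
  L <- min(floor(max_scale_s * fs), (n - 1L) %/% 2L)
  m <- matrix(1L, L, n)
  for (k in seq_len(L)) {
    for (i in seq_len(n)) {
      if (i > k && i <= n - k && x[i] > x[i - k] && x[i] > x[i + k]) {
        m[k, i] <- 0L
      }
    }
  }
  gamma <- rowSums(m)
  lambda <- which(gamma == min(gamma))[1L]
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (all(m[seq_len(lambda), i] == 0L)) peaks <- c(peaks, i)
  }
  peaks
}

# Loop-based SDNN / RMSSD straight from the defining sums.
sdnn_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (x[i] - mu)^2
  sqrt(acc / (n - 1))
}

rmssd_oracle <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n - 1)) acc <- acc + (x[i + 1] - x[i])^2
  sqrt(acc / (n - 1))
}

# Overlap-add coverage count by brute force: how many plan windows cover
# each sample.
coverage_oracle <- function(plan) {
  n <- attr(plan, "n_samples")
  cov <- integer(n)
  for (j in seq_len(nrow(plan))) {
    cov[plan$start_i[j]:plan$end_i[j]] <- cov[plan$start_i[j]:plan$end_i[j]] + 1L
  }
  cov
}

# Frequency of the largest FFT magnitude (one-sided, DC excluded).
dominant_frequency_vec <- function(values, fs) {
  n <- length(values)
  sp <- abs(stats::fft(values - mean(values)))[seq_len(floor(n / 2))]
  ((seq_len(floor(n / 2)) - 1) * fs / n)[which.max(sp)]
}

make_sine <- function(freq, fs, duration, amp = 1, phase = 0) {
  sampled_signal(amp * sin(2 * pi * freq * (0:(round(duration * fs) - 1)) / fs
                           + phase), fs = fs)
}
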