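test_that("AMPD finds one peak per period on a clean pulse train", {
  spec <- synth_spec(mean_rr_ms = 1000, sigma_ms = 0, duration_s = 30,
                     fs = 32, snr_db = Inf, drift_amp = 0, seed = 1)
  truth <- generate_ibi_series(spec)
  rec <- render_ppg(truth, spec)
  pk <- detect_peaks_ampd(rec$signal)
  expect_gte(length(pk$indices), 29)
  expect_lte(length(pk$indices), 30)
  expect_true(all(diff(pk$indices) > 0))
})

test_that("a monotonic ramp has no peaks and short signals warn", {
  ramp <- sampled_signal(exp(seq(0, 1, length.out = 200)), 32)
  expect_length(detect_peaks_ampd(ramp)$indices, 0)
  expect_warning(pk <- detect_peaks_ampd(sampled_signal(c(1, 2), 32)),
                 "too short")
  expect_length(pk$indices, 0)
})

test_that("AMPD at 20 dB SNR localizes every peak within 100 ms, no duplicates", {
  for (seed in 1:3) {
    spec <- synth_spec(mean_rr_ms = 800, sigma_ms = 25, duration_s = 60,
                       fs = 32, snr_db = 20, drift_amp = 0, seed = seed)
    truth <- generate_ibi_series(spec)
    rec <- render_ppg(truth, spec)
    pk <- detect_peaks_ampd(rec$signal)
    matched <- vapply(pk$times, function(tp) {
      min(abs(rec$beat_times - tp))
    }, numeric(1))
    expect_lt(max(matched), 0.100)
    # no two detections claim the same beat
    nearest <- vapply(pk$times, function(tp) which.min(abs(rec$beat_times - tp)),
                      integer(1))
    expect_false(any(duplicated(nearest)))
  }
})

test_that("AMPD equals the brute-force scalogram definition index-for-index", {
  set.seed(41)
  for (rep in 1:4) {
    v <- sin(2 * pi * runif(1, 0.8, 1.4) * (0:199) / 20) + 0.25 * rnorm(200)
    expect_identical(detect_peaks_ampd(sampled_signal(v, 20))$indices,
                     ampd_oracle(v, 20))
  }
})

test_that("IBI conversion is exact sample arithmetic", {
  pk <- structure(list(indices = c(1L, 33L, 65L), times = c(0, 32, 64) / 32,
                       fs = 32, lambda = 5L), class = "peak_set")
  s <- peaks_to_ibis(pk)
  expect_equal(s$ibis_ms, c(1000, 1000))
  pk2 <- structure(list(indices = c(1L, 31L, 63L), times = c(0, 30, 62) / 32,
                        fs = 32, lambda = 5L), class = "peak_set")
  expect_equal(peaks_to_ibis(pk2)$ibis_ms, c(937.5, 1000))
  # fewer than two peaks: empty series
  pk0 <- structure(list(indices = 5L, times = 5 / 32, fs = 32, lambda = 1L),
                   class = "peak_set")
  expect_length(peaks_to_ibis(pk0), 0)
})

test_that("parabolic refinement recovers sub-sample peak positions", {
  fs <- 32
  true_t <- 1.01375                       # deliberately between samples
  t <- (0:(3 * fs - 1)) / fs
  sig <- sampled_signal(1 - (t - true_t)^2, fs)
  i_max <- which.max(sig$values)
  pk <- structure(list(indices = c(1L, i_max),
                       times = c(0, (i_max - 1) / fs), fs = fs, lambda = 3L),
                  class = "peak_set")
  refined <- peaks_to_ibis(pk, sig = sig, subsample = TRUE)
  est_t <- refined$beat_times_s[1]
  expect_lt(abs(est_t - true_t), 0.1 / fs)
  # without refinement the error is the sample quantization itself
  coarse <- peaks_to_ibis(pk, subsample = FALSE)
  expect_gt(abs(coarse$beat_times_s[1] - true_t), abs(est_t - true_t))
})

test_that("the three refinement rules drop exactly the right intervals", {
  mk <- function(ibis) ibi_series(ibis, cumsum(ibis) / 1000)

  # all-clean series passes untouched
  r <- refine_ibis(mk(c(800, 810, 790, 805)))
  expect_equal(r$series$ibis_ms, c(800, 810, 790, 805))
  expect_equal(nrow(r$drops), 0)
  expect_false(r$unreliable)

  # rule 1: hard physiological bounds
  r1 <- refine_ibis(mk(c(800, 350, 810)))
  expect_equal(r1$series$ibis_ms, c(800, 810))
  expect_equal(r1$drops$rule, 1L)
  expect_equal(r1$drops$index, 2L)

  # rule 2: twenty 800s plus one 1200: mean ~819, 1200 > mean + 0.4*mean
  ibis <- c(rep(800, 20), 1200)
  r2 <- refine_ibis(mk(ibis))
  expect_equal(r2$series$ibis_ms, rep(800, 20))
  expect_equal(r2$drops$rule, 2L)
  expect_equal(r2$drops$index, 21L)

  # rule 3: a block-local outlier passing rules 1-2
  # mean of 40 IBIs ~ 806 -> rule 2 bound ~ [484, 1129]; block of 10 with a
  # 1050 outlier: block mean 825, bound 0.2 * 825 = 165 -> 1050 > 990 dropped
  ibis3 <- c(rep(800, 15), 1050, rep(800, 24))
  r3 <- refine_ibis(mk(ibis3))
  expect_equal(r3$drops$rule, 3L)
  expect_equal(r3$drops$index, 16L)
  expect_equal(length(r3$series), 39)
})

test_that("refinement output is always a subsequence and converges quickly", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    # plausible beats with occasional gross outliers, as after peak detection
    ibis <- 800 + rnorm(n, 0, 100)
    k <- stats::rbinom(1, n, 0.1)
    if (k > 0) ibis[sample.int(n, k)] <- runif(k, 300, 1500)
    ibis <- pmax(ibis, 250)
    s <- ibi_series(ibis, cumsum(ibis) / 1000)
    r <- refine_ibis(s)
    # subsequence: surviving values appear in order in the input
    expect_true(all(r$series$ibis_ms %in% ibis))
    expect_true(!is.unsorted(match(r$series$beat_times_s, s$beat_times_s)))
    expect_equal(length(r$series) + nrow(r$drops), n)
    # convergence within 3 passes
    cur <- r$series; n_prev <- length(cur); passes <- 0
    while (length(cur) > 0 && passes < 3) {
      nxt <- refine_ibis(cur)$series
      if (length(nxt) == length(cur)) break
      cur <- nxt; passes <- passes + 1
    }
    if (length(cur) > 0) {
      expect_equal(length(refine_ibis(cur)$series), length(cur))
    }
  }
})

test_that("empty refinement is flagged unreliable", {
  s <- ibi_series(c(200, 250, 300), c(0.2, 0.45, 0.75))
  r <- refine_ibis(s)
  expect_true(r$unreliable)
  expect_length(r$series, 0)
  expect_equal(nrow(r$drops), 3)
})

test_that("IBI CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- ibi_series(c(800, 820), c(0.8, 1.62))
  write_ibis_csv(s, path)
  r <- read_ibis_csv(path)
  expect_equal(r$ibis_ms, s$ibis_ms)
  expect_equal(r$beat_times_s, s$beat_times_s)
})
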