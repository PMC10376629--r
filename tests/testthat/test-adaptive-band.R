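test_that("window plans tile the signal and clip the final window", {
  plan <- window_plan(60, 32, window_seconds = 14.5, step_seconds = 2)
  expect_equal(plan$start_s, seq(0, 46, by = 2))
  expect_true(all(plan$end_s <= 60))
  expect_equal(plan$end_s[nrow(plan)], 60)
  expect_true(all(plan$end_i <= attr(plan, "n_samples")))
  # a short record yields a single full-cover window
  p1 <- window_plan(10, 32)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$end_s, 10)
  expect_error(window_plan(60, 32, step_seconds = 0), "step")
})

test_that("energy interpolation is linear between pooled frames", {
  co <- structure(list(
    S = cbind(c(2, 1), c(4, 3)),
    frame_times = c(8, 24),
    center_frequencies = c(1, 2),
    pooling_seconds = 16, fs = 32), class = "scattering_coeffs")
  at <- function(t) interp_window_energy(co, t)$energies
  expect_equal(at(8), c(2, 1))          # x = 0: left frame
  expect_equal(at(24), c(4, 3))         # x = D: right frame
  expect_equal(at(16), c(3, 2))         # midpoint
  expect_equal(at(0), c(2, 1))          # clamped below
  expect_equal(at(100), c(4, 3))        # clamped above
  # single-frame fallback
  co1 <- co; co1$S <- co$S[, 1, drop = FALSE]; co1$frame_times <- 8
  expect_equal(interp_window_energy(co1, 30)$energies, c(2, 1))
})

test_that("band estimation brackets a sharp energy peak and is reproducible", {
  freqs <- exp(seq(log(0.7), log(5), length.out = 20))
  energies <- exp(-(log(freqs / 1.2))^2 / (2 * 0.08^2))  # sharp peak at 1.2 Hz
  b <- estimate_band(freqs, energies, seed = 0)
  expect_s3_class(b, "frequency_band")
  expect_lte(b[[1]], 1.2)
  expect_gte(b[[2]], 1.2)
  expect_lt(b[[2]] - b[[1]], 5 - 0.7)   # narrower than the full band
  expect_identical(estimate_band(freqs, energies, seed = 0), b)
  b42 <- estimate_band(freqs, energies, seed = 42)
  expect_identical(estimate_band(freqs, energies, seed = 42), b42)
})

test_that("flat energies stay in the global band deterministically", {
  freqs <- exp(seq(log(0.7), log(5), length.out = 20))
  b <- estimate_band(freqs, rep(1, 20), seed = 0)
  expect_gte(b[[1]], 0.7)
  expect_lte(b[[2]], 5)
  expect_identical(estimate_band(freqs, rep(1, 20), seed = 0), b)
})

test_that("band estimation falls back gracefully on degenerate inputs", {
  expect_warning(b <- estimate_band(c(1, 1, 1), c(1, 2, 3), seed = 0),
                 "full band")
  expect_equal(unclass(b), c(low = 0.7, high = 5))
  expect_warning(estimate_band(c(1, 2), c(1, 2), seed = 0), "full band")
})

test_that("peak_cluster rule spans the high-energy wavelets", {
  freqs <- exp(seq(log(0.7), log(5), length.out = 20))
  energies <- exp(-(log(freqs / 1.5))^2 / (2 * 0.1^2))
  b <- estimate_band(freqs, energies, seed = 0, rule = "peak_cluster")
  expect_lte(b[[1]], 1.5)
  expect_gte(b[[2]], 1.5)
})

test_that("window refinement keeps in-band tones, kills drift, centres output", {
  seg <- make_sine(1.2, 32, 14.5)
  out <- refine_window(seg, frequency_band(1.0, 1.5))
  mid <- seq(round(length(out$values) * 0.25), round(length(out$values) * 0.75))
  expect_gt(max(abs(out$values[mid])), 0.9)
  expect_lt(max(abs(out$values[mid])), 1.1)
  expect_lt(abs(mean(out$values)), 1e-9 * stats::sd(out$values))

  # stopband measured on a longer segment so edge transients (short relative
  # to the record) do not dominate the spectrum estimate
  drift <- sampled_signal(make_sine(1.2, 32, 30)$values +
                            2 * sin(2 * pi * 0.3 * (0:(30 * 32 - 1)) / 32), 32)
  outd <- refine_window(drift, frequency_band(1.0, 1.5))
  n <- length(outd$values)
  sp <- function(v, f0) {
    m <- abs(stats::fft(v))[1:(n / 2)]
    m[which.min(abs((0:(n / 2 - 1)) * 32 / n - f0))]
  }
  expect_lt(20 * log10(sp(outd$values, 0.3) / sp(drift$values, 0.3)), -40)
  # degenerate band is widened instead of failing
  expect_silent(refine_window(seg, frequency_band(1.2, 1.21)))
})

test_that("overlap-add reconstruction sums covering windows", {
  # single window covering everything: identity
  plan1 <- window_plan(10, 32, window_seconds = 10, step_seconds = 10)
  seg <- make_sine(1, 32, 10)
  expect_equal(reconstruct_overlap_add(list(seg), plan1)$values, seg$values)

  # two half-overlapping identical windows double the overlap region
  plan2 <- window_plan(15, 32, window_seconds = 10, step_seconds = 5)
  expect_equal(nrow(plan2), 2)
  segs <- lapply(seq_len(nrow(plan2)), function(j) {
    sampled_signal(rep(1, plan2$end_i[j] - plan2$start_i[j] + 1), 32)
  })
  rec <- reconstruct_overlap_add(segs, plan2)
  cov <- coverage_oracle(plan2)
  expect_equal(rec$values, as.numeric(cov))
  expect_true(any(cov == 2))

  # default geometry: per-sample coverage matches the brute-force count
  plan <- window_plan(60, 32)
  segs <- lapply(seq_len(nrow(plan)), function(j) {
    rep(1, plan$end_i[j] - plan$start_i[j] + 1)
  })
  rec <- reconstruct_overlap_add(segs, plan)
  cov <- coverage_oracle(plan)
  expect_equal(rec$values, as.numeric(cov))
  interior <- cov[(15 * 32):(44 * 32)]
  expect_true(all(interior %in% c(floor(14.5 / 2), ceiling(14.5 / 2))))

  expect_error(reconstruct_overlap_add(segs[-1], plan), "segments")
})

test_that("reconstruction is linear in its segments", {
  plan <- window_plan(30, 32)
  mk <- function(f) lapply(seq_len(nrow(plan)), function(j) {
    n <- plan$end_i[j] - plan$start_i[j] + 1
    f(n)
  })
  set.seed(31)
  a <- mk(function(n) rnorm(n)); b <- mk(function(n) rnorm(n))
  ab <- Map(function(x, y) 2 * x + 3 * y, a, b)
  expect_equal(reconstruct_overlap_add(ab, plan)$values,
               2 * reconstruct_overlap_add(a, plan)$values +
                 3 * reconstruct_overlap_add(b, plan)$values)
})

test_that("edge gains equalize window coverage and leave the interior alone", {
  plan <- window_plan(120, 32)
  w <- attr(plan, "w"); s <- attr(plan, "s")
  expect_equal(w / s, 7.25)
  # first slice gain is w/s / 1 = 7.25 (applied to a unit signal)
  unit <- sampled_signal(rep(1, attr(plan, "n_samples")), 32)
  amp <- amplify_edges(unit, plan)
  expect_equal(amp$values[1], 7.25)
  expect_equal(amp$values[length(amp$values)], 7.25)
  # second slice: 7.25 / 2
  expect_equal(amp$values[round(1.5 * s * 32)], 7.25 / 2)
  # interior (beyond w from the ends) is bit-identical
  interior <- (round(w * 32) + 32):(attr(plan, "n_samples") - round(w * 32) - 32)
  expect_identical(amp$values[interior], unit$values[interior])
  # gains are capped below at 1 (no interior attenuation)
  expect_true(all(amp$values >= 1))
})

test_that("reconstruct + amplify yields a uniform envelope end to end", {
  fs <- 32
  sine <- make_sine(1.25, fs, 120)
  plan <- window_plan(120, fs)
  segs <- lapply(seq_len(nrow(plan)), function(j) {
    sine$values[plan$start_i[j]:plan$end_i[j]]
  })
  out <- amplify_edges(reconstruct_overlap_add(segs, plan), plan)
  # envelope via RMS in step-length blocks; uniform within 10% everywhere,
  # including both record ends
  block <- attr(plan, "s") * fs
  nb <- floor(length(out$values) / block)
  env <- vapply(seq_len(nb), function(b) {
    sqrt(mean(out$values[((b - 1) * block + 1):(b * block)]^2))
  }, numeric(1))
  expect_lt(max(env) / min(env), 1.10)
})
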