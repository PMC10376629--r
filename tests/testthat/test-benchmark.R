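mk_series <- function(ibis) ibi_series(ibis, cumsum(ibis) / 1000)

test_that("clean ground truth accepts plausible series untouched", {
  r <- clean_ground_truth(mk_series(rep(800, 40) + rep(c(-10, 10), 20)))
  expect_true(r$accepted)
  expect_length(r$reasons, 0)
  expect_equal(r$ibis_removed, 0)
  expect_equal(length(r$cleaned), 40)
})

test_that("implausible instantaneous heart rate rejects the recording", {
  # a 250 ms interval is 240 bpm: device glitch, evaluated before cleaning
  r <- clean_ground_truth(mk_series(c(rep(800, 30), 250)))
  expect_false(r$accepted)
  expect_true("hr_out_of_range" %in% r$reasons)
  # 45-200 bpm boundary: 1400 ms would be ~43 bpm but is caught by HR rule
  r2 <- clean_ground_truth(mk_series(c(rep(800, 30), 1400)))
  expect_true("hr_out_of_range" %in% r2$reasons)
})

test_that("face_covered metadata rejects regardless of the data", {
  r <- clean_ground_truth(mk_series(rep(800, 30)), face_covered = TRUE)
  expect_false(r$accepted)
  expect_equal(r$reasons, "face_covered")
})

test_that("the 30% segment rule drops exactly the outliers", {
  # 25 * 800 ms with one 1100 ms inside the first segment:
  # segment mean 812, bound 0.3 * 812 = 243.6 -> 1100 > 1055.6 dropped
  ibis <- c(rep(800, 12), 1100, rep(800, 12))
  r <- clean_ground_truth(mk_series(ibis))
  expect_true(r$accepted)
  expect_equal(r$ibis_removed, 1)
  expect_equal(length(r$cleaned), 24)
  expect_false(1100 %in% r$cleaned$ibis_ms)
})

test_that("excessive SDNN or RMSSD after cleaning rejects the recording", {
  set.seed(61)
  wild <- 800 + rnorm(60, 0, 150)
  wild <- pmin(pmax(wild, 450), 1250)    # keep HR in range
  r <- clean_ground_truth(mk_series(wild))
  if (!r$accepted) {
    expect_true(any(c("sdnn_too_high", "rmssd_too_high") %in% r$reasons))
  } else {
    expect_lte(sdnn(r$cleaned), 100)
    expect_lte(rmssd(r$cleaned), 100)
  }
  # alternating extremes survive the segment rule but fail RMSSD
  alt <- rep(c(640, 960), 20)            # segment mean 800, +/-20%
  ra <- clean_ground_truth(mk_series(alt))
  expect_false(ra$accepted)
  expect_true("rmssd_too_high" %in% ra$reasons)
})

test_that("cleaning is deterministic and order-preserving", {
  ibis <- c(rep(820, 10), 1150, rep(790, 20))
  r1 <- clean_ground_truth(mk_series(ibis))
  r2 <- clean_ground_truth(mk_series(ibis))
  expect_identical(r1, r2)
  expect_true(!is.unsorted(r1$cleaned$beat_times_s))
})

test_that("agreement statistics reproduce the defining hand cases", {
  # perfect agreement
  p <- agreement_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$mae, 0)
  expect_equal(p$sd, 0)
  expect_equal(p$mean_diff, 0)
  # y = (1,2,3), yhat = (2,2,2): MAE 2/3, RMS difference sqrt(2/3)
  # (constant estimates leave r undefined, flagged elsewhere)
  h <- suppressWarnings(agreement_stats(estimates = c(2, 2, 2),
                                        truths = c(1, 2, 3)))
  expect_equal(h$mae, 2 / 3)
  expect_equal(h$sd, sqrt(2 / 3))
  # constant shift: perfect correlation, t-test flags the bias
  y <- c(10, 12, 14, 13, 11, 15)
  s <- agreement_stats(y + 5, y)
  expect_equal(s$r, 1)
  expect_equal(s$mean_diff, 5)
  expect_lt(s$p, 0.05)
})

test_that("the reported SD is the uncentred RMS of differences", {
  # regression pin: with a pure constant offset the centred SD of the
  # differences is 0 but the reported quantity is the offset itself
  y <- c(1, 2, 3, 4)
  s <- agreement_stats(y + 2, y)
  expect_equal(s$sd, 2)
  expect_equal(stats::sd((y + 2) - y), 0)
})

test_that("paired t statistic matches the mean-difference formula", {
  set.seed(62)
  a <- rnorm(12, 50, 8); b <- a + rnorm(12, 2, 3)
  s <- agreement_stats(b, a)
  d <- b - a
  expect_equal(s$t, mean(d) / (stats::sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
  expect_equal(s$p,
               2 * stats::pt(-abs(s$t), df = length(d) - 1),
               tolerance = 1e-12)
  expect_lte(s$loa_low, s$mean_diff)
  expect_gte(s$loa_high, s$mean_diff)
})

test_that("degenerate agreement inputs are flagged", {
  expect_warning(agreement_stats(c(1, 2, 3), c(1, 2, 4)), NA)
  expect_warning(z <- agreement_stats(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_true(is.na(z$r))
  expect_error(agreement_stats(1, 1:2), "equal-length")
})

test_that("batch agreement runs over a manifest of CSV pairs", {
  dir <- withr::local_tempdir()
  set.seed(63)
  ids <- c("a", "b", "c")
  for (i in seq_along(ids)) {
    rr <- 800 + cumsum(rnorm(60, 0, 8)) + rnorm(60, 0, 15)
    truth <- mk_series(rr)
    est <- mk_series(rr + rnorm(60, 0, 10))
    write_ibis_csv(truth, file.path(dir, paste0(ids[i], "_truth.csv")))
    write_ibis_csv(est, file.path(dir, paste0(ids[i], "_est.csv")))
  }
  manifest <- data.frame(
    id = ids,
    estimate_file = file.path(dir, paste0(ids, "_est.csv")),
    truth_file = file.path(dir, paste0(ids, "_truth.csv")),
    face_covered = c(FALSE, FALSE, TRUE))
  res <- batch_agreement(manifest)
  expect_length(res$records, 3)
  expect_false(res$records[[3]]$cleaning$accepted)
  expect_s3_class(res$agreement$sdnn, "agreement_stats")
  expect_equal(res$agreement$sdnn$n, 2)   # only the uncovered records
})
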