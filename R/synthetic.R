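# Synthetic PPG generator with known beat times. Every pipeline stage can be
# validated against exact ground truth without external recordings: beat
# intervals follow a controllable AR(1) model (optionally with sinusoidal
# respiratory modulation), each beat renders a fixed asymmetric pulse
# template, and baseline drift, white noise and injectable artifacts emulate
# the failure modes real recordings show.

#' Specification of a synthetic PPG recording
#'
#' @param mean_rr_ms target mean interval in ms (default 800, i.e. 75 bpm;
#'   valid-by-construction records stay within 400-1300 ms).
#' @param phi AR(1) coefficient of the interval model, `|phi| < 1`
#'   (default 0.8: neighbouring intervals are correlated, as in resting
#'   sinus rhythm).
#' @param sigma_ms innovation standard deviation in ms (default 25).
#' @param duration_s record length in seconds (default 120).
#' @param fs sampling rate in Hz, >= 16 (default 32, a typical camera-like
#'   power-of-two rate).
#' @param snr_db additive-white-noise level relative to the clean signal
#'   power (default 30; `Inf` disables noise).
#' @param drift_amp baseline drift amplitude relative to the unit pulse
#'   amplitude (default 0.2).
#' @param drift_hz drift frequency in Hz, below the heart-rate band
#'   (default 0.15).
#' @param rsa_depth_ms amplitude of a sinusoidal respiratory (RSA)
#'   modulation of the intervals in ms (default 0 = off).
#' @param rsa_hz respiratory frequency in Hz (default 0.25).
#' @param mean_rr_end_ms optional final mean interval: the target mean ramps
#'   linearly from `mean_rr_ms` to this value over the record, emulating a
#'   drifting heart rate.
#' @param seed integer RNG seed.
#' @return a validated list of class `synth_spec`.
#' @export
synth_spec <- function(mean_rr_ms = 800, phi = 0.8, sigma_ms = 25,
                       duration_s = 120, fs = 32, snr_db = 30,
                       drift_amp = 0.2, drift_hz = 0.15, rsa_depth_ms = 0,
                       rsa_hz = 0.25, mean_rr_end_ms = NULL, seed = 1) {
  if (!(mean_rr_ms >= 400 && mean_rr_ms <= 1300)) {
    stop_wavehrv("synth_spec: mean_rr_ms must lie in [400, 1300] ms")
  }
  if (!is.null(mean_rr_end_ms) &&
      !(mean_rr_end_ms >= 400 && mean_rr_end_ms <= 1300)) {
    stop_wavehrv("synth_spec: mean_rr_end_ms must lie in [400, 1300] ms")
  }
  if (!(abs(phi) < 1)) stop_wavehrv("synth_spec: need |phi| < 1")
  if (!(fs >= 16)) {
    stop_wavehrv("synth_spec: fs < 16 Hz cannot resolve the pulse template")
  }
  if (!(duration_s > 0) || !(sigma_ms >= 0)) {
    stop_wavehrv("synth_spec: invalid duration or sigma")
  }
  if (!(drift_hz < 0.3)) {
    stop_wavehrv("synth_spec: drift_hz must stay below 0.3 Hz")
  }
  structure(list(mean_rr_ms = mean_rr_ms, phi = phi, sigma_ms = sigma_ms,
                 duration_s = duration_s, fs = fs, snr_db = snr_db,
                 drift_amp = drift_amp, drift_hz = drift_hz,
                 rsa_depth_ms = rsa_depth_ms, rsa_hz = rsa_hz,
                 mean_rr_end_ms = mean_rr_end_ms, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a ground-truth IBI series
#'
#' Intervals follow `RR_n = mu_n + phi (RR_[n-1] - mu_[n-1]) + eps_n` with
#' `eps ~ N(0, sigma^2)` and an optional sinusoidal RSA term, truncated to
#' [400, 1300] ms; `mu_n` ramps linearly when `mean_rr_end_ms` is set. Beats
#' are generated until the record duration is exceeded. Reproducible given
#' the spec seed.
#'
#' @param spec a [synth_spec()].
#' @return an [ibi_series()]; the first beat is at time 0, so the series
#'   timestamps are the cumulative interval sums. A warning is raised when
#'   more than 20% of intervals hit the truncation bounds.
#' @export
generate_ibi_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    mu_at <- function(t) {
      if (is.null(spec$mean_rr_end_ms)) spec$mean_rr_ms
      else spec$mean_rr_ms +
        (spec$mean_rr_end_ms - spec$mean_rr_ms) *
          min(t / spec$duration_s, 1)
    }
    ibis <- numeric(0); times <- numeric(0)
    t <- 0; prev <- mu_at(0); prev_mu <- mu_at(0); truncated <- 0L
    while (t <= spec$duration_s) {
      mu <- mu_at(t)
      rr <- mu + spec$phi * (prev - prev_mu) + stats::rnorm(1, 0, spec$sigma_ms)
      if (spec$rsa_depth_ms > 0) {
        rr <- rr + spec$rsa_depth_ms * sin(2 * pi * spec$rsa_hz * t)
      }
      if (rr < 400 || rr > 1300) truncated <- truncated + 1L
      rr <- min(max(rr, 400), 1300)
      t <- t + rr / 1000
      ibis <- c(ibis, rr); times <- c(times, t)
      prev <- rr; prev_mu <- mu
    }
    if (truncated > 0.2 * length(ibis)) {
      warning(sprintf(
        "generate_ibi_series: %d of %d intervals truncated to [400, 1300] ms; distribution distorted",
        truncated, length(ibis)))
    }
    ibi_series(ibis, times)
  })
}

# Asymmetric pulse template: difference of two gamma-like lobes on the unit
# interval, v^3 exp(-v/0.10) for the fast systolic upstroke minus a smaller,
# later v^5 exp(-v/0.11) lobe (a dicrotic-wave-like undershoot). Normalized
# to unit peak; the argmax location is solved on a fine grid once so pulses
# can be placed with their maximum exactly at the beat time.
pulse_template <- function() {
  v <- seq(0, 1, by = 1e-4)
  lobe <- function(v, k, th) {
    y <- v^(k - 1) * exp(-v / th)
    y / max(y)
  }
  y <- lobe(v, 4, 0.10) - 0.35 * lobe(v, 6, 0.11)
  y <- y / max(y)
  list(v = v, y = y, v_peak = v[which.max(y)])
}

#' Render a synthetic PPG trace from an IBI series
#'
#' Places a fixed asymmetric pulse (fast systolic rise, slow decay; total
#' width 0.4 of the local interval) with its maximum exactly at each beat
#' time, then adds sinusoidal baseline drift of amplitude
#' `drift_amp * pulse amplitude` and white Gaussian noise scaled so that the
#' clean-signal-to-noise power ratio equals `snr_db`.
#'
#' @param ibis an [ibi_series()], e.g. from [generate_ibi_series()].
#' @param spec the [synth_spec()] carrying rendering parameters.
#' @return list with `signal` (a [sampled_signal()]), `beat_times`
#'   (ground-truth beat times inside the record, seconds), and `clean` (the
#'   noise-free signal, for SNR measurement).
#' @export
render_ppg <- function(ibis, spec) {
  stopifnot(inherits(ibis, "ibi_series"), inherits(spec, "synth_spec"))
  if (spec$fs < 16) stop_wavehrv("render_ppg: fs < 16 Hz rejected")
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  beats <- c(ibis$beat_times_s[1L] - ibis$ibis_ms[1L] / 1000,
             ibis$beat_times_s)
  tmpl <- pulse_template()
  clean <- numeric(n)
  kept <- numeric(0)
  for (b in seq_along(beats)) {
    tb <- beats[b]
    if (tb < 0 || tb > (n - 1) / fs) next
    rr_s <- if (b <= length(ibis$ibis_ms)) ibis$ibis_ms[b] / 1000
            else ibis$ibis_ms[length(ibis$ibis_ms)] / 1000
    width <- 0.4 * rr_s
    t_lo <- tb - tmpl$v_peak * width
    t_hi <- tb + (1 - tmpl$v_peak) * width
    i_lo <- max(1L, floor(t_lo * fs) + 1L)
    i_hi <- min(n, ceiling(t_hi * fs) + 1L)
    if (i_hi <= i_lo) next
    ts <- (seq(i_lo, i_hi) - 1L) / fs
    v <- (ts - t_lo) / width
    inside <- v >= 0 & v <= 1
    add <- numeric(length(ts))
    add[inside] <- stats::approx(tmpl$v, tmpl$y, xout = v[inside])$y
    clean[i_lo:i_hi] <- clean[i_lo:i_hi] + add
    kept <- c(kept, tb)
  }
  tt <- (seq_len(n) - 1L) / fs
  clean <- clean + spec$drift_amp * sin(2 * pi * spec$drift_hz * tt)
  noisy <- if (is.finite(spec$snr_db)) {
    sigma <- stats::sd(clean) * 10^(-spec$snr_db / 20)
    with_seed(spec$seed + 1L, clean + stats::rnorm(n, 0, sigma))
  } else {
    clean
  }
  list(signal = sampled_signal(noisy, fs = fs),
       beat_times = kept,
       clean = sampled_signal(clean, fs = fs))
}

#' Inject artifacts into a signal or IBI series
#'
#' Deterministically (under `seed`) corrupts a copy of the input, logging
#' every corruption, so the ground-truth cleaner can be tested against known
#' failure modes: `flatline` (sensor dropout: a segment held at its first
#' value), `spike` (amplitude transients added at random samples), or
#' `outlier_ibi` (intervals multiplied by a factor, emulating missed or
#' false beats; beat times are re-accumulated).
#'
#' @param x a [sampled_signal()] (`flatline`, `spike`) or [ibi_series()]
#'   (`outlier_ibi`).
#' @param kind one of `"flatline"`, `"spike"`, `"outlier_ibi"`.
#' @param params list of parameters: `duration_s` (flatline length),
#'   `n` (spike count), `amp` (spike amplitude), `factor` (IBI multiplier,
#'   default 1.6), `n_outliers` (default 1).
#' @param seed integer RNG seed (default 1).
#' @return list with `x` (the corrupted copy) and `log` (a data frame
#'   describing each injected artifact).
#' @export
inject_artifacts <- function(x, kind = c("flatline", "spike", "outlier_ibi"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "flatline") {
      stopifnot(inherits(x, "sampled_signal"))
      dur <- params$duration_s %||% 5
      n <- length(x$values)
      len <- round(dur * x$fs)
      if (len >= n) stop_wavehrv("inject_artifacts: flatline longer than record")
      start <- sample.int(n - len, 1L)
      x$values[start:(start + len - 1L)] <- x$values[start]
      log <- data.frame(kind = "flatline",
                        t_start = (start - 1L) / x$fs,
                        t_end = (start + len - 2L) / x$fs)
    } else if (kind == "spike") {
      stopifnot(inherits(x, "sampled_signal"))
      k <- params$n %||% 3
      amp <- params$amp %||% (10 * stats::sd(x$values))
      pos <- sort(sample.int(length(x$values), k))
      x$values[pos] <- x$values[pos] + amp
      log <- data.frame(kind = "spike", t_start = (pos - 1L) / x$fs,
                        t_end = (pos - 1L) / x$fs)
    } else {
      stopifnot(inherits(x, "ibi_series"))
      k <- params$n_outliers %||% 1
      factor <- params$factor %||% 1.6
      if (length(x$ibis_ms) < k) {
        stop_wavehrv("inject_artifacts: more outliers than intervals")
      }
      pos <- sort(sample.int(length(x$ibis_ms), k))
      ibis <- x$ibis_ms
      ibis[pos] <- ibis[pos] * factor
      t0 <- x$beat_times_s[1L] - x$ibis_ms[1L] / 1000
      x <- ibi_series(ibis, t0 + cumsum(ibis) / 1000)
      log <- data.frame(kind = "outlier_ibi", index = pos, factor = factor)
    }
    list(x = x, log = log)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
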