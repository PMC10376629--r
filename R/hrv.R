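# Time- and frequency-domain HRV metrics from a refined IBI series.

as_ibi_vector <- function(series) {
  if (inherits(series, "ibi_series")) series$ibis_ms else as.numeric(series)
}

#' SDNN: standard deviation of NN intervals
#'
#' Sample standard deviation (N - 1 denominator) of the intervals, in ms.
#' An overall-variability marker; short-term (< 5 min) resting values are
#' typically 32-93 ms.
#'
#' @param series an [ibi_series()] or numeric vector of intervals in ms.
#' @return SDNN in ms, or `NA` with a warning for fewer than 2 intervals.
#' @examples
#' sdnn(c(700, 800, 900))  # 100
#' @export
sdnn <- function(series) {
  x <- as_ibi_vector(series)
  if (length(x) < 2L) {
    warning("sdnn: fewer than 2 intervals; undefined")
    return(NA_real_)
  }
  stats::sd(x)
}

#' RMSSD: root mean square of successive differences
#'
#' `sqrt(mean(diff^2))` over the N - 1 successive interval differences, in
#' ms. A parasympathetic marker; short-term resting values are typically
#' 19-75 ms.
#'
#' @inheritParams sdnn
#' @return RMSSD in ms, or `NA` with a warning for fewer than 2 intervals.
#' @examples
#' rmssd(c(700, 800, 900))  # 100
#' @export
rmssd <- function(series) {
  x <- as_ibi_vector(series)
  if (length(x) < 2L) {
    warning("rmssd: fewer than 2 intervals; undefined")
    return(NA_real_)
  }
  d <- diff(x)
  sqrt(sum(d^2) / length(d))
}

#' Baevsky stress index
#'
#' `SI = AMo / (2 * Mo * MxDMn)` from the IBI histogram: `Mo` is the mode
#' (centre of the tallest histogram bin, in seconds), `AMo` the mode
#' amplitude (percentage of intervals falling in that bin), and `MxDMn` the
#' interval range in seconds. Bins have fixed width `bin_ms` with centres at
#' integer multiples of `bin_ms` (the clinical convention, so modes land on
#' round values such as 0.80 s). Under these conventions resting values lie
#' roughly in 50-1500, rising with stress.
#'
#' @inheritParams sdnn
#' @param bin_ms histogram bin width in ms (default 50).
#' @return the dimensionless index, or `NA` with a warning when fewer than
#'   10 intervals are available or the interval range is zero.
#' @export
baevsky_si <- function(series, bin_ms = 50) {
  x <- as_ibi_vector(series)
  if (length(x) < 10L) {
    warning("baevsky_si: fewer than 10 intervals; undefined")
    return(NA_real_)
  }
  mxdmn_s <- (max(x) - min(x)) / 1000
  if (mxdmn_s <= 0) {
    warning("baevsky_si: zero interval range (MxDMn = 0); undefined")
    return(NA_real_)
  }
  bins <- round(x / bin_ms)            # bin centres at k * bin_ms
  counts <- table(bins)
  top <- counts[which.max(counts)]
  mo_s <- as.numeric(names(top)) * bin_ms / 1000
  amo_pct <- 100 * as.numeric(top) / length(x)
  amo_pct / (2 * mo_s * mxdmn_s)
}

#' LF/HF ratio from the interval tachogram
#'
#' Interpolates the tachogram (interval vs beat time) onto a uniform grid by
#' cubic spline, removes a linear trend, and integrates the FFT periodogram
#' over the low-frequency (0.04-0.15 Hz, sympathetic) and high-frequency
#' (0.15-0.4 Hz, parasympathetic) bands. Requires at least 30 s of beats for
#' meaningful low-frequency resolution.
#'
#' @param series an [ibi_series()] spanning >= 30 s.
#' @param resample_hz uniform tachogram rate in Hz (default 4, standard HRV
#'   practice).
#' @param lf_band,hf_band integration bands in Hz.
#' @return LF power / HF power (dimensionless); `NA` with a warning when HF
#'   power is numerically zero.
#' @export
lf_hf <- function(series, resample_hz = 4, lf_band = c(0.04, 0.15),
                  hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(series, "ibi_series"))
  if (length(series) < 4L) {
    stop_wavehrv("lf_hf: need at least 4 intervals")
  }
  span <- diff(range(series$beat_times_s))
  if (span < 30) {
    stop_wavehrv(sprintf(
      "lf_hf: record spans %.1f s; at least 30 s of beats are required", span))
  }
  grid <- seq(series$beat_times_s[1L],
              series$beat_times_s[length(series$beat_times_s)],
              by = 1 / resample_hz)
  tach <- stats::spline(series$beat_times_s, series$ibis_ms,
                        xout = grid, method = "fmm")$y
  tach <- stats::lm.fit(cbind(1, grid), tach)$residuals
  n <- length(tach)
  p <- Mod(stats::fft(tach))^2 / n
  freqs <- (seq_len(n) - 1L) * resample_hz / n
  lf <- sum(p[freqs >= lf_band[1L] & freqs < lf_band[2L]])
  hf <- sum(p[freqs >= hf_band[1L] & freqs <= hf_band[2L]])
  if (hf <= .Machine$double.eps * sum(p)) {
    warning("lf_hf: high-frequency power is numerically zero; undefined")
    return(NA_real_)
  }
  lf / hf
}

#' Assemble an HRV report from a refined IBI series
#'
#' @param series the refined [ibi_series()].
#' @param n_dropped number of intervals removed during refinement.
#' @param baevsky_bin_ms histogram bin for [baevsky_si()].
#' @param tachogram_hz resampling rate for [lf_hf()].
#' @param unreliable logical flag propagated from refinement.
#' @return an object of class `hrv_report`: `sdnn_ms`, `rmssd_ms`,
#'   `baevsky_si`, `lf_hf` (NA when the record is shorter than 30 s),
#'   `mean_hr_bpm`, `n_ibis_used`, `n_ibis_dropped`, `unreliable`.
#' @export
hrv_report <- function(series, n_dropped = 0L, baevsky_bin_ms = 50,
                       tachogram_hz = 4, unreliable = FALSE) {
  stopifnot(inherits(series, "ibi_series"))
  n <- length(series)
  lfhf <- NA_real_
  if (n >= 4L && diff(range(series$beat_times_s)) >= 30) {
    lfhf <- suppressWarnings(lf_hf(series, resample_hz = tachogram_hz))
  }
  structure(list(
    sdnn_ms = if (n >= 2L) sdnn(series) else NA_real_,
    rmssd_ms = if (n >= 2L) rmssd(series) else NA_real_,
    baevsky_si = if (n >= 10L) suppressWarnings(baevsky_si(series, baevsky_bin_ms))
                 else NA_real_,
    lf_hf = lfhf,
    mean_hr_bpm = if (n >= 1L) 60000 / mean(series$ibis_ms) else NA_real_,
    n_ibis_used = n,
    n_ibis_dropped = as.integer(n_dropped),
    unreliable = isTRUE(unreliable)
  ), class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat("<hrv_report>\n")
  cat(sprintf("  SDNN       %8.2f ms\n", x$sdnn_ms))
  cat(sprintf("  RMSSD      %8.2f ms\n", x$rmssd_ms))
  cat(sprintf("  Baevsky SI %8.2f\n", x$baevsky_si))
  cat(sprintf("  LF/HF      %8.3f\n", x$lf_hf))
  cat(sprintf("  mean HR    %8.2f bpm\n", x$mean_hr_bpm))
  cat(sprintf("  intervals  %d used, %d dropped%s\n", x$n_ibis_used,
              x$n_ibis_dropped, if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}
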