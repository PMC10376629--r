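# First-order wavelet scattering: Morlet filter bank, modulus, average
# pooling. The first-order coefficients are a pooled scalogram -- the energy
# density of the signal across frequency and (coarse) time -- and drive the
# adaptive band selection downstream.

# Map arbitrary integer indices onto 1..n by reflection at both boundaries
# (period 2n - 2), used to pad signals before convolution so that record
# edges do not ring.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  m <- (idx - 1L) %% (2L * n - 2L)
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

reflect_pad <- function(x, p) {
  n <- length(x)
  x[reflect_index(seq.int(1L - p, n + p), n)]
}

#' Build a Morlet wavelet filter bank
#'
#' Constructs log-spaced complex Morlet wavelets
#' `psi(t) = K pi^(-1/4) exp(i omega0 t/s) exp(-(t/s)^2/2)` whose centre
#' frequencies cover a target band geometrically, each L2-normalized. The
#' dimensionless frequency `omega0` is chosen so that adjacent filters cross
#' at approximately -3 dB, i.e. `omega0 = sqrt(ln 2) (r + 1)/(r - 1)` for the
#' geometric spacing ratio `r`.
#'
#' @param fs sampling rate in Hz; must exceed `2 * fmax`.
#' @param n_in_band number of wavelets with centres inside `[fmin, fmax]`
#'   (default 20).
#' @param pooling_seconds averaging window of the pooling low-pass (default
#'   16 s): sets the pooled frame spacing of the transform.
#' @param fmin,fmax band covered by the centre frequencies in Hz (default
#'   0.7-5 Hz, the plausible heart-rate band).
#' @param bandwidth_factor multiplier on `omega0`; > 1 narrows each filter,
#'   < 1 widens it (default 1, the -3 dB-crossing design).
#' @return an object of class `morlet_filterbank`: a list of wavelets (centre
#'   frequency, complex time-domain taps) plus `fs`, `pooling_seconds`,
#'   `omega0`.
#' @examples
#' bank <- build_filterbank(32)
#' range(filterbank_centers(bank))  # 0.7 .. 5
#' @export
build_filterbank <- function(fs, n_in_band = 20, pooling_seconds = 16,
                             fmin = 0.7, fmax = 5, bandwidth_factor = 1) {
  if (!(fs > 2 * fmax)) {
    stop_wavehrv("build_filterbank: fs must exceed 2*fmax (Nyquist)")
  }
  if (!(n_in_band >= 2)) stop_wavehrv("build_filterbank: n_in_band must be >= 2")
  if (!(fmin > 0 && fmin < fmax)) {
    stop_wavehrv("build_filterbank: need 0 < fmin < fmax")
  }
  if (!(pooling_seconds > 0)) {
    stop_wavehrv("build_filterbank: pooling_seconds must be > 0")
  }
  centers <- exp(seq(log(fmin), log(fmax), length.out = n_in_band))
  r <- (fmax / fmin)^(1 / (n_in_band - 1))
  omega0 <- sqrt(log(2)) * (r + 1) / (r - 1) * bandwidth_factor
  wavelets <- lapply(centers, function(fc) {
    s <- omega0 / (2 * pi * fc)          # time scale in seconds
    m <- ceiling(6.5 * s * fs)           # Gaussian < 1e-9 beyond the support
    u <- ((-m):m) / (fs * s)
    taps <- pi^(-1 / 4) * exp(1i * omega0 * u) * exp(-u^2 / 2)
    taps <- taps / sqrt(sum(Mod(taps)^2))
    list(center = fc, taps = taps)
  })
  structure(list(wavelets = wavelets, fs = fs,
                 pooling_seconds = pooling_seconds, omega0 = omega0,
                 fmin = fmin, fmax = fmax),
            class = "morlet_filterbank")
}

#' Centre frequencies of a filter bank
#'
#' @param bank a [build_filterbank()] object.
#' @return numeric vector of centre frequencies in Hz, increasing.
#' @export
filterbank_centers <- function(bank) {
  stopifnot(inherits(bank, "morlet_filterbank"))
  vapply(bank$wavelets, `[[`, numeric(1), "center")
}

#' @export
print.morlet_filterbank <- function(x, ...) {
  fc <- filterbank_centers(x)
  cat(sprintf(
    "<morlet_filterbank> %d wavelets, %.3g-%.3g Hz (log-spaced), fs = %g Hz, pooling %g s\n",
    length(fc), min(fc), max(fc), x$fs, x$pooling_seconds))
  invisible(x)
}

#' First-order scattering coefficients
#'
#' Convolves the signal with every wavelet of the bank, takes the complex
#' modulus, and averages over non-overlapping pooling frames:
#' `S[lambda, i] = mean over frame i of |(x * psi_lambda)(t)|`. Convolutions
#' are computed by FFT on a reflection-padded copy of the signal so record
#' edges do not produce wrap-around transients; a trailing partial frame is
#' dropped.
#'
#' @param sig a [sampled_signal()] at the bank's rate, at least one pooling
#'   window long.
#' @param bank a [build_filterbank()] object.
#' @return an object of class `scattering_coeffs`: non-negative matrix `S`
#'   (wavelet x pooled frame), `frame_times` (frame centres, seconds),
#'   `center_frequencies` (Hz), `pooling_seconds`, `fs`.
#' @export
scatter_first_order <- function(sig, bank) {
  stopifnot(inherits(sig, "sampled_signal"),
            inherits(bank, "morlet_filterbank"))
  if (sig$fs != bank$fs) {
    stop_wavehrv(sprintf(
      "scatter_first_order: signal rate (%g Hz) does not match bank rate (%g Hz)",
      sig$fs, bank$fs))
  }
  n <- length(sig$values)
  lp <- round(bank$pooling_seconds * sig$fs)
  n_frames <- floor(n / lp)
  if (n_frames < 1L) {
    stop_wavehrv(sprintf(
      "scatter_first_order: signal (%.1f s) shorter than one pooling window (%g s)",
      signal_duration(sig), bank$pooling_seconds))
  }
  S <- matrix(0, nrow = length(bank$wavelets), ncol = n_frames)
  for (w in seq_along(bank$wavelets)) {
    taps <- bank$wavelets[[w]]$taps
    m <- (length(taps) - 1L) %/% 2L
    xe <- reflect_pad(sig$values, m)
    nf <- stats::nextn(length(xe) + length(taps) - 1L, 2)
    conv <- stats::fft(stats::fft(c(xe, rep(0, nf - length(xe)))) *
                       stats::fft(c(taps, rep(0, nf - length(taps)))),
                       inverse = TRUE) / nf
    env <- Mod(conv[(2L * m + 1L):(2L * m + n)])
    frames <- matrix(env[seq_len(n_frames * lp)], nrow = lp)
    S[w, ] <- colMeans(frames)
  }
  structure(list(
    S = S,
    frame_times = sig$t0 + (seq_len(n_frames) - 0.5) * lp / sig$fs,
    center_frequencies = filterbank_centers(bank),
    pooling_seconds = lp / sig$fs,
    fs = sig$fs
  ), class = "scattering_coeffs")
}

#' @export
print.scattering_coeffs <- function(x, ...) {
  cat(sprintf(
    "<scattering_coeffs> %d wavelets x %d frames (pooling %g s, %.3g-%.3g Hz)\n",
    nrow(x$S), ncol(x$S), x$pooling_seconds,
    min(x$center_frequencies), max(x$center_frequencies)))
  invisible(x)
}

#' Write scattering coefficients to CSV
#'
#' One row per wavelet (first column its centre frequency), one column per
#' pooled frame, suitable for plotting scalogram-style heatmaps.
#'
#' @param coeffs a [scatter_first_order()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scattering_csv <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "scattering_coeffs"))
  df <- data.frame(center_hz = coeffs$center_frequencies, coeffs$S)
  names(df)[-1L] <- sprintf("t%.1fs", coeffs$frame_times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
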