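# Butterworth band-pass filtering in second-order sections.
#
# The pipeline filters at design order 7 with pass-bands as narrow as a
# fraction of a percent of the sampling rate (e.g. 0.7-5 Hz at 256 Hz), where
# a single transfer-function polynomial of degree 14 is numerically unstable
# (its poles cluster near z = 1 and round-off pushes them outside the unit
# circle). The filter is therefore designed analytically -- Butterworth
# prototype poles, band-pass transformation, bilinear transform -- and applied
# as a cascade of biquads, which is well conditioned at any rate used here.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' @param order design order of the low-pass prototype (the band-pass filter
#'   has twice this order).
#' @param low,high pass-band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return a list of class `butter_sos` with one `(b, a)` biquad per entry
#'   and the design parameters as attributes.
#' @keywords internal
#' @export
butter_sos <- function(order, low, high, fs) {
  if (!(order >= 1)) stop_wavehrv("butter_sos: order must be >= 1")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_wavehrv(sprintf(
      "butter_sos: band edges must satisfy 0 < low < high < fs/2 (got [%g, %g] Hz at fs = %g Hz)",
      low, high, fs))
  }
  n <- as.integer(order)
  # pre-warped analog edges for the bilinear transform
  wl <- 2 * fs * tan(pi * low / fs)
  wh <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # band-pass transformation s -> (s^2 + w0^2) / (bw * s):
  # each prototype pole p yields the two roots of s^2 - p*bw*s + w0^2
  pb <- proto * bw
  disc <- sqrt(pb^2 - 4 * w0^2)
  s_poles <- c((pb + disc) / 2, (pb - disc) / 2)
  # bilinear transform to the z-plane
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  # group conjugate pairs into real-coefficient biquads; each section gets
  # one zero at z = 1 and one at z = -1 (the transformed s = 0 and s = Inf
  # zeros of the band-pass filter)
  tol <- 1e-9
  re_p <- z_poles[abs(Im(z_poles)) <= tol * Mod(z_poles)]
  cx_p <- z_poles[Im(z_poles) > tol * Mod(z_poles)]
  sections <- list()
  for (p in cx_p) {
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2))
  }
  if (length(re_p) %% 2L != 0L) {
    stop_wavehrv("butter_sos: internal error, unpaired real pole")
  }
  re_p <- sort(Re(re_p))
  while (length(re_p) >= 2L) {
    p1 <- re_p[1L]; p2 <- re_p[length(re_p)]  # pair extremes for balance
    re_p <- re_p[-c(1L, length(re_p))]
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 0, -1), a = c(1, -(p1 + p2), p1 * p2))
  }
  # unit gain at the (warped-back) geometric centre frequency
  fc <- atan(w0 / (2 * fs)) * fs / pi
  zc <- exp(2i * pi * fc / fs)
  h <- vapply(sections, function(s) {
    num <- s$b[1] + s$b[2] / zc + s$b[3] / zc^2
    den <- s$a[1] + s$a[2] / zc + s$a[3] / zc^2
    Mod(num / den)
  }, numeric(1))
  g <- (1 / prod(h))^(1 / length(sections))
  sections <- lapply(sections, function(s) { s$b <- s$b * g; s })
  structure(sections, class = "butter_sos",
            order = n, low = low, high = high, fs = fs)
}

# One biquad, zero initial conditions; MA part vectorized, AR part via the
# C-level recursive filter in stats.
apply_biquad <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  if (n >= 2L) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1L)]
  if (n >= 3L) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2L)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Forward-backward application (squares the magnitude response, cancels the
#' phase) with odd-reflection padding at both ends to suppress edge
#' transients.
#'
#' @param sos a [butter_sos()] design.
#' @param x numeric vector.
#' @param padlen reflection pad length in samples; defaults to twelve periods
#'   of the low band edge (enough for the order-7 step transient to settle
#'   below 1e-6), capped at `length(x) - 1`.
#' @return filtered vector, same length as `x`.
#' @keywords internal
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  stopifnot(inherits(sos, "butter_sos"))
  n <- length(x)
  if (is.null(padlen)) {
    padlen <- ceiling(12 * attr(sos, "fs") / attr(sos, "low"))
  }
  padlen <- min(padlen, n - 1L)
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  for (s in sos) xe <- apply_biquad(xe, s$b, s$a)
  xe <- rev(xe)
  for (s in sos) xe <- apply_biquad(xe, s$b, s$a)
  xe <- rev(xe)
  if (padlen > 0L) xe <- xe[(padlen + 1L):(padlen + n)]
  xe
}

#' Band-pass filter a sampled signal (zero-phase Butterworth)
#'
#' Pre-cleaning step of the pipeline: an order-7 Butterworth band-pass over
#' the plausible heart-rate band 0.7-5 Hz, applied forward-backward so that
#' peak positions are not shifted in time. The stated order is the design
#' order of the one-pass filter.
#'
#' @param sig a [sampled_signal()].
#' @param band numeric length-2, pass-band `[low, high]` in Hz.
#' @param order filter design order (default 7).
#' @return a [sampled_signal()] of identical length and rate.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1.2 * (0:959) / 32) + 1, fs = 32)
#' f <- butter_bandpass(s)   # DC removed, 1.2 Hz retained
#' @export
butter_bandpass <- function(sig, band = c(0.7, 5), order = 7) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (length(band) != 2L || !(band[1] > 0 && band[1] < band[2])) {
    stop_wavehrv("butter_bandpass: 'band' must be increasing positive [low, high]")
  }
  if (band[2] >= sig$fs / 2) {
    stop_wavehrv(sprintf(
      "butter_bandpass: high edge %g Hz is at or above Nyquist (%g Hz)",
      band[2], sig$fs / 2))
  }
  sos <- butter_sos(order, band[1], band[2], sig$fs)
  sampled_signal(sos_filtfilt(sos, sig$values), fs = sig$fs, t0 = sig$t0)
}
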