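#' Uniformly sampled one-dimensional signal
#'
#' The basic container of the package: a finite, non-empty numeric trace
#' sampled at a fixed rate, such as a contact PPG signal or an rPPG pulse
#' candidate.
#'
#' @param values numeric vector of sample values (arbitrary amplitude units).
#' @param fs sampling rate in Hz, > 0.
#' @param t0 start time in seconds (default 0).
#' @return an object of class `sampled_signal` with fields `values`, `fs`,
#'   `t0`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1.2 * (0:255) / 32), fs = 32)
#' signal_duration(s)
#' @export
sampled_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_wavehrv("sampled_signal: 'values' must be non-empty")
  }
  if (!all(is.finite(values))) {
    stop_wavehrv("sampled_signal: all sample values must be finite ",
                 "(found NA/NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_wavehrv("sampled_signal: 'fs' must be a single positive number")
  }
  structure(list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
              length(x$values), x$fs, signal_duration(x), x$t0))
  invisible(x)
}

#' Duration of a sampled signal in seconds
#'
#' @param sig a [sampled_signal()].
#' @return length(values) / fs, in seconds.
#' @export
signal_duration <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  length(sig$values) / sig$fs
}

#' Sample times of a sampled signal
#'
#' @param sig a [sampled_signal()].
#' @return numeric vector `t0 + (0:(n-1))/fs`.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  sig$t0 + (seq_along(sig$values) - 1L) / sig$fs
}

#' Per-frame mean RGB trace
#'
#' Holds the spatial means of the three colour channels over time, the input
#' to the plane-orthogonal-to-skin (POS) projection.
#'
#' @param r,g,b equal-length numeric vectors of per-frame channel means
#'   (non-negative).
#' @param fs frame rate in Hz.
#' @return an object of class `rgb_trace`.
#' @export
rgb_trace <- function(r, g, b, fs) {
  r <- as.numeric(r); g <- as.numeric(g); b <- as.numeric(b)
  n <- length(r)
  if (n < 2L || length(g) != n || length(b) != n) {
    stop_wavehrv("rgb_trace: r, g, b must have equal length >= 2")
  }
  if (!all(is.finite(c(r, g, b))) || any(c(r, g, b) < 0)) {
    stop_wavehrv("rgb_trace: channel means must be finite and non-negative")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_wavehrv("rgb_trace: 'fs' must be a single positive number")
  }
  structure(list(r = r, g = g, b = b, fs = as.numeric(fs)),
            class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d frames @ %g Hz (%.2f s)\n",
              length(x$r), x$fs, length(x$r) / x$fs))
  invisible(x)
}

#' Resample a signal to the nearest power-of-two rate
#'
#' Interpolates the trace onto a uniform grid at the power-of-two rate
#' closest to the original sampling rate (ties resolved upward), using cubic
#' spline interpolation. Power-of-two rates simplify the dyadic structure of
#' the scattering transform and keep samples equally spaced in time.
#'
#' @param sig a [sampled_signal()] with at least 2 samples.
#' @return a [sampled_signal()] at the new rate; duration is preserved to
#'   within one output sample. Signals already at a power-of-two rate are
#'   returned interpolated at their own rate (values unchanged at the knots).
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1.2 * (0:299) / 30), fs = 30)
#' resample_to_pow2(s)$fs  # 32
#' @export
resample_to_pow2 <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  n <- length(sig$values)
  if (n < 2L) stop_wavehrv("resample_to_pow2: need at least 2 samples")
  fs2 <- nearest_pow2(sig$fs)
  t_rel <- (seq_len(n) - 1L) / sig$fs
  # last output sample must not extrapolate beyond the original record
  m <- floor(t_rel[n] * fs2 * (1 + 1e-12)) + 1L
  xout <- (seq_len(m) - 1L) / fs2
  vals <- stats::spline(t_rel, sig$values, xout = xout, method = "fmm")$y
  sampled_signal(vals, fs = fs2, t0 = sig$t0)
}

#' Plane-orthogonal-to-skin (POS) pulse extraction
#'
#' Projects a mean-RGB trace onto the plane orthogonal to the standardized
#' skin-tone axis to obtain an rPPG pulse candidate. Within each sliding
#' window the channels are temporally normalized by their window means,
#' projected onto the axes (0, 1, -1) and (-2, 1, 1), combined with the
#' sigma-ratio tuning, mean-centred, and overlap-added.
#'
#' @param trace an [rgb_trace()].
#' @param win_seconds sliding-window length in seconds (default 1.6 s, the
#'   standard POS choice; the dominant pulse frequency is insensitive to
#'   values in roughly 1-2 s).
#' @return a [sampled_signal()] at the trace's frame rate.
#' @export
pos_rppg <- function(trace, win_seconds = 1.6) {
  stopifnot(inherits(trace, "rgb_trace"))
  n <- length(trace$r)
  l <- round(win_seconds * trace$fs)
  if (l < 2L || n < l) {
    stop_wavehrv("pos_rppg: trace shorter than one POS window (",
                 win_seconds, " s)")
  }
  h <- numeric(n)
  C <- rbind(trace$r, trace$g, trace$b)
  for (start in seq_len(n - l + 1L)) {
    idx <- start:(start + l - 1L)
    mu <- rowMeans(C[, idx, drop = FALSE])
    if (any(mu == 0)) {
      stop_wavehrv("pos_rppg: zero channel mean in window starting at frame ",
                   start, "; normalization undefined")
    }
    Cn <- C[, idx, drop = FALSE] / mu
    s1 <- Cn[2L, ] - Cn[3L, ]
    s2 <- -2 * Cn[1L, ] + Cn[2L, ] + Cn[3L, ]
    sd2 <- stats::sd(s2)
    alpha <- if (sd2 > 0) stats::sd(s1) / sd2 else 0
    p <- s1 + alpha * s2
    h[idx] <- h[idx] + (p - mean(p))
  }
  sampled_signal(h, fs = trace$fs)
}

#' Read a pulse or RGB trace from CSV
#'
#' Accepts either a `t,value` file (pulse trace) or a `t,R,G,B` file
#' (per-frame channel means). The sampling rate is inferred from the median
#' spacing of `t` unless given.
#'
#' @param path CSV file path.
#' @param fs optional sampling rate in Hz; overrides the rate inferred from
#'   the time column.
#' @return a [sampled_signal()] or [rgb_trace()] depending on the header.
#' @export
read_trace_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  if (is.null(fs)) {
    if (!"t" %in% nm) {
      stop_wavehrv("read_trace_csv: no 't' column and no 'fs' given")
    }
    dt <- stats::median(diff(df[[which(nm == "t")[1L]]]))
    if (!is.finite(dt) || dt <= 0) {
      stop_wavehrv("read_trace_csv: cannot infer sampling rate from 't'")
    }
    fs <- 1 / dt
  }
  if (all(c("r", "g", "b") %in% nm)) {
    rgb_trace(df[[which(nm == "r")[1L]]], df[[which(nm == "g")[1L]]],
              df[[which(nm == "b")[1L]]], fs = fs)
  } else if ("value" %in% nm) {
    t0 <- if ("t" %in% nm) df[[which(nm == "t")[1L]]][1L] else 0
    sampled_signal(df[[which(nm == "value")[1L]]], fs = fs, t0 = t0)
  } else {
    stop_wavehrv("read_trace_csv: expected columns t,value or t,R,G,B")
  }
}

#' Write a pulse trace to CSV
#'
#' @param sig a [sampled_signal()].
#' @param path output file path; columns `t,value`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sig, path) {
  stopifnot(inherits(sig, "sampled_signal"))
  utils::write.csv(data.frame(t = signal_times(sig), value = sig$values),
                   path, row.names = FALSE)
  invisible(path)
}
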