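# Sliding-window adaptive narrow-band filtering. For each window the
# scattering energies (linearly interpolated to the window end) are clustered
# with K-means over (frequency, energy); the span of the outer cluster
# centroids defines a narrow pass-band around the momentary heart rate. Each
# window is band-passed, mean-centred, and the windows are overlap-added;
# the record edges, covered by fewer windows, are re-amplified.

#' Sliding-window plan
#'
#' Windows of length `w` start every `s` seconds; the final window is clipped
#' to the signal end. A clipped final window shorter than `min_seconds` is
#' merged into the previous window (too few samples to filter stably).
#'
#' @param duration_s signal duration in seconds.
#' @param fs sampling rate in Hz.
#' @param window_seconds,step_seconds window and step sizes in seconds
#'   (defaults 14.5 s and 2 s).
#' @param min_seconds minimum final-window length before merging (default 1 s).
#' @return an object of class `window_plan`: a data frame of window
#'   start/end times and sample indices, with `w`, `s`, `fs`, `n_samples`
#'   attributes.
#' @export
window_plan <- function(duration_s, fs, window_seconds = 14.5,
                        step_seconds = 2, min_seconds = 1) {
  w <- window_seconds; s <- step_seconds
  if (!(s > 0 && s <= w)) {
    stop_wavehrv("window_plan: need 0 < step_seconds <= window_seconds")
  }
  n <- round(duration_s * fs)
  if (n < 2L) stop_wavehrv("window_plan: signal too short")
  dur <- n / fs
  j_max <- if (dur <= w) 0L else as.integer(ceiling((dur - w) / s - 1e-9))
  starts <- (0:j_max) * s
  ends <- pmin(starts + w, dur)
  # merge a too-short clipped final window into the previous one
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)]) < min_seconds) {
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
    ends[length(ends)] <- dur
  }
  start_i <- round(starts * fs) + 1L
  end_i <- pmin(round(ends * fs), n)
  df <- data.frame(window = seq_along(starts), start_s = starts, end_s = ends,
                   start_i = start_i, end_i = end_i)
  structure(df, class = c("window_plan", "data.frame"),
            w = w, s = s, fs = fs, n_samples = n)
}

#' Interpolate scattering energies to a window end
#'
#' Pooled frames are `pooling_seconds` apart; the per-wavelet energy at an
#' arbitrary time is the linear interpolation between the two bracketing
#' frames: `E = ((D - x)/D) E_[i-1] + (x/D) E_i` with `D` the pooling spacing
#' and `x` the offset of the window end past frame `i-1`. Times outside the
#' frame range are clamped; a single-frame record falls back to that frame's
#' energies.
#'
#' @param coeffs a [scatter_first_order()] result.
#' @param window_end time in seconds (typically the right end of a sliding
#'   window).
#' @param fmin,fmax restrict to wavelets with centres inside this band
#'   (default 0.7-5 Hz).
#' @return list with `freqs` (Hz) and `energies` (same units as the
#'   coefficients) for the in-band wavelets.
#' @export
interp_window_energy <- function(coeffs, window_end, fmin = 0.7, fmax = 5) {
  stopifnot(inherits(coeffs, "scattering_coeffs"))
  in_band <- coeffs$center_frequencies >= fmin - 1e-12 &
    coeffs$center_frequencies <= fmax + 1e-12
  if (!any(in_band)) {
    stop_wavehrv("interp_window_energy: no wavelet centres inside the band")
  }
  ft <- coeffs$frame_times
  S <- coeffs$S[in_band, , drop = FALSE]
  if (length(ft) < 2L) {
    e <- S[, 1L]
  } else {
    we <- min(max(window_end, ft[1L]), ft[length(ft)])
    i <- min(max(findInterval(we, ft), 1L), length(ft) - 1L)
    delta <- ft[i + 1L] - ft[i]
    x <- we - ft[i]
    e <- ((delta - x) / delta) * S[, i] + (x / delta) * S[, i + 1L]
  }
  list(freqs = coeffs$center_frequencies[in_band], energies = as.numeric(e))
}

# k-means++ seeding: first centre uniform, later centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Estimate a narrow heart-rate band from scattering energies
#'
#' The clustering operates on the spectral neighbourhood of the first
#' harmonic: the energy argmax locates the beat frequency, points further
#' than a factor `harmonic_radius` from it are discarded, and K-means
#' (K = 3, k-means++ seeding, Lloyd iterations, 10 restarts) is run on the
#' remaining (log-frequency, energy) pairs, both min-max normalized to
#' `[0, 1]`. Log-frequency is the natural axis for a geometrically spaced
#' filter bank; energies enter squared (the pooled scattering coefficients
#' are amplitudes). Centroids are sorted by frequency (geometric cluster
#' means) and the band is the span from the leftmost to the rightmost
#' centroid frequency (`rule = "centroid_span"`, the default), or the
#' frequency extent of the highest-mean-energy cluster
#' (`rule = "peak_cluster"`). The band is clamped to `band_limits`.
#' Deterministic for a fixed seed; degenerate clusterings fall back to the
#' full band with a warning.
#'
#' @param freqs wavelet centre frequencies in Hz (>= 3 distinct values).
#' @param energies per-wavelet energies, same length.
#' @param seed integer RNG seed for the k-means++ restarts (default 0).
#' @param k number of clusters (default 3).
#' @param rule band extraction rule, see above.
#' @param band_limits clamp interval in Hz (default `c(0.7, 5)`).
#' @param harmonic_radius multiplicative radius of the first-harmonic
#'   neighbourhood fed to the clustering (default 1.6, about two thirds of
#'   an octave either side of the energy peak).
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart (default 300).
#' @return an object of class `frequency_band`: numeric `c(low, high)` in Hz.
#' @export
estimate_band <- function(freqs, energies, seed = 0, k = 3,
                          rule = c("centroid_span", "peak_cluster"),
                          band_limits = c(0.7, 5), harmonic_radius = 1.6,
                          nstart = 10, iter_max = 300) {
  rule <- match.arg(rule)
  freqs <- as.numeric(freqs); energies <- as.numeric(energies)
  stopifnot(length(freqs) == length(energies))
  full_band <- frequency_band(band_limits[1L], band_limits[2L], band_limits)
  if (length(freqs) < k || length(unique(freqs)) < k) {
    warning("estimate_band: fewer than ", k,
            " distinct frequencies; falling back to the full band")
    return(full_band)
  }
  e_all <- energies^2
  f_peak <- freqs[which.max(e_all)]
  sel <- freqs >= f_peak / harmonic_radius & freqs <= f_peak * harmonic_radius
  if (length(unique(freqs[sel])) < k) sel <- rep(TRUE, length(freqs))
  freqs <- freqs[sel]
  energies <- e_all[sel]
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) rep(0, length(v)) else (v - r[1L]) / diff(r)
  }
  X <- cbind(f = minmax(log(freqs)), e = minmax(energies))
  fit <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(nstart)) {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = kmeanspp_centers(X, k),
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) && all(km$size > 0) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
    best
  })
  if (is.null(fit)) {
    warning("estimate_band: degenerate clustering; falling back to the full band")
    return(full_band)
  }
  fr <- range(log(freqs))
  cent_f <- exp(fit$centers[, "f"] * diff(fr) + fr[1L])
  if (rule == "centroid_span") {
    lo <- min(cent_f); hi <- max(cent_f)
  } else {
    emean <- tapply(energies, fit$cluster, mean)
    top <- as.integer(names(emean)[which.max(emean)])
    lo <- min(freqs[fit$cluster == top]); hi <- max(freqs[fit$cluster == top])
  }
  frequency_band(lo, hi, band_limits)
}

#' Frequency band container
#'
#' @param low,high band edges in Hz.
#' @param limits clamp interval (default `c(0.7, 5)`, the global heart-rate
#'   band).
#' @return numeric `c(low, high)` of class `frequency_band`.
#' @export
frequency_band <- function(low, high, limits = c(0.7, 5)) {
  lo <- min(max(low, limits[1L]), limits[2L])
  hi <- min(max(high, limits[1L]), limits[2L])
  if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
  structure(c(low = lo, high = hi), class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> [%.3f, %.3f] Hz\n", x[1L], x[2L]))
  invisible(x)
}

#' Band-pass and mean-centre one window segment
#'
#' Applies a zero-phase Butterworth band-pass with the window's estimated
#' band, then subtracts the segment mean to keep only the pulsatile part.
#' A degenerate band (width < 0.05 Hz) is widened symmetrically to 0.1 Hz.
#'
#' @param segment a [sampled_signal()] (one sliding window of the cleaned
#'   trace), longer than `3 * order` samples.
#' @param band a [frequency_band()] or numeric `c(low, high)` in Hz.
#' @param order Butterworth design order (default 7).
#' @return the refined segment as a [sampled_signal()].
#' @export
refine_window <- function(segment, band, order = 7) {
  stopifnot(inherits(segment, "sampled_signal"))
  lo <- band[[1L]]; hi <- band[[2L]]
  if (hi - lo < 0.05) {
    mid <- (lo + hi) / 2
    lo <- max(mid - 0.05, 0.01)
    hi <- lo + 0.1
  }
  hi <- min(hi, segment$fs / 2 * 0.99)
  if (length(segment$values) <= 3 * order) {
    stop_wavehrv("refine_window: segment shorter than 3x the filter order")
  }
  f <- butter_bandpass(segment, band = c(lo, hi), order = order)
  sampled_signal(f$values - mean(f$values), fs = f$fs, t0 = f$t0)
}

#' Overlap-add reconstruction of refined windows
#'
#' Each output sample is the sum of all window segments covering it, as in
#' additive overlap-add reconstruction.
#'
#' @param segments list of [sampled_signal()] segments, one per plan window.
#' @param plan the [window_plan()] the segments were cut with.
#' @return a [sampled_signal()] of the original length.
#' @export
reconstruct_overlap_add <- function(segments, plan) {
  stopifnot(inherits(plan, "window_plan"))
  if (length(segments) != nrow(plan)) {
    stop_wavehrv("reconstruct_overlap_add: ", length(segments),
                 " segments for ", nrow(plan), " plan windows")
  }
  out <- numeric(attr(plan, "n_samples"))
  for (j in seq_len(nrow(plan))) {
    idx <- plan$start_i[j]:plan$end_i[j]
    v <- if (inherits(segments[[j]], "sampled_signal")) segments[[j]]$values
         else as.numeric(segments[[j]])
    if (length(v) != length(idx)) {
      stop_wavehrv(sprintf(
        "reconstruct_overlap_add: segment %d has %d samples, plan slot has %d",
        j, length(v), length(idx)))
    }
    out[idx] <- out[idx] + v
  }
  sampled_signal(out, fs = attr(plan, "fs"))
}

#' Amplify the attenuated edges of an overlap-added signal
#'
#' Samples near the record ends are covered by fewer sliding windows than
#' interior samples, so overlap-add leaves the edge peaks smaller. Each
#' sample within one window length of either end is multiplied by the
#' coverage-equalizing gain `(w/s) / coverage`, capped below at 1. At the
#' head this is exactly the slice rule `c_j = (w/s) / (j + 1)` for the slice
#' `[j*s, (j+1)*s)` (covered by `j + 1` windows versus `w/s` in the
#' interior); at the tail the coverage steps fall at the clipped window ends,
#' offset by `w mod s`, which the per-sample count follows exactly. Samples
#' beyond `w` from both ends are untouched.
#'
#' @param sig a [sampled_signal()] produced by [reconstruct_overlap_add()].
#' @param plan the matching [window_plan()].
#' @return a [sampled_signal()] with equalized edges.
#' @export
amplify_edges <- function(sig, plan) {
  stopifnot(inherits(sig, "sampled_signal"), inherits(plan, "window_plan"))
  w <- attr(plan, "w"); s <- attr(plan, "s"); fs <- sig$fs
  ws <- w / s
  if (ws < 1) return(sig)
  n <- length(sig$values)
  coverage <- integer(n)
  for (j in seq_len(nrow(plan))) {
    idx <- plan$start_i[j]:plan$end_i[j]
    coverage[idx] <- coverage[idx] + 1L
  }
  edge <- seq_len(n) <= round(w * fs) | seq_len(n) > n - round(w * fs)
  gain <- rep(1, n)
  gain[edge] <- pmax(1, ws / coverage[edge])
  sampled_signal(sig$values * gain, fs = fs, t0 = sig$t0)
}

#' Adaptive narrow-band filtering of a cleaned pulse trace
#'
#' The per-window driver: for each sliding window of `plan`, interpolate the
#' scattering energies to the window end, estimate the narrow band by
#' K-means, band-pass and mean-centre the window, then overlap-add all
#' windows and amplify the edges.
#'
#' @param sig the pre-cleaned [sampled_signal()] (band-passed 0.7-5 Hz).
#' @param coeffs [scatter_first_order()] coefficients of `sig`.
#' @param plan a [window_plan()] for the signal.
#' @param seed K-means seed (default 0).
#' @param rule band extraction rule, see [estimate_band()].
#' @param order Butterworth design order (default 7).
#' @param band_limits global clamp in Hz (default `c(0.7, 5)`).
#' @param harmonic_radius first-harmonic neighbourhood radius, see
#'   [estimate_band()].
#' @return list with `signal` (the reconstructed [sampled_signal()]) and
#'   `bands` (data frame: window, start_s, end_s, low_hz, high_hz).
#' @export
adaptive_narrowband_filter <- function(sig, coeffs, plan, seed = 0,
                                       rule = "centroid_span", order = 7,
                                       band_limits = c(0.7, 5),
                                       harmonic_radius = 1.6) {
  stopifnot(inherits(sig, "sampled_signal"))
  segments <- vector("list", nrow(plan))
  bands <- matrix(NA_real_, nrow(plan), 2L)
  for (j in seq_len(nrow(plan))) {
    en <- interp_window_energy(coeffs, plan$end_s[j],
                               fmin = band_limits[1L], fmax = band_limits[2L])
    band <- estimate_band(en$freqs, en$energies, seed = seed, rule = rule,
                          band_limits = band_limits,
                          harmonic_radius = harmonic_radius)
    bands[j, ] <- band
    seg <- sampled_signal(sig$values[plan$start_i[j]:plan$end_i[j]],
                          fs = sig$fs, t0 = sig$t0 + plan$start_s[j])
    segments[[j]] <- refine_window(seg, band, order = order)
  }
  rec <- reconstruct_overlap_add(segments, plan)
  rec <- amplify_edges(rec, plan)
  rec$t0 <- sig$t0
  list(signal = rec,
       bands = data.frame(window = plan$window, start_s = plan$start_s,
                          end_s = plan$end_s, low_hz = bands[, 1L],
                          high_hz = bands[, 2L]))
}
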