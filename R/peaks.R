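# Beat detection and inter-beat-interval refinement.

#' Automatic multiscale-based peak detection (AMPD)
#'
#' Detects beats without amplitude thresholds. After linear detrending, a
#' local-maxima scalogram is built over window scales `k = 1..L`: entry
#' `(k, i)` is 0 when `x[i] > x[i-k]` and `x[i] > x[i+k]`, else 1. The
#' operating scale `lambda*` is the row-sum argmin (the scale exposing the
#' most maxima; ties go to the smallest scale), and a sample is a peak iff it
#' is a scale-`k` maximum for every `k <= lambda*`. The original algorithm
#' fills non-maxima entries with small uniform random values whose only role
#' is tie-breaking; the constant 1 with a smallest-scale tie rule makes the
#' detector fully deterministic.
#'
#' @param sig a [sampled_signal()].
#' @param max_scale_s largest scale considered, in seconds (default 1.5 s,
#'   roughly half again the slowest plausible beat interval); caps `L` at
#'   `max_scale_s * fs`.
#' @return an object of class `peak_set`: `indices` (1-based sample indices,
#'   strictly increasing), `times` (seconds), `fs`, `lambda` (the selected
#'   scale). A signal too short for one scale yields an empty set with a
#'   warning.
#' @export
detect_peaks_ampd <- function(sig, max_scale_s = 1.5) {
  stopifnot(inherits(sig, "sampled_signal"))
  x <- sig$values
  n <- length(x)
  L <- min(floor(max_scale_s * sig$fs), (n - 1L) %/% 2L)
  if (L < 1L) {
    warning("detect_peaks_ampd: signal too short for a single scale; no peaks")
    return(structure(list(indices = integer(0), times = numeric(0),
                          fs = sig$fs, lambda = NA_integer_),
                     class = "peak_set"))
  }
  idx <- seq_len(n)
  x <- x - (stats::cov(idx, x) / stats::var(idx)) * (idx - mean(idx)) - mean(x)
  is_max_at_scale <- function(k) {
    ok <- logical(n)
    i <- (k + 1L):(n - k)
    ok[i] <- x[i] > x[i - k] & x[i] > x[i + k]
    ok
  }
  gamma <- vapply(seq_len(L), function(k) n - sum(is_max_at_scale(k)),
                  numeric(1))
  lambda <- which.min(gamma)          # ties resolve to the smallest scale
  all_max <- rep(TRUE, n)
  for (k in seq_len(lambda)) all_max <- all_max & is_max_at_scale(k)
  ind <- which(all_max)
  structure(list(indices = ind, times = sig$t0 + (ind - 1L) / sig$fs,
                 fs = sig$fs, lambda = as.integer(lambda)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz (scale lambda* = %s)\n",
              length(x$indices), x$fs,
              ifelse(is.na(x$lambda), "NA", x$lambda)))
  invisible(x)
}

#' Ordered inter-beat-interval series
#'
#' @param ibis_ms intervals in milliseconds, all > 0.
#' @param beat_times_s timestamps of the second beat of each interval,
#'   strictly increasing, same length.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(ibis_ms, beat_times_s) {
  ibis_ms <- as.numeric(ibis_ms); beat_times_s <- as.numeric(beat_times_s)
  if (length(ibis_ms) != length(beat_times_s)) {
    stop_wavehrv("ibi_series: lengths of intervals and timestamps differ")
  }
  if (length(ibis_ms) > 0L) {
    if (any(!is.finite(ibis_ms)) || any(ibis_ms <= 0)) {
      stop_wavehrv("ibi_series: intervals must be finite and positive")
    }
    if (any(diff(beat_times_s) <= 0)) {
      stop_wavehrv("ibi_series: beat timestamps must be strictly increasing")
    }
  }
  structure(list(ibis_ms = ibis_ms, beat_times_s = beat_times_s),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  n <- length(x$ibis_ms)
  if (n == 0L) {
    cat("<ibi_series> empty\n")
  } else {
    cat(sprintf("<ibi_series> %d intervals, mean %.1f ms (span %.1f s)\n",
                n, mean(x$ibis_ms),
                diff(range(x$beat_times_s))))
  }
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$ibis_ms)

#' Convert detected peaks to inter-beat intervals
#'
#' Successive peak-time differences in milliseconds. With sub-sample
#' refinement (recommended at low frame rates, where the sample quantization
#' otherwise dominates RMSSD error) each interior peak time is refined by a
#' three-point parabolic fit around the sample maximum.
#'
#' @param peaks a [detect_peaks_ampd()] result with >= 2 peaks (fewer give an
#'   empty series).
#' @param sig the signal the peaks were detected on; required for
#'   `subsample = TRUE`.
#' @param subsample logical, apply parabolic sub-sample refinement (default:
#'   on when `sig` is supplied).
#' @return an [ibi_series()].
#' @export
peaks_to_ibis <- function(peaks, sig = NULL, subsample = !is.null(sig)) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$indices) < 2L) {
    return(ibi_series(numeric(0), numeric(0)))
  }
  times <- peaks$times
  if (subsample) {
    if (is.null(sig)) {
      stop_wavehrv("peaks_to_ibis: sub-sample refinement needs the signal")
    }
    x <- sig$values; n <- length(x)
    for (p in seq_along(peaks$indices)) {
      i <- peaks$indices[p]
      if (i > 1L && i < n) {
        denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
        if (denom < 0) {
          delta <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
          delta <- max(-0.5, min(0.5, delta))
          times[p] <- times[p] + delta / peaks$fs
        }
      }
    }
  }
  ibi_series(diff(times) * 1000, times[-1L])
}

#' Rule-based refinement of an IBI series
#'
#' Removes physically impossible or misplaced-peak intervals in three ordered
#' rules: (1) drop intervals outside `bounds_ms`; (2) drop intervals outside
#' `mean +/- mean_tol * mean`, the mean taken once over rule-1 survivors;
#' (3) partition the survivors into consecutive non-overlapping blocks of
#' `block_size` (final partial block included; singleton blocks trivially
#' pass) and drop intervals outside `blockmean +/- block_tol * blockmean`.
#'
#' @param series an [ibi_series()].
#' @param bounds_ms hard physiological bounds in ms (default `c(400, 1300)`,
#'   suited to adults at rest; task-dependent).
#' @param mean_tol global-mean tolerance (default 0.4).
#' @param block_size rule-3 window size in intervals (default 10).
#' @param block_tol rule-3 tolerance (default 0.2).
#' @return list with `series` (the surviving [ibi_series()]), `drops` (data
#'   frame `index`, `rule` for every removed interval, indices into the
#'   input), and `unreliable` (TRUE when nothing survives).
#' @export
refine_ibis <- function(series, bounds_ms = c(400, 1300), mean_tol = 0.4,
                        block_size = 10, block_tol = 0.2) {
  stopifnot(inherits(series, "ibi_series"))
  ibis <- series$ibis_ms
  times <- series$beat_times_s
  orig_idx <- seq_along(ibis)
  drops <- data.frame(index = integer(0), rule = integer(0))
  note_drop <- function(idx, rule) {
    rbind(drops, data.frame(index = idx, rule = rep(rule, length(idx))))
  }

  keep1 <- ibis >= bounds_ms[1L] & ibis <= bounds_ms[2L]
  drops <- note_drop(orig_idx[!keep1], 1L)
  ibis <- ibis[keep1]; times <- times[keep1]; orig_idx <- orig_idx[keep1]

  if (length(ibis) > 0L) {
    m <- mean(ibis)
    keep2 <- abs(ibis - m) <= mean_tol * m
    drops <- note_drop(orig_idx[!keep2], 2L)
    ibis <- ibis[keep2]; times <- times[keep2]; orig_idx <- orig_idx[keep2]
  }

  if (length(ibis) > 0L) {
    block <- (seq_along(ibis) - 1L) %/% block_size
    keep3 <- rep(TRUE, length(ibis))
    for (b in unique(block)) {
      sel <- block == b
      bm <- mean(ibis[sel])
      keep3[sel] <- abs(ibis[sel] - bm) <= block_tol * bm
    }
    drops <- note_drop(orig_idx[!keep3], 3L)
    ibis <- ibis[keep3]; times <- times[keep3]
  }

  drops <- drops[order(drops$index), , drop = FALSE]
  rownames(drops) <- NULL
  list(series = ibi_series(ibis, times), drops = drops,
       unreliable = length(ibis) == 0L)
}

#' Read an IBI series from CSV (`t_s,ibi_ms`)
#'
#' @param path CSV file path with columns `t_s` and `ibi_ms`.
#' @return an [ibi_series()].
#' @export
read_ibis_csv <- function(path) {
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  if (!all(c("t_s", "ibi_ms") %in% nm)) {
    stop_wavehrv("read_ibis_csv: expected columns t_s,ibi_ms")
  }
  ibi_series(df[[which(nm == "ibi_ms")[1L]]], df[[which(nm == "t_s")[1L]]])
}

#' Write an IBI series to CSV (`t_s,ibi_ms`)
#'
#' @param series an [ibi_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ibis_csv <- function(series, path) {
  stopifnot(inherits(series, "ibi_series"))
  utils::write.csv(data.frame(t_s = series$beat_times_s,
                              ibi_ms = series$ibis_ms),
                   path, row.names = FALSE)
  invisible(path)
}
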