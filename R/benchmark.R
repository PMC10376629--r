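# Ground-truth cleaning criteria for contact PPG/ECG reference recordings
# and paired agreement statistics for benchmarking estimated HRV against a
# reference device.

#' Clean and vet a ground-truth IBI series
#'
#' Applies acceptance criteria aimed at detecting corrupted reference
#' recordings (device disconnection, loose electrodes, motion):
#' \enumerate{
#'   \item a covered face at any instant invalidates the recording;
#'   \item any instantaneous heart rate `60000/IBI` outside `hr_limits`
#'     bpm -- evaluated on the raw intervals, before outlier removal, since
#'     disconnections are exactly what the outlier rule would mask --
#'     invalidates the recording;
#'   \item intervals outside `segment mean +/- seg_tol * segment mean`
#'     (consecutive segments of `segment_size` intervals, final partial
#'     segment included) are removed as misplaced beats;
#'   \item SDNN > `sdnn_max` ms or RMSSD > `rmssd_max` ms on the cleaned
#'     series (beyond the physiologically plausible short-term range)
#'     invalidates the recording.
#' }
#'
#' @param series the reference [ibi_series()].
#' @param face_covered logical metadata flag (video analysis is not done
#'   here).
#' @param hr_limits plausible instantaneous heart-rate range in bpm
#'   (default `c(45, 200)`).
#' @param segment_size segment length for the outlier rule, in intervals
#'   (default 25, within the customary 20-30).
#' @param seg_tol relative deviation tolerated around the segment mean
#'   (default 0.3).
#' @param sdnn_max,rmssd_max upper plausibility bounds in ms (default 100).
#' @return an object of class `cleaning_report`: `accepted`, `reasons`
#'   (subset of face_covered / hr_out_of_range / sdnn_too_high /
#'   rmssd_too_high / empty_after_cleaning), `ibis_removed` (count removed
#'   by the segment rule), `cleaned` (the surviving [ibi_series()]).
#' @export
clean_ground_truth <- function(series, face_covered = FALSE,
                               hr_limits = c(45, 200), segment_size = 25,
                               seg_tol = 0.3, sdnn_max = 100,
                               rmssd_max = 100) {
  stopifnot(inherits(series, "ibi_series"))
  if (length(series) == 0L) stop_wavehrv("clean_ground_truth: empty series")
  reasons <- character(0)
  if (isTRUE(face_covered)) reasons <- c(reasons, "face_covered")
  hr <- 60000 / series$ibis_ms
  if (any(hr < hr_limits[1L] | hr > hr_limits[2L])) {
    reasons <- c(reasons, "hr_out_of_range")
  }
  ibis <- series$ibis_ms
  times <- series$beat_times_s
  seg <- (seq_along(ibis) - 1L) %/% segment_size
  keep <- rep(TRUE, length(ibis))
  for (g in unique(seg)) {
    sel <- seg == g
    sm <- mean(ibis[sel])
    keep[sel] <- abs(ibis[sel] - sm) <= seg_tol * sm
  }
  removed <- sum(!keep)
  cleaned <- ibi_series(ibis[keep], times[keep])
  if (length(cleaned) == 0L) {
    reasons <- c(reasons, "empty_after_cleaning")
  } else if (length(cleaned) >= 2L) {
    if (sdnn(cleaned) > sdnn_max) reasons <- c(reasons, "sdnn_too_high")
    if (rmssd(cleaned) > rmssd_max) reasons <- c(reasons, "rmssd_too_high")
  }
  structure(list(accepted = length(reasons) == 0L, reasons = reasons,
                 ibis_removed = removed, cleaned = cleaned),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %s; %d interval(s) removed%s\n",
              if (x$accepted) "accepted" else "REJECTED",
              x$ibis_removed,
              if (length(x$reasons)) paste0(" [",
                paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Paired agreement statistics between estimates and reference values
#'
#' Computes, for paired vectors `estimates` (predicted) and `truths`
#' (actual): mean absolute error; the root-mean-square of the differences
#' (reported as `sd` -- note this is the uncentred RMS difference, not a
#' mean-centred standard deviation); Pearson correlation; a two-sided paired
#' t-test of the differences (`n - 1` degrees of freedom); and Bland-Altman
#' mean difference with 95% limits of agreement
#' `mean_diff +/- 1.96 * sd(differences)`.
#'
#' @param estimates,truths equal-length numeric vectors, `n >= 2`, finite.
#' @return an object of class `agreement_stats` with fields `mae`, `sd`,
#'   `r`, `t`, `p`, `n`, `mean_diff`, `loa_low`, `loa_high`. `r` is `NA`
#'   with a warning when either vector has zero variance.
#' @examples
#' agreement_stats(c(2, 2, 2), c(1, 2, 3))  # MAE 2/3, RMS-diff sqrt(2/3)
#' @export
agreement_stats <- function(estimates, truths) {
  y <- as.numeric(truths); yhat <- as.numeric(estimates)
  n <- length(y)
  if (n < 2L || length(yhat) != n) {
    stop_wavehrv("agreement_stats: need equal-length vectors with n >= 2")
  }
  if (!all(is.finite(c(y, yhat)))) {
    stop_wavehrv("agreement_stats: values must be finite")
  }
  d <- yhat - y
  mae <- mean(abs(d))
  rms <- sqrt(mean(d^2))
  r <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("agreement_stats: zero variance; correlation undefined")
    NA_real_
  } else {
    stats::cor(y, yhat)
  }
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    ht <- stats::t.test(yhat, y, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  sd_d <- stats::sd(d)
  structure(list(mae = mae, sd = rms, r = r, t = tt$statistic,
                 p = tt$p.value, n = n, mean_diff = mean(d),
                 loa_low = mean(d) - 1.96 * sd_d,
                 loa_high = mean(d) + 1.96 * sd_d),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n = %d: MAE %.4g, RMS diff %.4g, r %.3f\n",
    x$n, x$mae, x$sd, x$r))
  cat(sprintf("  bias %.4g [LoA %.4g, %.4g], paired t = %.3f, p = %.4g\n",
              x$mean_diff, x$loa_low, x$loa_high, x$t, x$p))
  invisible(x)
}

#' Bland-Altman summary table
#'
#' @param estimates,truths paired numeric vectors.
#' @return a one-row data frame with the mean difference, the SD of the
#'   differences and the 95% limits of agreement.
#' @export
bland_altman_table <- function(estimates, truths) {
  st <- agreement_stats(estimates, truths)
  data.frame(n = st$n, mean_diff = st$mean_diff,
             sd_diff = stats::sd(estimates - truths),
             loa_low = st$loa_low, loa_high = st$loa_high)
}

#' Batch agreement over a manifest of paired IBI recordings
#'
#' Reads a manifest (`id,estimate_file,truth_file,face_covered`), cleans each
#' ground-truth series with [clean_ground_truth()], computes SDNN and RMSSD
#' for estimate and cleaned truth of every accepted record, and returns
#' per-metric agreement statistics.
#'
#' @param manifest a data frame with columns `id`, `estimate_file`,
#'   `truth_file`, `face_covered`, or the path of such a CSV.
#' @param ... passed to [clean_ground_truth()].
#' @return list with `records` (per-record cleaning reports and metric
#'   values) and `agreement` (list of [agreement_stats()] keyed by metric;
#'   `NULL` when fewer than 2 records are accepted).
#' @export
batch_agreement <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("id", "estimate_file", "truth_file", "face_covered")
  if (!all(need %in% names(manifest))) {
    stop_wavehrv("batch_agreement: manifest needs columns ",
                 paste(need, collapse = ","))
  }
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    truth <- read_ibis_csv(manifest$truth_file[i])
    est <- read_ibis_csv(manifest$estimate_file[i])
    rep <- clean_ground_truth(truth,
                              face_covered = isTRUE(as.logical(manifest$face_covered[i])),
                              ...)
    list(id = manifest$id[i], cleaning = rep,
         est_sdnn = suppressWarnings(sdnn(est)),
         est_rmssd = suppressWarnings(rmssd(est)),
         true_sdnn = if (rep$accepted) sdnn(rep$cleaned) else NA_real_,
         true_rmssd = if (rep$accepted) rmssd(rep$cleaned) else NA_real_)
  })
  ok <- vapply(records, function(r) r$cleaning$accepted, logical(1))
  agreement <- NULL
  if (sum(ok) >= 2L) {
    g <- function(f) vapply(records[ok], `[[`, numeric(1), f)
    agreement <- list(
      sdnn = agreement_stats(g("est_sdnn"), g("true_sdnn")),
      rmssd = agreement_stats(g("est_rmssd"), g("true_rmssd")))
  }
  list(records = records, agreement = agreement)
}
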