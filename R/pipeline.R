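# End-to-end orchestration: trace -> rPPG candidate -> power-of-two
# resampling -> 0.7-5 Hz pre-cleaning -> first-order scattering -> adaptive
# narrow-band windowing -> overlap-add + edge amplification -> AMPD beats ->
# IBI refinement -> HRV report.

#' Pipeline configuration with validated defaults
#'
#' All tunable parameters of the chain in one validated list. Defaults:
#' heart-rate band 0.7-5 Hz, Butterworth design order 7, scattering pooling
#' 16 s with a bank of 20 in-band wavelets, sliding windows of 14.5 s with a
#' 2 s step, IBI bounds 400-1300 ms, 50 ms Baevsky bins, 4 Hz tachogram,
#' 16 s minimum record duration.
#'
#' @param ... overrides of any default, by name.
#' @return a validated list of class `wavehrv_config`.
#' @examples
#' cfg <- wavehrv_config(window_seconds = 10)
#' cfg$window_seconds
#' @export
wavehrv_config <- function(...) {
  cfg <- list(
    band_limits = c(0.7, 5),
    filter_order = 7,
    window_seconds = 14.5,
    step_seconds = 2,
    pooling_seconds = 16,
    n_wavelets = 20,
    band_rule = "centroid_span",
    harmonic_radius = 1.6,
    kmeans_seed = 0,
    ibi_bounds_ms = c(400, 1300),
    ibi_mean_tol = 0.4,
    ibi_block_size = 10,
    ibi_block_tol = 0.2,
    baevsky_bin_ms = 50,
    tachogram_hz = 4,
    pos_window_seconds = 1.6,
    ampd_max_scale_s = 1.5,
    subsample_peaks = TRUE,
    min_duration_s = 16,
    schema_version = "wavehrv-report/1"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_wavehrv("wavehrv_config: unknown key(s): ",
                 paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  with(cfg, {
    stopifnot(band_limits[1] > 0, band_limits[1] < band_limits[2],
              filter_order >= 1, step_seconds > 0,
              step_seconds <= window_seconds, pooling_seconds > 0,
              n_wavelets >= 2, ibi_bounds_ms[1] > 0,
              ibi_bounds_ms[1] < ibi_bounds_ms[2], ibi_mean_tol > 0,
              ibi_block_size >= 1, ibi_block_tol > 0, baevsky_bin_ms > 0,
              tachogram_hz > 0, pos_window_seconds > 0,
              ampd_max_scale_s > 0, min_duration_s > 0,
              harmonic_radius > 1)
    stopifnot(band_rule %in% c("centroid_span", "peak_cluster"))
  })
  structure(cfg, class = c("wavehrv_config", "list"))
}

#' Run the full HRV extraction pipeline
#'
#' @param input a [sampled_signal()] (pulse trace) or [rgb_trace()]
#'   (per-frame channel means; projected to a pulse candidate first).
#' @param config a [wavehrv_config()].
#' @param dump_dir optional directory: when given, intermediate stages
#'   (rPPG candidate, scattering CSV, per-window bands, reconstructed
#'   signal, raw and refined IBIs) are written there.
#' @return list of class `wavehrv_result` with `report` (an `hrv_report`)
#'   and `intermediates` (rppg, resampled, clean, scattering, plan, bands,
#'   reconstructed, peaks, ibis_raw, ibis_refined, drops). Deterministic
#'   given the config seeds. Records shorter than `min_duration_s` are
#'   refused; an empty refined series yields a report flagged unreliable.
#' @examples
#' \donttest{
#' spec <- synth_spec(duration_s = 64, fs = 32, seed = 7)
#' truth <- generate_ibi_series(spec)
#' rec <- render_ppg(truth, spec)
#' res <- run_wavehrv(rec$signal)
#' res$report
#' }
#' @export
run_wavehrv <- function(input, config = wavehrv_config(), dump_dir = NULL) {
  stopifnot(inherits(config, "wavehrv_config"))
  rppg <- NULL
  if (inherits(input, "rgb_trace")) {
    rppg <- pos_rppg(input, win_seconds = config$pos_window_seconds)
    sig <- rppg
  } else if (inherits(input, "sampled_signal")) {
    sig <- input
  } else {
    stop_wavehrv("run_wavehrv: input must be a sampled_signal or rgb_trace")
  }
  dur <- signal_duration(sig)
  if (dur < config$min_duration_s) {
    stop_wavehrv(sprintf(
      "run_wavehrv: record is %.1f s; at least %g s are required for meaningful HRV",
      dur, config$min_duration_s))
  }

  resampled <- resample_to_pow2(sig)
  clean <- butter_bandpass(resampled, band = config$band_limits,
                           order = config$filter_order)
  pooling <- min(config$pooling_seconds, signal_duration(clean))
  bank <- build_filterbank(clean$fs, n_in_band = config$n_wavelets,
                           pooling_seconds = pooling,
                           fmin = config$band_limits[1L],
                           fmax = config$band_limits[2L])
  coeffs <- scatter_first_order(clean, bank)
  plan <- window_plan(signal_duration(clean), clean$fs,
                      window_seconds = config$window_seconds,
                      step_seconds = config$step_seconds)
  adaptive <- adaptive_narrowband_filter(
    clean, coeffs, plan, seed = config$kmeans_seed,
    rule = config$band_rule, order = config$filter_order,
    band_limits = config$band_limits,
    harmonic_radius = config$harmonic_radius)
  reconstructed <- adaptive$signal

  peaks <- detect_peaks_ampd(reconstructed,
                             max_scale_s = config$ampd_max_scale_s)
  ibis_raw <- peaks_to_ibis(peaks,
                            sig = if (config$subsample_peaks) reconstructed,
                            subsample = config$subsample_peaks)
  if (length(ibis_raw) == 0L) {
    refined <- list(series = ibis_raw,
                    drops = data.frame(index = integer(0), rule = integer(0)),
                    unreliable = TRUE)
  } else {
    refined <- refine_ibis(ibis_raw, bounds_ms = config$ibi_bounds_ms,
                           mean_tol = config$ibi_mean_tol,
                           block_size = config$ibi_block_size,
                           block_tol = config$ibi_block_tol)
  }
  report <- hrv_report(refined$series, n_dropped = nrow(refined$drops),
                       baevsky_bin_ms = config$baevsky_bin_ms,
                       tachogram_hz = config$tachogram_hz,
                       unreliable = refined$unreliable)

  intermediates <- list(rppg = rppg, resampled = resampled, clean = clean,
                        scattering = coeffs, plan = plan,
                        bands = adaptive$bands,
                        reconstructed = reconstructed, peaks = peaks,
                        ibis_raw = ibis_raw, ibis_refined = refined$series,
                        drops = refined$drops)
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(rppg)) write_trace_csv(rppg, file.path(dump_dir, "rppg.csv"))
    write_trace_csv(reconstructed, file.path(dump_dir, "reconstructed.csv"))
    write_scattering_csv(coeffs, file.path(dump_dir, "scattering.csv"))
    utils::write.csv(adaptive$bands, file.path(dump_dir, "bands.csv"),
                     row.names = FALSE)
    write_ibis_csv(ibis_raw, file.path(dump_dir, "ibis_raw.csv"))
    write_ibis_csv(refined$series, file.path(dump_dir, "ibis_refined.csv"))
    utils::write.csv(refined$drops, file.path(dump_dir, "ibi_drops.csv"),
                     row.names = FALSE)
  }
  structure(list(report = report, config = config,
                 intermediates = intermediates),
            class = "wavehrv_result")
}

#' @export
print.wavehrv_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Serialize an HRV report (plus the configuration used) to JSON
#'
#' @param result a `wavehrv_result` from [run_wavehrv()] or an `hrv_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_hrv_report <- function(result, path) {
  if (inherits(result, "wavehrv_result")) {
    payload <- c(list(schema = result$config$schema_version),
                 unclass(result$report),
                 list(config = unclass(result$config)))
  } else if (inherits(result, "hrv_report")) {
    payload <- unclass(result)
  } else {
    stop_wavehrv("write_hrv_report: unsupported object")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
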