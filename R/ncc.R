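#' Normalized cross-correlation of a template against a signal
#'
#' For every lag `k` (0-based), computes the Pearson correlation between the
#' template and the signal window starting at sample `k`: both are
#' mean-subtracted and divided by the product of their root sums of squared
#' deviations, so the result lies in \[-1, 1\] and is invariant to affine
#' rescaling of either input. Windows with zero variance yield 0.
#'
#' The implementation uses an FFT cross-correlation for the numerator and
#' cumulative sums for the window statistics; [ncc_brute_force()] is the
#' direct per-lag reference implementation.
#'
#' @param signal numeric signal.
#' @param template numeric template, not longer than the signal and not
#'   constant.
#' @param fs sampling rate in Hz (carried for peak-distance conversion).
#' @return an `ncc_series`: list with `values` (length
#'   `length(signal) - length(template) + 1`), `fs`, `template_length`.
#' @export
normalized_cross_correlation <- function(signal, template, fs = NA_real_) {
  L <- length(template)
  N <- length(signal)
  if (L > N)
    cm_error("template longer than signal", "cardiomatch_length_error")
  tz <- template - mean(template)
  st <- sqrt(sum(tz^2))
  if (st == 0)
    cm_error("constant template has no correlation structure",
             "cardiomatch_degenerate_template_error")
  m <- stats::nextn(N, 2)
  fs_sig <- fft(c(signal, numeric(m - N)))
  fs_tpl <- fft(c(tz, numeric(m - L)))
  cross <- Re(fft(fs_sig * Conj(fs_tpl), inverse = TRUE)) / m
  cross <- cross[1:(N - L + 1L)]
  cs1 <- cumsum(c(0, signal))
  cs2 <- cumsum(c(0, signal^2))
  idx <- 1:(N - L + 1L)
  s1 <- cs1[idx + L] - cs1[idx]
  s2 <- cs2[idx + L] - cs2[idx]
  wvar <- pmax(s2 - s1^2 / L, 0)
  denom <- sqrt(wvar) * st
  vals <- ifelse(denom > 0, cross / denom, 0)
  vals <- pmin(pmax(vals, -1), 1)
  structure(list(values = vals, fs = fs, template_length = L),
            class = "ncc_series")
}

#' Brute-force per-lag Pearson correlation (reference implementation)
#'
#' Direct O(N*L) loop computing `cor(template, window)` at every lag; used
#' as the independent oracle for [normalized_cross_correlation()].
#'
#' @inheritParams normalized_cross_correlation
#' @return numeric vector of per-lag correlations.
#' @export
ncc_brute_force <- function(signal, template) {
  L <- length(template)
  N <- length(signal)
  vapply(1:(N - L + 1L), function(k) {
    w <- signal[k:(k + L - 1L)]
    if (var(w) == 0) return(0)
    cor(template, w)
  }, numeric(1))
}

#' Locate heartbeat matches on an NCC trace
#'
#' Local NCC maxima with topographic prominence of at least
#' `cfg$ncc_min_prominence` (0.5), thinned so that no two retained peaks are
#' closer than `cfg$ncc_min_distance_s` (0.5 s, i.e. a 120 bpm ceiling on
#' reported beat rate); within the exclusion distance the higher peak wins.
#'
#' @param ncc an `ncc_series` with a known `fs`.
#' @param cfg a [detector_config()].
#' @return 0-based peak lags in samples, increasing (possibly empty).
#' @export
detect_ncc_peaks <- function(ncc, cfg = detector_config()) {
  stopifnot(inherits(ncc, "ncc_series"))
  if (!is.finite(ncc$fs))
    cm_error("NCC series needs a sampling rate for distance pruning",
             "cardiomatch_config_error")
  pk <- find_peaks(ncc$values, min_prominence = cfg$ncc_min_prominence,
                   min_distance = cfg$ncc_min_distance_s * ncc$fs)
  pk$index - 1L
}

#' Reconstruct beat times from NCC peak lags
#'
#' An NCC peak at lag `k` means the template matched the window starting at
#' sample `k`; the beat is reported at the template's anchor (its envelope
#' peak), i.e. at time `(k + anchor_offset_samples) / fs`. Reporting at the
#' anchor makes beat times comparable across templates.
#'
#' @param peak_lags 0-based lags from [detect_ncc_peaks()].
#' @param template the matching `heartbeat_template`.
#' @param fs sampling rate in Hz.
#' @param ncc optional `ncc_series`, to record the NCC value at each peak.
#' @return a `beat_detections`: list with `beat_times_s`, `ncc_at_peak`,
#'   `template_ref`.
#' @export
beats_from_ncc_peaks <- function(peak_lags, template, fs, ncc = NULL) {
  stopifnot(inherits(template, "heartbeat_template"))
  times <- (peak_lags + template$anchor_offset_samples) / fs
  vals <- if (!is.null(ncc)) ncc$values[peak_lags + 1L]
          else rep(NA_real_, length(peak_lags))
  structure(list(beat_times_s = times, ncc_at_peak = vals,
                 template_ref = template$source_window_index),
            class = "beat_detections")
}

#' Inter-beat intervals from detected beats
#'
#' @param beats a `beat_detections`, or a numeric vector of beat times in
#'   seconds.
#' @return an `ibi_series`: list with `ibis_ms` (consecutive differences in
#'   milliseconds) and `valid_mask` (all `TRUE` until error exclusion).
#' @export
compute_ibis <- function(beats) {
  times <- if (inherits(beats, "beat_detections")) beats$beat_times_s
           else as.numeric(beats)
  if (is.unsorted(times))
    cm_error("beat times must be sorted", "cardiomatch_precondition_error")
  ibis <- diff(times) * 1000
  structure(list(ibis_ms = ibis, valid_mask = rep(TRUE, length(ibis))),
            class = "ibi_series")
}

#' End-to-end ECG-free heartbeat detection
#'
#' Runs the full template-matching pipeline on one cardiomechanical channel:
#' oversampling to 1 kHz if the record is sampled below
#' `cfg$resample_below_hz`, role-specific conditioning
#' ([preprocess_channel()]), automatic template selection
#' ([auto_select_template()]), normalized cross-correlation of the template
#' against the whole conditioned signal, NCC peak detection and beat-time
#' reconstruction. All intermediates are returned for inspection.
#'
#' @param record a `waveform_record`.
#' @param channel channel name; defaults to the first channel.
#' @param role override the stored channel role; must be one of `"scg"`,
#'   `"gcg"`, `"fcg_raw"`, `"dhf_fcg"`.
#' @param cfg a [detector_config()].
#' @return a `heartbeat_detection`: list with `beats` (`beat_detections`),
#'   `template` (`heartbeat_template`), `ncc` (`ncc_series`), `ibis`
#'   (`ibi_series`), `fs` (rate the detection ran at), `record_id`.
#' @export
detect_heartbeats <- function(record, channel = NULL, role = NULL,
                              cfg = detector_config()) {
  stopifnot(inherits(record, "waveform_record"))
  if (is.null(channel)) channel <- names(record$samples)[1]
  if (is.null(role)) role <- record$channel_roles[[channel]]
  if (!role %in% c("scg", "gcg", "fcg_raw", "dhf_fcg"))
    cm_error(paste0("role '", role, "' is not a cardiomechanical channel"),
             "cardiomatch_config_error")
  if (record$fs < cfg$resample_below_hz)
    record <- resample_linear(record, cfg$resample_to_hz)
  fs <- record$fs
  if (length(record$samples[[1]]) < cfg$window_s * fs)
    cm_error("record shorter than one template-search window",
             "cardiomatch_length_error")
  x <- preprocess_channel(record, channel, role, cfg)
  tpl <- auto_select_template(x, fs, cfg)
  ncc <- normalized_cross_correlation(x, tpl$waveform, fs = fs)
  lags <- detect_ncc_peaks(ncc, cfg)
  beats <- beats_from_ncc_peaks(lags, tpl, fs, ncc)
  structure(list(beats = beats, template = tpl, ncc = ncc,
                 ibis = compute_ibis(beats), fs = fs,
                 record_id = record$record_id),
            class = "heartbeat_detection")
}

#' @export
print.heartbeat_detection <- function(x, ...) {
  cat(sprintf("<heartbeat_detection '%s'>  %d beats @ %g Hz, template from window %d\n",
              x$record_id, length(x$beats$beat_times_s), x$fs,
              x$template$source_window_index))
  if (length(x$ibis$ibis_ms))
    cat(sprintf("  mean IBI %.1f ms (%.1f bpm)\n", mean(x$ibis$ibis_ms),
                60000 / mean(x$ibis$ibis_ms)))
  invisible(x)
}
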