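#' Heartbeat envelope of a signal segment
#'
#' Raises the segment to the 4th power, low-pass filters it at 3 Hz with a
#' 2nd order zero-lag Butterworth filter, clips negative filter ripple at
#' zero, and normalizes to the maximum within the segment. On the resulting
#' 0--1 scale each heartbeat's vibration packet appears as one smooth bump.
#'
#' @param segment numeric signal segment (>= 1 s of samples).
#' @param fs sampling rate in Hz.
#' @param cfg a [detector_config()].
#' @param window_start_s offset of the segment within its parent record, in
#'   seconds (provenance only).
#' @return an `envelope_series`: list with `values` (normalized envelope),
#'   `fs`, `window_start_s`.
#' @export
compute_envelope <- function(segment, fs, cfg = detector_config(),
                             window_start_s = 0) {
  if (length(segment) < fs)
    cm_error("segment shorter than 1 s", "cardiomatch_length_error")
  pw <- segment^cfg$env_power
  env <- butterworth_zero_lag(pw, fs, cfg$env_lp_hz,
                              order = cfg$env_lp_order, type = "low")
  env[env < 0] <- 0
  m <- max(env)
  if (!is.finite(m) || m <= 0)
    cm_error("degenerate (flat) segment: envelope has no energy",
             "cardiomatch_degenerate_segment_error")
  structure(list(values = env / m, fs = fs, window_start_s = window_start_s),
            class = "envelope_series")
}

#' Locate heartbeat peaks on a normalized envelope
#'
#' Local maxima with topographic prominence of at least
#' `cfg$env_min_prominence` (0.25 on the normalized 0--1 scale) are taken as
#' individual heartbeats.
#'
#' @param env an `envelope_series` from [compute_envelope()].
#' @param cfg a [detector_config()].
#' @return segment-relative beat times in seconds, increasing (possibly
#'   empty).
#' @export
detect_envelope_peaks <- function(env, cfg = detector_config()) {
  stopifnot(inherits(env, "envelope_series"))
  pk <- find_peaks(env$values, min_prominence = cfg$env_min_prominence)
  (pk$index - 1L) / env$fs
}

#' Reliability assessment of a template-search window
#'
#' A 10 s window is considered reliable for template selection when at least
#' `min_beats` heartbeats were found on its envelope and the mean absolute
#' deviation (MAD) of the inter-beat intervals is below `mad_threshold_ms`.
#' The beat-count floor assumes a minimum plausible heart rate of 30 bpm;
#' the MAD bound is set just above the 99th-percentile SDNN expected in
#' atrial fibrillation, so genuine arrhythmia is not rejected while windows
#' riddled with spurious envelope peaks are.
#'
#' @param beat_times sorted beat times in seconds.
#' @param cfg a [detector_config()].
#' @return a `window_reliability`: list with `n_beats`, `ibis_ms`, `mad_ms`,
#'   `reliable`, `reasons` (character subset of `too_few_beats`,
#'   `high_mad`).
#' @export
assess_window_reliability <- function(beat_times, cfg = detector_config()) {
  if (is.unsorted(beat_times))
    cm_error("beat times must be sorted", "cardiomatch_precondition_error")
  n <- length(beat_times)
  ibis <- if (n >= 2L) diff(beat_times) * 1000 else numeric(0)
  mad_ms <- if (length(ibis)) mean(abs(ibis - mean(ibis))) else 0
  reasons <- character(0)
  if (n < cfg$min_beats) reasons <- c(reasons, "too_few_beats")
  if (length(ibis) && mad_ms >= cfg$mad_threshold_ms)
    reasons <- c(reasons, "high_mad")
  structure(list(n_beats = n, ibis_ms = ibis, mad_ms = mad_ms,
                 reliable = length(reasons) == 0L, reasons = reasons),
            class = "window_reliability")
}

#' Segment candidate heartbeats around envelope peaks
#'
#' Cuts one candidate segment per beat, spanning `seg_pre_ms` before to
#' `seg_post_ms` after the envelope peak (200 to 500 ms by default). Beats
#' whose full support does not fit inside the segment are dropped. All
#' candidates share the same length and the same anchor offset (the sample
#' at the originating envelope-peak time).
#'
#' @param segment the signal segment the beats were found in.
#' @param fs sampling rate in Hz.
#' @param beat_times segment-relative beat times in seconds.
#' @param cfg a [detector_config()].
#' @return a `template_candidates`: list with `candidates` (list of
#'   equal-length numeric vectors), `anchor_offset_samples` (0-based),
#'   `beat_times_s`.
#' @export
segment_candidate_beats <- function(segment, fs, beat_times,
                                    cfg = detector_config()) {
  pre <- as.integer(round(cfg$seg_pre_ms * fs / 1000))
  post <- as.integer(round(cfg$seg_post_ms * fs / 1000))
  n <- length(segment)
  idx <- as.integer(round(beat_times * fs))    # 0-based sample of each peak
  ok <- idx - pre >= 0L & idx + post <= n - 1L
  cands <- lapply(idx[ok], function(i) segment[(i - pre):(i + post) + 1L])
  if (length(cands) < 2L)
    cm_error("fewer than 2 candidate beats fit inside the segment",
             "cardiomatch_insufficient_candidates_error")
  structure(list(candidates = cands, anchor_offset_samples = pre,
                 beat_times_s = beat_times[ok]),
            class = "template_candidates")
}

#' Score candidates and select the heartbeat template
#'
#' Computes the Pearson correlation of every candidate with every other
#' candidate (all vs. all, self excluded). Each candidate is scored by the
#' ratio of the mean to the sample standard deviation of its `n - 1`
#' correlations; the candidate with the highest score becomes the template.
#' This favours the beat that is most similar, most consistently, to all
#' others -- the one expected to match the most heartbeats in the full
#' signal. A zero standard deviation is floored at 1e-12; exact score ties
#' resolve to the earliest beat.
#'
#' @param cands a `template_candidates` from [segment_candidate_beats()].
#' @param fs sampling rate in Hz (recorded in the template).
#' @param source_window_index 0-based index of the originating 10 s window.
#' @param window_start_s record-absolute start time of that window.
#' @return a `heartbeat_template`: list with `waveform`, `fs`,
#'   `anchor_offset_samples`, `source_window_index`, `score`, `scores` (all
#'   candidate scores), `beat_time_s` (record-absolute anchor time).
#' @export
score_and_select_template <- function(cands, fs = NA_real_,
                                      source_window_index = 0L,
                                      window_start_s = 0) {
  stopifnot(inherits(cands, "template_candidates"))
  xs <- cands$candidates
  nc <- length(xs)
  if (nc < 2L)
    cm_error("need at least 2 candidates", "cardiomatch_precondition_error")
  lens <- vapply(xs, length, integer(1))
  if (length(unique(lens)) != 1L)
    cm_error("candidates must all have the same length",
             "cardiomatch_precondition_error")
  if (any(vapply(xs, function(v) var(v) == 0, logical(1))))
    cm_error("flat (zero-variance) candidate segment",
             "cardiomatch_degenerate_candidate_error")
  cmat <- cor(do.call(cbind, xs))
  scores <- vapply(seq_len(nc), function(i) {
    r <- cmat[i, -i]
    mean(r) / max(sd(r), 1e-12)
  }, numeric(1))
  best <- which(scores == max(scores))[1]   # earliest beat wins ties
  structure(list(waveform = xs[[best]], fs = fs,
                 anchor_offset_samples = cands$anchor_offset_samples,
                 source_window_index = as.integer(source_window_index),
                 score = scores[best], scores = scores,
                 beat_time_s = window_start_s + cands$beat_times_s[best]),
            class = "heartbeat_template")
}

#' @export
print.heartbeat_template <- function(x, ...) {
  cat(sprintf(paste0("<heartbeat_template>  %d samples @ %g Hz, anchor %d, ",
                     "window %d, score %.3g\n"),
              length(x$waveform), x$fs, x$anchor_offset_samples,
              x$source_window_index, x$score))
  invisible(x)
}

#' Fully automatic heartbeat-template selection
#'
#' Scans consecutive non-overlapping 10 s windows from the start of the
#' (already pre-processed) signal. In each window it computes the heartbeat
#' envelope, locates envelope peaks, and applies the reliability gate
#' ([assess_window_reliability()]). The first reliable window is segmented
#' into candidate beats and scored ([score_and_select_template()]); the
#' winning segment is returned as the template with record-absolute
#' provenance. A trailing partial window is not searched.
#'
#' @param x pre-processed cardiomechanical signal.
#' @param fs sampling rate in Hz.
#' @param cfg a [detector_config()].
#' @return a `heartbeat_template`; additionally carries
#'   `windows_examined`, a list of per-window `window_reliability` results.
#' @export
auto_select_template <- function(x, fs, cfg = detector_config()) {
  wlen <- as.integer(round(cfg$window_s * fs))
  if (length(x) < wlen)
    cm_error("signal shorter than one template-search window",
             "cardiomatch_length_error")
  n_windows <- length(x) %/% wlen
  examined <- vector("list", n_windows)
  for (w in seq_len(n_windows) - 1L) {
    seg <- x[(w * wlen + 1L):((w + 1L) * wlen)]
    env <- tryCatch(
      compute_envelope(seg, fs, cfg, window_start_s = w * wlen / fs),
      cardiomatch_degenerate_segment_error = function(e) NULL)
    if (is.null(env)) {
      examined[[w + 1L]] <- assess_window_reliability(numeric(0), cfg)
      next
    }
    beats <- detect_envelope_peaks(env, cfg)
    rel <- assess_window_reliability(beats, cfg)
    examined[[w + 1L]] <- rel
    if (!rel$reliable) next
    cands <- tryCatch(segment_candidate_beats(seg, fs, beats, cfg),
                      cardiomatch_insufficient_candidates_error =
                        function(e) NULL)
    if (is.null(cands)) next
    tpl <- tryCatch(
      score_and_select_template(cands, fs = fs, source_window_index = w,
                                window_start_s = w * wlen / fs),
      cardiomatch_degenerate_candidate_error = function(e) NULL)
    if (is.null(tpl)) next
    tpl$windows_examined <- examined[seq_len(w + 1L)]
    return(tpl)
  }
  cm_error("no reliable 10 s window found in the record",
           "cardiomatch_no_reliable_window_error")
}

#' Export a heartbeat template to CSV plus a YAML sidecar
#'
#' The CSV has columns `sample` (0-based) and `value`; the sidecar
#' (`<path>.meta.yaml`) stores `fs`, `anchor_offset_samples`,
#' `source_window_index` and `score`.
#'
#' @param path output CSV path.
#' @param template a `heartbeat_template`.
#' @return `path`, invisibly.
#' @export
write_template_csv <- function(path, template) {
  stopifnot(inherits(template, "heartbeat_template"))
  df <- data.frame(sample = seq_along(template$waveform) - 1L,
                   value = template$waveform)
  write.csv(df, path, row.names = FALSE)
  meta <- template[c("fs", "anchor_offset_samples", "source_window_index",
                     "score")]
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a heartbeat template written by [write_template_csv()]
#' @param path CSV path; expects the `.meta.yaml` sidecar alongside.
#' @return a `heartbeat_template`.
#' @export
read_template_csv <- function(path) {
  if (!file.exists(path))
    cm_error(paste0("file not found: ", path), "cardiomatch_io_error")
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path))
    cm_error(paste0("missing template sidecar: ", meta_path),
             "cardiomatch_io_error")
  meta <- yaml::read_yaml(meta_path)
  structure(list(waveform = df$value, fs = meta$fs,
                 anchor_offset_samples = as.integer(meta$anchor_offset_samples),
                 source_window_index = as.integer(meta$source_window_index),
                 score = meta$score, scores = NULL, beat_time_s = NA_real_),
            class = "heartbeat_template")
}
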