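#' Detector configuration
#'
#' All tunable parameters of the detection pipeline, with the published
#' defaults. Units are embedded in the field names (`_hz`, `_ms`, `_s`).
#'
#' @param band_low_hz,band_high_hz,bp_order cardiomechanical band-pass:
#'   7--30 Hz, 4th order, applied zero-lag (forward-backward).
#' @param env_lp_hz,env_lp_order,env_power,env_min_prominence envelope used
#'   for template selection: the signal is raised to `env_power` (4), low-pass
#'   filtered at 3 Hz (2nd order, zero-lag), normalized to its maximum, and
#'   peaks with topographic prominence >= 0.25 are taken as heartbeats.
#' @param window_s,min_beats,mad_threshold_ms reliability gate for the 10 s
#'   template-search windows: at least 5 envelope beats (a 30 bpm floor over
#'   10 s) and a mean absolute deviation of the inter-beat intervals below
#'   335 ms (the 99th-percentile bound of atrial-fibrillation SDNN,
#'   117.9 + 3*72.2 = 334.5 ms, rounded up).
#' @param seg_pre_ms,seg_post_ms candidate-beat segmentation around each
#'   envelope peak: 200 ms before to 500 ms after.
#' @param ncc_min_prominence,ncc_min_distance_s peak picking on the NCC
#'   trace: prominence >= 0.5 and at least 0.5 s between beats.
#' @param savgol_order,savgol_frame_s Savitzky-Golay respiration estimate
#'   subtracted from raw FCG: order 3, frame of about 1.5 s.
#' @param ecg_band,ecg_bp_order,notch_base_hz,notch_n_harmonics,notch_q ECG
#'   conditioning: 0.5--40 Hz band-pass plus a powerline notch bank (50 Hz
#'   base by default, harmonics up to Nyquist, biquad Q = 35).
#' @param resample_below_hz records sampled below this rate are linearly
#'   oversampled to `resample_to_hz` before detection.
#' @param resample_to_hz target rate for oversampling (1 kHz).
#' @return an object of class `detector_config` (a validated list).
#' @export
detector_config <- function(band_low_hz = 7, band_high_hz = 30, bp_order = 4,
                            env_lp_hz = 3, env_lp_order = 2, env_power = 4,
                            env_min_prominence = 0.25,
                            window_s = 10, min_beats = 5,
                            mad_threshold_ms = 335,
                            seg_pre_ms = 200, seg_post_ms = 500,
                            ncc_min_prominence = 0.5,
                            ncc_min_distance_s = 0.5,
                            savgol_order = 3, savgol_frame_s = 1.5,
                            ecg_band = c(0.5, 40), ecg_bp_order = 4,
                            notch_base_hz = 50, notch_n_harmonics = Inf,
                            notch_q = 35,
                            resample_below_hz = 500, resample_to_hz = 1000) {
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              bp_order = bp_order, env_lp_hz = env_lp_hz,
              env_lp_order = env_lp_order, env_power = env_power,
              env_min_prominence = env_min_prominence, window_s = window_s,
              min_beats = min_beats, mad_threshold_ms = mad_threshold_ms,
              seg_pre_ms = seg_pre_ms, seg_post_ms = seg_post_ms,
              ncc_min_prominence = ncc_min_prominence,
              ncc_min_distance_s = ncc_min_distance_s,
              savgol_order = savgol_order, savgol_frame_s = savgol_frame_s,
              ecg_band = ecg_band, ecg_bp_order = ecg_bp_order,
              notch_base_hz = notch_base_hz,
              notch_n_harmonics = notch_n_harmonics, notch_q = notch_q,
              resample_below_hz = resample_below_hz,
              resample_to_hz = resample_to_hz)
  scalars <- setdiff(names(cfg), "ecg_band")
  for (nm in scalars) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      cm_error(paste0("`", nm, "` must be a positive scalar"),
               "cardiomatch_config_error")
  }
  if (length(cfg$ecg_band) != 2L || any(cfg$ecg_band <= 0) ||
      cfg$ecg_band[1] >= cfg$ecg_band[2])
    cm_error("`ecg_band` must be increasing positive cutoffs",
             "cardiomatch_config_error")
  if (cfg$band_low_hz >= cfg$band_high_hz)
    cm_error("`band_low_hz` must be below `band_high_hz`",
             "cardiomatch_config_error")
  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Derivation of the reliability-gate defaults
#'
#' Recomputes the two gating parameters of [detector_config()] from their
#' physiological inputs. The minimum beat count per window is the beat
#' count implied by a minimum plausible heart rate; the IBI-variability
#' bound is the upper end of the SDNN distribution reported for atrial
#' fibrillation (the arrhythmia with the highest rhythm variability),
#' `mean + 3 sd`, under a normality assumption -- variability above that
#' bound is more plausibly due to spurious envelope peaks than to rhythm.
#'
#' @param sdnn_mean_ms,sdnn_sd_ms mean and SD of the SDNN statistic in
#'   atrial fibrillation (117.9 +- 72.2 ms).
#' @param min_hr_bpm minimum plausible heart rate (30 bpm).
#' @param window_s window length (10 s).
#' @return list with `min_beats` (beats implied by `min_hr_bpm` over
#'   `window_s`), `sdnn_bound_ms` (`mean + 3 sd`) and `mad_threshold_ms`
#'   (the bound rounded up to the next millisecond).
#' @export
selection_gate_derivation <- function(sdnn_mean_ms = 117.9,
                                      sdnn_sd_ms = 72.2,
                                      min_hr_bpm = 30, window_s = 10) {
  bound <- sdnn_mean_ms + 3 * sdnn_sd_ms
  list(min_beats = min_hr_bpm / 60 * window_s,
       sdnn_bound_ms = bound,
       mad_threshold_ms = ceiling(bound))
}

#' Read a detector configuration from a YAML file
#'
#' Field names mirror [detector_config()] arguments exactly; unknown fields
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `detector_config`.
#' @export
read_detector_config <- function(path) {
  if (!file.exists(path))
    cm_error(paste0("file not found: ", path), "cardiomatch_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(detector_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    cm_error(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
             "cardiomatch_config_error")
  vals <- lapply(vals, function(v) if (identical(v, ".inf")) Inf else v)
  do.call(detector_config, vals)
}

#' Write a detector configuration to a YAML file
#' @param path output path.
#' @param cfg a `detector_config`.
#' @return `path`, invisibly.
#' @export
write_detector_config <- function(path, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
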