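#' Pan-Tompkins R-peak detection
#'
#' Standard Pan-Tompkins chain for locating QRS complexes in a conditioned
#' ECG: 5--15 Hz band-pass emphasis, derivative, squaring, 150 ms
#' moving-window integration, then adaptive dual signal/noise thresholds
#' with a 200 ms refractory period and RR-guided search-back for missed
#' beats. Accepted detections are refined to the local extremum of the
#' emphasised ECG within +-150 ms. Thresholds track running signal and noise
#' peak levels, so detection is invariant to amplitude rescaling.
#'
#' @param ecg ECG signal, ideally pre-conditioned with
#'   [preprocess_channel()] (`role = "ecg"`).
#' @param fs sampling rate in Hz.
#' @return R-peak times in seconds, increasing (empty for flat input).
#' @export
detect_r_peaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n < 10 * fs)
    cm_error("ECG shorter than 10 s", "cardiomatch_length_error")
  if (max(ecg) == min(ecg)) return(numeric(0))

  bp <- butterworth_zero_lag(ecg, fs, c(5, 15), order = 2, type = "pass")
  der <- c(diff(bp), 0) * fs
  sq <- der^2
  wlen <- max(1L, as.integer(round(0.15 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  mwi[is.na(mwi)] <- 0

  refractory <- as.integer(round(0.2 * fs))
  cand <- find_peaks(mwi, min_prominence = 0,
                     min_distance = refractory)$index
  if (!length(cand)) return(numeric(0))

  # threshold initialization from the first two seconds
  init <- mwi[1:min(n, 2 * fs)]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  accepted <- integer(0)
  rr_hist <- numeric(0)

  accept <- function(i) {
    spki <<- 0.125 * mwi[i] + 0.875 * spki
    accepted <<- c(accepted, i)
    if (length(accepted) >= 2L) {
      rr <- diff(tail(accepted, 2L))
      rr_hist <<- tail(c(rr_hist, rr), 8L)
    }
  }

  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    since_last <- if (length(accepted)) i - tail(accepted, 1L) else Inf
    if (mwi[i] > thr && since_last > refractory) {
      # search-back first: did we skip a beat over a long RR gap?
      if (length(rr_hist) >= 2L && is.finite(since_last) &&
          since_last > 1.66 * mean(rr_hist)) {
        lo <- tail(accepted, 1L) + refractory
        missed <- cand[cand > lo & cand < i - refractory]
        missed <- missed[mwi[missed] > npki + 0.125 * (spki - npki)]
        if (length(missed)) accept(missed[which.max(mwi[missed])])
      }
      accept(i)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(accepted)) return(numeric(0))

  # refine each detection to the extremum of the emphasised ECG; the MWI
  # peak lags the QRS by up to the integration window
  half <- as.integer(round(0.15 * fs))
  r_idx <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # collapse refinements that landed within the refractory of each other
  if (length(r_idx) > 1L) {
    keep <- c(TRUE, diff(r_idx) > refractory)
    r_idx <- r_idx[keep]
  }
  (r_idx - 1L) / fs
}
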