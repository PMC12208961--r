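#' Zero-phase (forward-backward) IIR filtering with reflective padding
#'
#' Applies `filter(b, a)` forward and backward so the net phase response is
#' zero and the magnitude response is squared. Edges are handled by odd
#' reflection of the signal about its endpoints before filtering, which keeps
#' start-up transients out of the returned samples.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal.
#' @param pad reflection length in samples; defaults to three times the
#'   filter order, clamped to `length(x) - 1`.
#' @return filtered signal, same length as `x`.
#' @keywords internal
filtfilt_reflect <- function(b, a, x, pad = NULL) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  if (is.null(pad)) pad <- 3L * (nfilt - 1L)
  if (n <= 3L * (nfilt - 1L))
    cm_error("signal too short for zero-phase filtering",
             "cardiomatch_length_error")
  pad <- min(pad, n - 1L)
  # odd (point-symmetric) extension, as is standard for zero-phase filtering
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back  <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(front, x, back)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

# pad long enough to settle the slowest pole: ~10 periods of the lowest
# cutoff (a 7 Hz band edge needs > 1 s to ring down below 1e-9), never less
# than the coefficient-based default
zero_lag_pad <- function(fs, lowest_hz, nfilt) {
  max(3L * (nfilt - 1L), as.integer(ceiling(10 * fs / lowest_hz)))
}

#' Zero-lag Butterworth filtering
#'
#' Designs a Butterworth filter of the stated order and applies it
#' forward-backward, so the output has exactly zero phase shift and the
#' effective magnitude response is the square of the single-pass response.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param cutoffs one cutoff (low/high-pass) or two (band-pass), in Hz.
#' @param order filter order as stated (the forward pass alone has this
#'   order).
#' @param type `"pass"`, `"low"` or `"high"`.
#' @return filtered signal, same length as `x`.
#' @export
butterworth_zero_lag <- function(x, fs, cutoffs, order = 4,
                                 type = c("pass", "low", "high")) {
  type <- match.arg(type)
  if (any(cutoffs <= 0) || any(cutoffs >= fs / 2))
    cm_error("cutoff frequencies must lie in (0, fs/2)",
             "cardiomatch_config_error")
  if (type == "pass" && length(cutoffs) != 2L)
    cm_error("band-pass needs two cutoffs", "cardiomatch_config_error")
  bt <- signal::butter(order, cutoffs / (fs / 2), type = type)
  pad <- zero_lag_pad(fs, min(cutoffs), max(length(bt$a), length(bt$b)))
  filtfilt_reflect(bt$b, bt$a, x, pad = pad)
}

# RBJ-cookbook second-order IIR notch at f0 with quality factor q
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Powerline notch bank
#'
#' Removes the powerline fundamental and its harmonics with second-order IIR
#' notches (quality factor `q`), each applied zero-lag. Harmonics at or above
#' Nyquist are silently skipped.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param base_hz powerline fundamental (50 Hz default; set 60 for 60 Hz
#'   mains).
#' @param n_harmonics number of harmonics to notch (`Inf` = all below
#'   Nyquist).
#' @param q notch quality factor (centre frequency / -3 dB bandwidth).
#' @return filtered signal, same length as `x`.
#' @export
notch_powerline <- function(x, fs, base_hz = 50, n_harmonics = Inf, q = 35) {
  if (base_hz <= 0 || base_hz >= fs / 2)
    cm_error("notch base frequency must lie in (0, fs/2)",
             "cardiomatch_config_error")
  kmax <- floor((fs / 2 - 1e-9) / base_hz)
  if (is.finite(n_harmonics)) kmax <- min(kmax, n_harmonics)
  for (k in seq_len(kmax)) {
    nf <- design_notch(k * base_hz, fs, q)
    pad <- zero_lag_pad(fs, base_hz, 3L)
    x <- filtfilt_reflect(nf$b, nf$a, x, pad = pad)
  }
  x
}

#' Respiration removal for raw forcecardiography
#'
#' Estimates the slow respiratory component with a Savitzky-Golay smoother
#' (polynomial order 3, frame of about 1.5 s) and subtracts it, isolating the
#' cardiac component of the raw force signal.
#'
#' @param x raw FCG signal.
#' @param fs sampling rate in Hz.
#' @param order polynomial order.
#' @param frame_s frame length in seconds; the frame used is the nearest odd
#'   number of samples, clamped to the signal length.
#' @return `x` minus its Savitzky-Golay smooth, same length.
#' @export
remove_respiration_savgol <- function(x, fs, order = 3, frame_s = 1.5) {
  n <- length(x)
  frame <- round(frame_s * fs)
  if (frame %% 2 == 0) frame <- frame + 1
  if (frame > n) frame <- if (n %% 2 == 1) n else n - 1L
  if (frame < order + 2 || n < order + 2)
    cm_error("signal shorter than the smoothing frame",
             "cardiomatch_length_error")
  x - as.numeric(signal::sgolayfilt(x, p = order, n = frame))
}

#' Forward-difference derivative
#'
#' `out[n] = (x[n+1] - x[n]) * fs`, in units of `x` per second; the output is
#' one sample shorter than the input.
#'
#' @param x numeric signal of length >= 2.
#' @param fs sampling rate in Hz.
#' @return derivative sequence of length `length(x) - 1`.
#' @export
forward_difference <- function(x, fs) {
  if (length(x) < 2L)
    cm_error("need at least 2 samples for a forward difference",
             "cardiomatch_length_error")
  diff(x) * fs
}

#' Role-specific signal conditioning
#'
#' Applies the conditioning chain appropriate to a channel's role:
#' \describe{
#'   \item{scg, gcg, dhf_fcg}{7--30 Hz zero-lag band-pass (extracts the
#'     high-frequency cardiac vibration band).}
#'   \item{fcg_raw}{Savitzky-Golay respiration removal, 7--30 Hz band-pass,
#'     then forward-difference derivative (the output is the dHF-FCG signal,
#'     one sample shorter than the input).}
#'   \item{ecg}{0.5--40 Hz band-pass plus the powerline notch bank.}
#' }
#'
#' @param record a `waveform_record`.
#' @param channel channel name; defaults to the first channel.
#' @param role override the role stored in the record.
#' @param cfg a [detector_config()].
#' @return the conditioned signal as a numeric vector.
#' @export
preprocess_channel <- function(record, channel = NULL, role = NULL,
                               cfg = detector_config()) {
  stopifnot(inherits(record, "waveform_record"))
  if (is.null(channel)) channel <- names(record$samples)[1]
  if (!channel %in% names(record$samples))
    cm_error(paste0("no channel named '", channel, "'"),
             "cardiomatch_config_error")
  if (is.null(role)) role <- record$channel_roles[[channel]]
  x <- record$samples[[channel]]
  fs <- record$fs
  switch(role,
    scg = ,
    gcg = ,
    dhf_fcg = butterworth_zero_lag(x, fs,
                                   c(cfg$band_low_hz, cfg$band_high_hz),
                                   order = cfg$bp_order, type = "pass"),
    fcg_raw = {
      cardiac <- remove_respiration_savgol(x, fs, order = cfg$savgol_order,
                                           frame_s = cfg$savgol_frame_s)
      hf <- butterworth_zero_lag(cardiac, fs,
                                 c(cfg$band_low_hz, cfg$band_high_hz),
                                 order = cfg$bp_order, type = "pass")
      forward_difference(hf, fs)
    },
    ecg = {
      bp <- butterworth_zero_lag(x, fs, cfg$ecg_band,
                                 order = cfg$ecg_bp_order, type = "pass")
      notch_powerline(bp, fs, base_hz = cfg$notch_base_hz,
                      n_harmonics = cfg$notch_n_harmonics, q = cfg$notch_q)
    },
    cm_error(paste0("no preprocessing chain for role '", role, "'"),
             "cardiomatch_config_error"))
}
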