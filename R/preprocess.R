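# forward-backward (zero-phase) filtering with odd-reflection padding so
# startup transients decay inside the pad, not the data; pad length covers
# several time constants of the slowest filter corner
zero_phase <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- n - 1L
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1):(pad + n)]
}

# apply a zero-phase filter row-wise, preserving recording metadata
filter_rows <- function(rec, filt, pad = NULL) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- zero_phase(filt, rec$data[i, ], pad = pad)
  }
  out
}

#' Power-line notch filter
#'
#' Second-order IIR notch (constrained biquad) centred at `f0`, applied
#' forward-backward so the net filter is zero-phase. At the default quality
#' factor the 50 Hz line component is attenuated by more than 95% while
#' frequencies 10 Hz away pass essentially unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param f0 Notch centre frequency in Hz (default 50).
#' @param q Quality factor, f0 / bandwidth (default 30).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, f0 = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (f0 >= rec$fs / 2) {
    stop(sprintf("notch frequency %g Hz is at or above Nyquist (%g Hz)",
                 f0, rec$fs / 2), call. = FALSE)
  }
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  # ring time ~ 2 q / w0; pad several of them
  pad <- ceiling(5 * q / (pi * f0) * rec$fs)
  filter_rows(rec, signal::Arma(b = b / a[1], a = a / a[1]), pad = pad)
}

#' Band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero-phase, so effective
#' 8th order with doubled attenuation and no group delay).
#'
#' @param rec An [eeg_recording()].
#' @param low,high Corner frequencies in Hz.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(0 < low && low < high && high < rec$fs / 2)) {
    stop(sprintf("invalid band (%g, %g) Hz for fs = %g", low, high, rec$fs),
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  pad <- ceiling(5 / (2 * pi * low) * rec$fs)   # slow corner dominates
  filter_rows(rec, bf, pad = pad)
}

#' Re-reference a recording
#'
#' Common-average reference: the instantaneous mean over channels is
#' subtracted from every channel, so per-sample channel sums are zero. The
#' operation is idempotent.
#'
#' @param rec An [eeg_recording()].
#' @param scheme Only `"average"` is implemented.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, scheme = c("average")) {
  stopifnot(inherits(rec, "eeg_recording"))
  scheme <- match.arg(scheme)
  if (nrow(rec$data) < 2L) {
    stop("re-referencing needs at least 2 channels", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Amplitude-threshold segment rejection
#'
#' Deterministic stand-in for visual inspection: the recording is cut into
#' consecutive windows and any window in which any channel exceeds
#' `threshold_uv` in absolute value is dropped; the remaining windows are
#' concatenated.
#'
#' @param rec An [eeg_recording()].
#' @param threshold_uv Rejection threshold in microvolts (default 150).
#' @param window_s Window length in seconds (default 1).
#' @param mask Optional data.frame of manually flagged bad intervals with
#'   columns `start_s`, `end_s`; any window overlapping one is dropped too.
#' @return The recording with rejected windows removed; the number of
#'   dropped windows is attached as attribute `"n_rejected"`.
#' @export
reject_segments <- function(rec, threshold_uv = 150, window_s = 1,
                            mask = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- as.integer(round(window_s * rec$fs))
  n <- ncol(rec$data)
  nwin <- n %/% w
  if (nwin == 0L) return(rec)
  keep <- rep(TRUE, nwin)
  for (j in seq_len(nwin)) {
    idx <- ((j - 1) * w + 1):(j * w)
    if (max(abs(rec$data[, idx])) > threshold_uv) keep[j] <- FALSE
    if (!is.null(mask)) {
      ws <- (j - 1) * w / rec$fs; we <- j * w / rec$fs
      if (any(mask$start_s < we & mask$end_s > ws)) keep[j] <- FALSE
    }
  }
  tail_idx <- if (nwin * w < n) (nwin * w + 1):n else integer(0)
  cols <- c(unlist(lapply(which(keep), function(j) ((j - 1) * w + 1):(j * w))),
            tail_idx)
  if (length(cols) == 0L) stop("all segments rejected", call. = FALSE)
  out <- eeg_recording(rec$data[, cols, drop = FALSE], rec$channels, rec$fs,
                       rec$subject_id)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Standard preprocessing chain
#'
#' Notch, band-pass, optional EEMD-ICA artifact suppression, amplitude-based
#' segment rejection, and common-average re-referencing, in that order.
#'
#' @param rec An [eeg_recording()].
#' @param config An [eeg_config()].
#' @param reject_uv Segment-rejection threshold in microvolts; NULL disables.
#' @return The preprocessed recording.
#' @export
preprocess <- function(rec, config = eeg_config(), reject_uv = 150) {
  rec <- notch_filter(rec, config$notch_hz)
  rec <- bandpass_filter(rec, config$bandpass[1], config$bandpass[2])
  if (config$eemd_ica) {
    rec <- suppress_artifacts(rec, seed = config$seed)
  }
  if (!is.null(reject_uv)) rec <- reject_segments(rec, reject_uv)
  rereference(rec)
}
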