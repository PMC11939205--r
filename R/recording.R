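#' Construct a multichannel EEG recording
#'
#' An `eeg_recording` holds one subject's multichannel EEG as a channels x
#' samples matrix in microvolts, together with channel labels, the sampling
#' rate, and a subject identifier. Channel order is authoritative: it is
#' preserved from the source file and propagated unchanged through every
#' downstream stage. The canonical montage used throughout is the 8-channel
#' 10-20 subset F3, F4, T3, C3, C4, T4, O1, O2, but arbitrary montages are
#' accepted.
#'
#' @param data Numeric matrix, one row per channel, samples in columns,
#'   microvolts. All values must be finite.
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `eeg_recording` with fields `data`, `channels`,
#'   `fs`, `subject_id`, and derived `duration_s = ncol(data) / fs`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(16), 2), c("F3", "F4"), fs = 4)
#' rec$duration_s
#' @export
eeg_recording <- function(data, channels, fs, subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  channels <- as.character(channels)
  if (length(channels) == 0L) stop("at least one channel label is required", call. = FALSE)
  if (nrow(data) != length(channels)) {
    stop(sprintf("channel count mismatch: %d labels but %d data rows",
                 length(channels), nrow(data)), call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("all samples must be finite", call. = FALSE)
  rownames(data) <- channels
  structure(
    list(data = data, channels = channels, fs = as.numeric(fs),
         subject_id = as.character(subject_id),
         duration_s = ncol(data) / as.numeric(fs)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d channels x %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, length(x$channels), ncol(x$data), x$fs, x$duration_s))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(x$channels, each = ncol(x$data)),
    time_s = rep(seq_len(ncol(x$data)) - 1, times = length(x$channels)) / x$fs,
    value = as.vector(t(x$data))
  )
}

#' Canonical frequency bands
#'
#' The four classical EEG bands used for narrowband phase extraction:
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @param names Optional character vector to subset/reorder the bands.
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' eeg_bands()
#' eeg_bands("alpha")
#' @export
eeg_bands <- function(names = NULL) {
  b <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low_hz = c(0.5, 4, 8, 13),
    high_hz = c(4, 8, 13, 30)
  )
  if (is.null(names)) return(b)
  miss <- setdiff(names, b$band)
  if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "), call. = FALSE)
  b[match(names, b$band), ]
}

band_spec <- function(band, fs) {
  # resolve a band name or a c(low, high) pair against Nyquist
  if (is.character(band)) {
    row <- eeg_bands(band)
    low <- row$low_hz; high <- row$high_hz; name <- row$band
  } else {
    stopifnot(is.numeric(band), length(band) == 2L)
    low <- band[1]; high <- band[2]; name <- sprintf("%g-%g Hz", low, high)
  }
  if (!(0 < low && low < high && high < fs / 2)) {
    stop(sprintf("band (%g, %g) Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, fs / 2), call. = FALSE)
  }
  list(name = name, low_hz = low, high_hz = high)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline: the entropy
#' embedding dimension and tolerance factor, the multiscale range, filter
#' corners, the FDR level, and the random seed.
#'
#' @param m Embedding dimension for sample entropy (integer >= 1).
#' @param r_factor Tolerance as a multiple of the original series' SD.
#' @param scales Integer vector of coarse-graining scale factors.
#' @param bands Character vector of band names to analyse.
#' @param notch_hz Power-line notch centre frequency in Hz.
#' @param bandpass Length-2 numeric, band-pass corners in Hz.
#' @param fdr_alpha Significance level for FDR-adjusted comparisons.
#' @param seed Integer seed controlling all randomness in a pipeline run.
#' @param eemd_ica Logical, run EEMD-ICA artifact suppression in the pipeline.
#' @param modules Character subset of `c("complexity", "connectivity")`.
#' @return A list of class `eeg_config`.
#' @export
eeg_config <- function(m = 2L, r_factor = 0.15, scales = 1:20,
                       bands = c("delta", "theta", "alpha", "beta"),
                       notch_hz = 50, bandpass = c(0.5, 45),
                       fdr_alpha = 0.05, seed = 1L, eemd_ica = FALSE,
                       modules = c("complexity", "connectivity")) {
  stopifnot(m >= 1, r_factor > 0, length(scales) >= 1, all(scales >= 1),
            length(bandpass) == 2L, bandpass[1] < bandpass[2],
            fdr_alpha > 0, fdr_alpha < 1)
  modules <- match.arg(modules, c("complexity", "connectivity"), several.ok = TRUE)
  eeg_bands(bands)  # validates names
  structure(list(m = as.integer(m), r_factor = r_factor,
                 scales = as.integer(scales), bands = bands,
                 notch_hz = notch_hz, bandpass = bandpass,
                 fdr_alpha = fdr_alpha, seed = as.integer(seed),
                 eemd_ica = isTRUE(eemd_ica), modules = modules),
            class = "eeg_config")
}
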