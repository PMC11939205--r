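# analytic signal via the frequency-domain method: zero negative
# frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

wrap_phase <- function(p) ((p + pi) %% (2 * pi)) - pi   # [-pi, pi)

#' Band-limited instantaneous phase
#'
#' Filters each channel into the requested band (4th-order Butterworth,
#' forward-backward) and takes the angle of the analytic signal obtained via
#' the Hilbert transform. Instantaneous phase is only well defined for
#' narrowband signals, hence the mandatory band-pass. Phases are wrapped to
#' `[-pi, pi)`.
#'
#' @param rec An [eeg_recording()].
#' @param band Band name (see [eeg_bands()]) or `c(low, high)` Hz.
#' @return A list of class `phase_series`: `theta` (channels x samples phase
#'   matrix), `channels`, `fs`, `band`.
#' @export
instantaneous_phase <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  spec <- band_spec(band, rec$fs)
  filtered <- bandpass_filter(rec, spec$low_hz, spec$high_hz)
  theta <- t(apply(filtered$data, 1, function(x) wrap_phase(Arg(analytic_signal(x)))))
  rownames(theta) <- rec$channels
  structure(list(theta = theta, channels = rec$channels, fs = rec$fs,
                 band = spec$name),
            class = "phase_series")
}

#' Prediction delay from phase sign changes
#'
#' The delay used to form "past" phase states: `delta = round(Ns * Nch / Npm)`
#' clamped to at least 1, where `Ns` is the number of samples, `Nch` the
#' number of channels, and `Npm` the total count of sign changes of the
#' wrapped phase across all channels and time steps. Faster oscillations
#' change sign more often and therefore get a shorter delay.
#'
#' @param phases A `phase_series` from [instantaneous_phase()].
#' @return Integer delay in samples.
#' @export
estimate_delay <- function(phases) {
  stopifnot(inherits(phases, "phase_series"))
  th <- phases$theta
  ns <- ncol(th); nch <- nrow(th)
  if (nch < 2L) stop("delay estimation needs >= 2 channels", call. = FALSE)
  npm <- sum(apply(th, 1, function(p) sum(diff(sign(p)) != 0)))
  if (npm == 0) stop("constant phase: no sign changes, delay undefined", call. = FALSE)
  max(1L, as.integer(round(ns * nch / npm)))
}

#' Scott-type histogram bin width
#'
#' `3.5 * sd(x) / N^(1/3)`. Applied to phase sequences, the number of bins
#' over the circular support is `ceiling(2 * pi / width)`.
#'
#' @param x Numeric vector (length >= 2, positive SD).
#' @return The bin width.
#' @examples
#' scott_bin_width(rnorm(1000))
#' @export
scott_bin_width <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s <= 0) stop("zero variance: bin width undefined", call. = FALSE)
  3.5 * s / n^(1 / 3)
}

phase_bins <- function(width) max(2L, as.integer(ceiling(2 * pi / width)))

# bin wrapped phases into 1..nb over [-pi, pi)
bin_phase <- function(theta, nb) {
  b <- floor((theta + pi) / (2 * pi) * nb) + 1L
  pmin(pmax(b, 1L), nb)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Phase transfer entropy between two phase sequences
#'
#' The transfer entropy from source phase `theta_x` to target phase
#' `theta_y`, estimated from 1-, 2- and 3-dimensional histograms of the
#' binned phases (plug-in estimator, natural log; empty bins contribute 0):
#' `PTE = H(y_t, y_t') + H(y_t', x_t') - H(y_t') - H(y_t, y_t', x_t')`,
#' where the primed states are the phases `delay` samples in the past.
#' Only overlapping samples enter the histograms. The plug-in estimate can
#' come out slightly negative from finite-sample bias.
#'
#' @param theta_x,theta_y Phase vectors in radians, equal length.
#' @param delay Prediction delay in samples (>= 1).
#' @param n_bins Number of phase bins; default derives the Scott width from
#'   the pooled pair of sequences.
#' @return PTE in nats.
#' @export
phase_transfer_entropy <- function(theta_x, theta_y, delay, n_bins = NULL) {
  n <- length(theta_x)
  if (length(theta_y) != n) stop("phase sequences must have equal length", call. = FALSE)
  delay <- as.integer(delay)
  if (delay < 1L) stop("delay must be >= 1 sample", call. = FALSE)
  if (n - delay < 2L) stop("delay leaves too few overlapping samples", call. = FALSE)
  if (is.null(n_bins)) {
    # sigma pooled over the pair, N the per-sequence sample count
    n_bins <- phase_bins(3.5 * stats::sd(c(theta_x, theta_y)) / n^(1 / 3))
  }
  nb <- as.integer(n_bins)
  t_now <- (delay + 1L):n
  yt <- bin_phase(theta_y[t_now], nb)
  ytp <- bin_phase(theta_y[t_now - delay], nb)
  xtp <- bin_phase(theta_x[t_now - delay], nb)
  m <- length(t_now)
  if (m < 10L * nb) {
    warning(sprintf("only %d samples for %d bins: histogram underfilled", m, nb))
  }
  h_ytp <- entropy_from_counts(tabulate(ytp, nb))
  h_yt_ytp <- entropy_from_counts(tabulate(yt + nb * (ytp - 1L), nb^2))
  h_ytp_xtp <- entropy_from_counts(tabulate(ytp + nb * (xtp - 1L), nb^2))
  h_3 <- entropy_from_counts(
    tabulate(yt + nb * (ytp - 1L) + nb^2 * (xtp - 1L), nb^3))
  h_yt_ytp + h_ytp_xtp - h_ytp - h_3
}

#' Directed phase transfer entropy
#'
#' Normalizes a pair of directed PTE values onto \[0, 1\]:
#' `dPTE = PTE_xy / (PTE_xy + PTE_yx)`. Values above 0.5 indicate net
#' information flow x to y, below 0.5 the reverse, and exactly 0.5 balanced
#' flow. Negative PTE estimates (finite-sample bias) are floored at 0 before
#' normalizing; if both directions are 0 the balanced value 0.5 is returned.
#'
#' @param pte_xy,pte_yx Directed PTE estimates in nats.
#' @return A scalar in \[0, 1\]. `dpte(a, b) + dpte(b, a) == 1`.
#' @examples
#' dpte(0.3, 0.1)  # 0.75
#' @export
dpte <- function(pte_xy, pte_yx) {
  a <- max(pte_xy, 0)
  b <- max(pte_yx, 0)
  if (a + b == 0) return(0.5)
  a / (a + b)
}

#' Band-wise directed connectivity of a recording
#'
#' Computes PTE for every ordered channel pair of a band-limited phase
#' representation, the dPTE normalization, and directed node strengths. One
#' prediction delay is shared per recording and band (pooled over channels,
#' see [estimate_delay()]), and one bin count is derived from the pooled
#' phase sample. Diagonal entries are undefined (NA), so node strengths
#' exclude self-flow.
#'
#' @param rec A preprocessed [eeg_recording()] with >= 2 channels.
#' @param band Band name or `c(low, high)` Hz.
#' @param delay Prediction delay in samples, or `"auto"` (default) to use
#'   [estimate_delay()].
#' @param n_bins Bin count, or `"auto"` (default) for the Scott rule on the
#'   pooled phases.
#' @return An object of class `pte_result`: matrices `pte` and `dpte`
#'   (source x target, NA diagonal), tibbles via [tidy()], vectors
#'   `in_strength` / `out_strength`, plus `band`, `delay`, `n_bins`.
#' @export
pte_matrix <- function(rec, band, delay = "auto", n_bins = "auto") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$channels) < 2L) stop("need >= 2 channels", call. = FALSE)
  ph <- instantaneous_phase(rec, band)
  if (identical(delay, "auto")) delay <- estimate_delay(ph)
  if (identical(n_bins, "auto")) {
    # sigma pooled over all channels' phases, N the per-channel sample count
    n_bins <- phase_bins(3.5 * stats::sd(as.vector(ph$theta)) /
                           ncol(ph$theta)^(1 / 3))
  }
  nch <- length(ph$channels)
  pte <- matrix(NA_real_, nch, nch, dimnames = list(ph$channels, ph$channels))
  for (i in seq_len(nch)) {
    for (j in seq_len(nch)) {
      if (i == j) next
      pte[i, j] <- phase_transfer_entropy(ph$theta[i, ], ph$theta[j, ],
                                          delay = delay, n_bins = n_bins)
    }
  }
  dp <- matrix(NA_real_, nch, nch, dimnames = dimnames(pte))
  for (i in seq_len(nch)) {
    for (j in seq_len(nch)) {
      if (i < j) {
        dp[i, j] <- dpte(pte[i, j], pte[j, i])
        dp[j, i] <- 1 - dp[i, j]
      }
    }
  }
  structure(list(
    subject_id = rec$subject_id,
    band = ph$band, pte = pte, dpte = dp,
    in_strength = colSums(pte, na.rm = TRUE),
    out_strength = rowSums(pte, na.rm = TRUE),
    delay = as.integer(delay), n_bins = as.integer(n_bins)
  ), class = "pte_result")
}

#' @export
print.pte_result <- function(x, ...) {
  cat(sprintf("<pte_result> subject '%s', band %s: %d channels, delay %d samples, %d bins\n",
              x$subject_id, x$band, length(x$in_strength), x$delay, x$n_bins))
  invisible(x)
}
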