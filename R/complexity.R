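#' Sample entropy
#'
#' SaEn(m, r) is the negative logarithm of the conditional probability that
#' two templates matching for `m` points (Chebyshev distance <= r,
#' self-matches excluded) also match for `m + 1` points:
#' `SaEn = ln B_m(r) - ln A_m(r)`, where `B` and `A` are the average
#' m- and (m+1)-point template match counts. Lower values indicate a more
#' regular, predictable signal. The tolerance is `r = r_factor * sd(x)`
#' unless an absolute `r` is supplied (as multiscale entropy does, fixing r
#' from the original series), so SaEn is invariant to amplitude scaling.
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.15).
#' @param r Absolute tolerance; overrides `r_factor` when given.
#' @return A non-negative scalar; 0 when every m-match extends to an
#'   (m+1)-match; `NA` (with a warning) when no (m+1)-template pair matches,
#'   since the statistic is undefined there and a silent zero would bias
#'   group means.
#' @examples
#' sample_entropy(sin(seq(0, 20 * pi, length.out = 500)))
#' sample_entropy(rnorm(500))
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.15, r = NULL) {
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  n <- length(x)
  if (n < m + 2L) {
    stop(sprintf("series of length %d too short for m = %d (need >= m + 2)",
                 n, m), call. = FALSE)
  }
  if (is.null(r)) r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r < 0) stop("tolerance r must be non-negative", call. = FALSE)
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  if (cnt[["B"]] == 0) {
    warning("no m-template matches; sample entropy undefined (NA)")
    return(NA_real_)
  }
  if (cnt[["A"]] == 0) {
    warning("no (m+1)-template matches; sample entropy undefined (NA)")
    return(NA_real_)
  }
  # ln B - ln A, i.e. -ln(A/B); A <= B so the value is >= 0
  log(cnt[["B"]]) - log(cnt[["A"]])
}

#' Coarse-grain a series
#'
#' Non-overlapping averaging over windows of `s` consecutive samples:
#' `y_j = mean(x[((j-1)s + 1):(j s)])`, `j = 1..floor(N/s)`. Trailing
#' samples that do not fill a window are dropped.
#'
#' @param x Numeric vector.
#' @param s Integer scale factor (>= 1, <= length(x)).
#' @return Numeric vector of length `floor(length(x) / s)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
coarse_grain <- function(x, s) {
  s <- as.integer(s)
  n <- length(x)
  if (s < 1L) stop("scale must be >= 1", call. = FALSE)
  if (s > n) stop("scale exceeds series length", call. = FALSE)
  if (s == 1L) return(x)
  nb <- n %/% s
  colMeans(matrix(x[seq_len(nb * s)], nrow = s))
}

#' Multiscale entropy
#'
#' Sample entropy of coarse-grained versions of the series over a range of
#' scale factors. The tolerance is fixed at `r_factor * sd(x)` of the
#' original (scale-1) series for every scale, so the curve reflects genuine
#' changes in regularity under averaging, not renormalization. Scales where
#' the statistic is undefined are reported `NA` and excluded from the
#' scale-averaged summary.
#'
#' @inheritParams sample_entropy
#' @param scales Integer vector of scale factors (default 1:20).
#' @return A tibble with columns `scale` and `value`; `attr(., "mse_mean")`
#'   holds the mean over the finite values.
#' @export
multiscale_entropy <- function(x, m = 2L, r_factor = 0.15, scales = 1:20) {
  n <- length(x)
  if (n %/% max(scales) < m + 2L) {
    stop("series too short for the largest scale factor", call. = FALSE)
  }
  r <- r_factor * stats::sd(x)
  vals <- vapply(scales, function(s) {
    suppressWarnings(sample_entropy(coarse_grain(x, s), m = m, r = r))
  }, 0.0)
  if (all(is.na(vals))) stop("sample entropy undefined at every scale", call. = FALSE)
  out <- tibble::tibble(scale = as.integer(scales), value = vals)
  attr(out, "mse_mean") <- mean(vals[is.finite(vals)])
  out
}

#' Per-channel complexity profile
#'
#' Sample entropy and the multiscale entropy curve for every channel of a
#' recording, in tidy form. Channels are processed independently, so
#' reordering channels only reorders rows. A channel whose entropy is
#' undefined is reported with `NA`, never zero.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance factor (default 0.15).
#' @param scales Scale factors (default 1:20).
#' @return A tibble of class `eeg_complexity` with columns `subject_id`,
#'   `channel`, `metric` (`"saen"`, `"mse_s<scale>"`, or `"mse_mean"`) and
#'   `value`.
#' @export
complexity_profile <- function(rec, m = 2L, r_factor = 0.15, scales = 1:20) {
  stopifnot(inherits(rec, "eeg_recording"))
  rows <- lapply(seq_along(rec$channels), function(i) {
    mse <- multiscale_entropy(rec$data[i, ], m = m, r_factor = r_factor,
                              scales = scales)
    saen <- if (1L %in% scales) {
      mse$value[mse$scale == 1L]
    } else {
      suppressWarnings(sample_entropy(rec$data[i, ], m = m, r_factor = r_factor))
    }
    tibble::tibble(
      subject_id = rec$subject_id,
      channel = rec$channels[i],
      metric = c("saen", paste0("mse_s", mse$scale), "mse_mean"),
      value = c(saen, mse$value, attr(mse, "mse_mean"))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eeg_complexity", class(out))
  out
}
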