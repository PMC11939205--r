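# Seeded evaluation without disturbing the caller's RNG stream. Derived
# seeds stay below 2^31 - 1.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

derive_seed <- function(seed, ...) {
  # fold extra integers into a child seed; keeps streams distinct per
  # subject/channel without consuming the parent stream
  k <- as.double(seed)
  for (v in c(...)) k <- (k * 69069 + as.double(v) * 12345 + 1) %% 2147483629
  as.integer(k)
}

#' Generate calibrated noise
#'
#' White noise is i.i.d. Gaussian; pink noise has a 1/f power spectral
#' density, shaped in the frequency domain. Both are standardized to zero
#' mean and unit variance. These are the reference signal classes for
#' entropy calibration: coarse-graining destroys white-noise irregularity
#' quickly while 1/f noise retains complexity across scales.
#'
#' @param n Length (>= 100).
#' @param kind `"white"` or `"pink"`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param gamma Spectral exponent for `"pink"` (PSD proportional to
#'   1/f^gamma; default 1).
#' @return Numeric vector of length `n`, mean 0, variance 1.
#' @examples
#' w <- gen_noise(1000, "white", seed = 1)
#' p <- gen_noise(1000, "pink", seed = 1)
#' @export
gen_noise <- function(n, kind = c("white", "pink"), seed = 1L, gamma = 1) {
  kind <- match.arg(kind)
  if (n < 100) stop("n must be >= 100", call. = FALSE)
  x <- with_seed(seed, {
    z <- stats::rnorm(n)
    if (kind == "white") z else shape_spectrum(z, gamma)
  })
  as.numeric(scale(x))
}

# multiply the spectrum of z by f^(-gamma/2), keeping DC at zero
shape_spectrum <- function(z, gamma) {
  n <- length(z)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                   # two-sided frequency index
  amp <- c(0, f[-1]^(-gamma / 2))
  Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / n
}

# zero-phase Butterworth band-pass; the same filter family the analysis
# stages use, so simulated band content matches what the estimators see
band_noise <- function(n, band, fs, order = 4) {
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / (fs / 2),
                       type = "pass")
  pad <- ceiling(5 / (2 * pi * band$low_hz) * fs)
  as.numeric(scale(zero_phase(bf, stats::rnorm(n), pad = pad)))
}

#' Generate a directionally coupled signal pair
#'
#' Produces two band-limited series where `x` drives `y`:
#' `y = (1 - k) * independent band noise + k * x delayed by lag + weak white
#' noise`. For `k > 0` the instantaneous phase of `x` predicts the future
#' phase of `y`, so directed phase-transfer-entropy estimators should assign
#' net information flow x -> y. At `k = 0` the pair is independent; at
#' `k = 1`, `lag = 0` the construction is exchangeable and flow is balanced.
#'
#' @param n Number of samples.
#' @param band Band name (see [eeg_bands()]) or `c(low, high)` in Hz.
#' @param k Coupling strength in \[0, 1\].
#' @param lag Delay in samples (>= 0).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_sd SD of the additive white observation noise (default 0.05).
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @examples
#' p <- gen_coupled_pair(2000, "alpha", k = 0.8, lag = 25, fs = 250, seed = 1)
#' @export
gen_coupled_pair <- function(n, band, k, lag, fs = 1000, seed = 1L,
                             noise_sd = 0.05) {
  if (k < 0 || k > 1) stop("coupling strength k must be in [0, 1]", call. = FALSE)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  spec <- band_spec(band, fs)
  with_seed(seed, {
    xf <- band_noise(n + lag, spec, fs)
    yi <- band_noise(n, spec, fs)
    x <- xf[(lag + 1):(lag + n)]
    y <- (1 - k) * yi + k * xf[1:n] + noise_sd * stats::rnorm(n)
    list(x = x, y = y)
  })
}

#' Simulation specification for one cohort group
#'
#' Describes how to synthesize a group's recordings: montage, sampling rate,
#' duration, the 1/f background exponent, oscillatory band content, directed
#' coupling edges, the complexity scale (the relative weight of broadband
#' noise against predictable oscillations -- lower values yield more regular
#' signals and hence lower sample entropy), and a blink-artifact rate.
#'
#' @param n_subjects Subjects in the group.
#' @param channels Channel labels (default the canonical 8-channel montage).
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration_s Recording length in seconds (default 60).
#' @param gamma Background spectral exponent (default 1).
#' @param complexity_scale Broadband-noise weight multiplier (default 1).
#' @param complexity_jitter SD of the per-subject log-normal jitter applied
#'   to `complexity_scale` (default 0.05).
#' @param osc_bands Band names given oscillatory content (default alpha).
#' @param osc_amp Amplitude of each oscillatory component relative to the
#'   unit-variance background (default 0.8).
#' @param coupling Tibble/data.frame of directed coupling edges with columns
#'   `from`, `to`, `band`, `k`, `lag` (samples), or NULL.
#' @param artifact_rate Blink-like transients per minute (default 0).
#' @param amp_uv Output scaling: target per-channel SD in microvolts
#'   (default 20).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects, channels = c("F3", "F4", "T3", "C3",
                                              "C4", "T4", "O1", "O2"),
                     fs = 1000, duration_s = 60, gamma = 1,
                     complexity_scale = 1, complexity_jitter = 0.05,
                     osc_bands = "alpha", osc_amp = 0.8,
                     coupling = NULL, artifact_rate = 0, amp_uv = 20) {
  n <- fs * duration_s
  if (abs(n - round(n)) > 1e-9) stop("fs * duration_s must be an integer", call. = FALSE)
  if (!is.null(coupling)) {
    coupling <- tibble::as_tibble(coupling)
    stopifnot(all(c("from", "to", "band", "k", "lag") %in% names(coupling)))
    if (any(coupling$k < 0 | coupling$k > 1)) {
      stop("coupling strength k must be in [0, 1]", call. = FALSE)
    }
    if (any(coupling$lag < 1)) stop("coupling lag must be >= 1 sample", call. = FALSE)
    bad <- setdiff(c(coupling$from, coupling$to), channels)
    if (length(bad)) {
      stop("coupling edge names channel(s) not in montage: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), channels = channels,
                 fs = fs, duration_s = duration_s, gamma = gamma,
                 complexity_scale = complexity_scale,
                 complexity_jitter = complexity_jitter,
                 osc_bands = osc_bands, osc_amp = osc_amp,
                 coupling = coupling, artifact_rate = artifact_rate,
                 amp_uv = amp_uv),
            class = "sim_spec")
}

#' Synthesize one recording
#'
#' Each channel is a standardized mixture of 1/f^gamma background noise
#' (weighted by the subject's complexity scale), band-limited oscillations,
#' any coupled components injected along the spec's directed edges, and
#' optional blink-like transients (0.3-0.5 s raised-cosine bumps,
#' frontally weighted). Deterministic given `seed`.
#'
#' @param spec A [sim_spec()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @return An [eeg_recording()]. The realized per-subject complexity scale is
#'   attached as attribute `"complexity_scale"`; the ground-truth artifact-free
#'   signal as attribute `"clean"` when `artifact_rate > 0`.
#' @export
gen_recording <- function(spec, subject_id = "s01", seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- as.integer(round(spec$fs * spec$duration_s))
  nch <- length(spec$channels)
  with_seed(seed, {
    cscale <- spec$complexity_scale *
      exp(stats::rnorm(1, 0, spec$complexity_jitter))
    data <- matrix(0, nch, n)
    for (i in seq_len(nch)) {
      bg <- shape_spectrum(stats::rnorm(n), spec$gamma)
      bg <- as.numeric(scale(bg))
      ch <- cscale * bg
      for (b in spec$osc_bands) {
        ch <- ch + spec$osc_amp * band_noise(n, band_spec(b, spec$fs), spec$fs)
      }
      data[i, ] <- ch
    }
    if (!is.null(spec$coupling)) {
      for (e in seq_len(nrow(spec$coupling))) {
        ed <- spec$coupling[e, ]
        lag <- as.integer(ed$lag)
        src <- band_noise(n + lag, band_spec(ed$band, spec$fs), spec$fs)
        i_from <- match(ed$from, spec$channels)
        i_to <- match(ed$to, spec$channels)
        data[i_from, ] <- data[i_from, ] + src[(lag + 1):(lag + n)]
        data[i_to, ] <- data[i_to, ] + ed$k * src[1:n]
      }
    }
    data <- data / apply(data, 1, stats::sd) * spec$amp_uv
    clean <- NULL
    if (spec$artifact_rate > 0) {
      clean <- data
      n_events <- stats::rpois(1, spec$artifact_rate * spec$duration_s / 60)
      topo <- blink_topography(spec$channels)
      for (ev in seq_len(n_events)) {
        dur <- stats::runif(1, 0.3, 0.5)
        w <- as.integer(round(dur * spec$fs))
        t0 <- sample.int(max(n - w, 1L), 1)
        amp <- stats::runif(1, 100, 200)
        bump <- amp * (1 - cos(2 * pi * seq_len(w) / w)) / 2
        data[, t0:(t0 + w - 1)] <- data[, t0:(t0 + w - 1)] +
          outer(topo, bump)
      }
    }
    rec <- eeg_recording(data, spec$channels, spec$fs, subject_id)
    attr(rec, "complexity_scale") <- cscale
    if (!is.null(clean)) {
      attr(rec, "clean") <- eeg_recording(clean, spec$channels, spec$fs,
                                          subject_id)
    }
    rec
  })
}

# blinks project mostly onto frontal electrodes; crude anterior-posterior
# falloff by 10-20 prefix
blink_topography <- function(channels) {
  w <- rep(0.2, length(channels))
  w[grepl("^F", channels)] <- 1
  w[grepl("^C", channels)] <- 0.45
  w[grepl("^T", channels)] <- 0.3
  w[grepl("^O", channels)] <- 0.1
  w
}

#' Synthesize a two-group cohort on disk
#'
#' Writes one csv recording per subject for each group spec and a YAML
#' manifest usable by [run_pipeline()]. Per-subject seeds are derived from
#' `seed`, so the whole cohort is reproducible.
#'
#' @param specs Named list of two [sim_spec()]s; names are the group labels.
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param paired If TRUE the two specs are treated as pre/post conditions of
#'   the same subjects and the manifest carries a `pair_id` per subject.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @return The manifest tibble (also written to `out_dir/manifest.yaml`).
#' @export
gen_cohort <- function(specs, out_dir, seed = 1L, paired = FALSE,
                       force = FALSE) {
  stopifnot(is.list(specs), length(specs) == 2L)
  labels <- names(specs)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("`specs` must be a named list with two distinct group labels", call. = FALSE)
  }
  if (any(vapply(specs, function(s) s$n_subjects, 1L) < 1L)) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  if (paired && specs[[1]]$n_subjects != specs[[2]]$n_subjects) {
    stop("paired designs need equal group sizes", call. = FALSE)
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("out_dir exists and is not empty; use force = TRUE", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in seq_along(specs)) {
    for (i in seq_len(specs[[g]]$n_subjects)) {
      sid <- if (paired) sprintf("s%02d", i) else sprintf("%s_s%02d", labels[g], i)
      sseed <- if (paired) derive_seed(seed, 0L, i) else derive_seed(seed, g, i)
      rec <- gen_recording(specs[[g]], sid, seed = if (paired)
        derive_seed(sseed, g) else sseed)
      fn <- sprintf("%s_%s.csv", labels[g], sid)
      write_recording(rec, file.path(out_dir, fn))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, group = labels[g], path = fn,
        pair_id = if (paired) sid else NA_character_)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$path <- file.path(out_dir, manifest$path)
  manifest
}
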