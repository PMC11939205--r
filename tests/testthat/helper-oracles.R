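# Independent oracles used across the suite. These deliberately use naive
# O(N^2) counting / plain table() tabulation so they share no code with the
# package implementations they check.

# brute-force sample entropy: double loop over ordered template pairs
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  log(B) - log(A)
}

# brute-force BH step-up: sort, multiply by n/rank, running minimum, cap
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# plug-in entropy of a joint sample via table()
brute_entropy <- function(...) {
  tab <- table(...)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p))
}

# brute-force PTE from binned phases via table()-based entropies
brute_pte <- function(theta_x, theta_y, delay, nb) {
  bin <- function(th) pmin(pmax(floor((th + pi) / (2 * pi) * nb) + 1, 1), nb)
  n <- length(theta_x)
  t_now <- (delay + 1):n
  yt <- bin(theta_y[t_now])
  ytp <- bin(theta_y[t_now - delay])
  xtp <- bin(theta_x[t_now - delay])
  brute_entropy(yt, ytp) + brute_entropy(ytp, xtp) -
    brute_entropy(ytp) - brute_entropy(yt, ytp, xtp)
}

# dominant spectral peak in Hz
peak_hz <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / n * fs
  half <- f > 0 & f <= fs / 2
  f[half][which.max(p[half])]
}

# small deterministic recording fixture
toy_recording <- function(nch = 3, n = 1000, fs = 250, seed = 42) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(nch * n), nch), paste0("ch", seq_len(nch)),
                fs, "toy")
}
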