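test_that("instantaneous phase of a pure tone advances at its frequency", {
  fs <- 1000
  n <- 10000
  t <- seq_len(n) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)),
                       c("a", "b"), fs)
  ph <- instantaneous_phase(rec, "alpha")
  expect_true(all(ph$theta >= -pi & ph$theta < pi))
  # unwrapped phase slope = 2*pi*10 rad/s within 1%, edges excluded
  mid <- 1000:9000
  unwrapped <- cumsum(c(ph$theta[1, mid[1]],
                        wrap_diff <- {
                          d <- diff(ph$theta[1, mid])
                          d - 2 * pi * round(d / (2 * pi))
                        }))
  slope <- coef(stats::lm(unwrapped ~ seq_along(unwrapped)))[2] * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # sin vs cos: constant quadrature offset
  dphi <- ph$theta[2, mid] - ph$theta[1, mid]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_lt(max(abs(abs(dphi) - pi / 2)), 0.02)

  expect_error(instantaneous_phase(rec, c(0.5, 600)), "fs/2")
})

test_that("delay estimation follows the sign-change formula and is monotone", {
  fs <- 1000
  n <- 4000
  t <- seq_len(n) / fs
  mk <- function(freq) {
    rec <- eeg_recording(rbind(sin(2 * pi * freq * t),
                               sin(2 * pi * freq * t + 1)), c("a", "b"), fs)
    instantaneous_phase(rec, c(max(0.6 * freq, 0.5), 1.5 * freq))
  }
  ph <- mk(10)
  npm <- sum(apply(ph$theta, 1, function(p) sum(diff(sign(p)) != 0)))
  expect_equal(estimate_delay(ph), max(1L, as.integer(round(n * 2 / npm))))
  # faster oscillations give shorter or equal delays
  expect_lte(estimate_delay(mk(20)), estimate_delay(mk(10)))
  expect_lte(estimate_delay(mk(40)), estimate_delay(mk(20)))

  const <- structure(list(theta = matrix(0.5, 2, 100), channels = c("a", "b"),
                          fs = 100, band = "x"), class = "phase_series")
  expect_error(estimate_delay(const), "sign changes")
})

test_that("Scott bin width is 3.5 sd / N^(1/3) and sets the phase bin count", {
  set.seed(8)
  x <- rnorm(1000)
  x <- x / sd(x)          # unit SD
  expect_equal(scott_bin_width(x), 0.35, tolerance = 1e-12)
  expect_equal(scott_bin_width(2 * x), 0.70, tolerance = 1e-12)
  expect_equal(ceiling(2 * pi / 0.35), 18)
  expect_error(scott_bin_width(rep(1, 10)), "zero variance")
  expect_error(scott_bin_width(1), "at least 2")
})

test_that("histogram entropies match a brute-force probability table", {
  set.seed(21)
  for (s in 1:5) {
    tx <- runif(800, -pi, pi)
    ty <- 0.6 * tx + 0.4 * runif(800, -pi, pi)
    ty <- atan2(sin(ty), cos(ty))
    for (nb in c(4, 8)) {
      expect_equal(phase_transfer_entropy(tx, ty, delay = 3, n_bins = nb),
                   brute_pte(tx, ty, 3, nb), tolerance = 1e-12)
    }
  }
})

test_that("identical inputs give symmetric PTE and balanced dPTE", {
  set.seed(3)
  th <- runif(2000, -pi, pi)
  p_fwd <- phase_transfer_entropy(th, th, delay = 5, n_bins = 8)
  p_bwd <- phase_transfer_entropy(th, th, delay = 5, n_bins = 8)
  expect_identical(p_fwd, p_bwd)
  expect_equal(dpte(p_fwd, p_bwd), 0.5)
})

test_that("dPTE normalization identities hold", {
  expect_equal(dpte(0.3, 0.1), 0.75)
  expect_equal(dpte(0.2, 0.2), 0.5)
  expect_equal(dpte(0, 0), 0.5)          # balanced by convention
  expect_equal(dpte(-0.01, 0.1), 0)      # negatives floored
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(dpte(a, b) + dpte(b, a), 1, tolerance = 1e-12)
  }
})

test_that("coupled pairs yield directed flow, independent pairs stay balanced", {
  hits <- 0
  devs <- numeric(10)
  for (s in 1:10) {
    p <- gen_coupled_pair(20000, "alpha", k = 0.8, lag = 25, fs = 1000,
                          seed = s)
    rec <- eeg_recording(rbind(p$x, p$y), c("x", "y"), 1000)
    ph <- instantaneous_phase(rec, "alpha")
    fwd <- phase_transfer_entropy(ph$theta[1, ], ph$theta[2, ], delay = 25)
    bwd <- phase_transfer_entropy(ph$theta[2, ], ph$theta[1, ], delay = 25)
    hits <- hits + (dpte(fwd, bwd) > 0.5)

    q <- gen_coupled_pair(20000, "alpha", k = 0, lag = 25, fs = 1000,
                          seed = 100 + s)
    rec0 <- eeg_recording(rbind(q$x, q$y), c("x", "y"), 1000)
    ph0 <- instantaneous_phase(rec0, "alpha")
    devs[s] <- abs(dpte(
      phase_transfer_entropy(ph0$theta[1, ], ph0$theta[2, ], delay = 25),
      phase_transfer_entropy(ph0$theta[2, ], ph0$theta[1, ], delay = 25)) - 0.5)
  }
  expect_gte(hits, 9)
  expect_lt(mean(devs), 0.05)
})

test_that("the connectivity matrix satisfies its structural invariants", {
  spec <- sim_spec(1, fs = 250, duration_s = 40)
  rec <- gen_recording(spec, "s", seed = 6)
  res <- pte_matrix(rec, "alpha")
  nch <- 8
  expect_true(all(is.na(diag(res$pte))))
  expect_equal(sum(!is.na(res$pte)), nch * (nch - 1))  # 56 directed entries
  expect_equal(sum(!is.na(res$dpte)), nch * (nch - 1))
  # antisymmetry
  offdiag <- res$dpte + t(res$dpte)
  expect_lt(max(abs(offdiag[!is.na(offdiag)] - 1)), 1e-9)
  # conservation: both strength totals equal total directed mass
  total <- sum(res$pte, na.rm = TRUE)
  expect_equal(sum(res$in_strength), total, tolerance = 1e-9)
  expect_equal(sum(res$out_strength), total, tolerance = 1e-9)
  expect_equal(unname(res$in_strength["F3"]), sum(res$pte[, "F3"], na.rm = TRUE))
  expect_equal(unname(res$out_strength["F3"]), sum(res$pte["F3", ], na.rm = TRUE))

  td <- tidy(res)
  expect_equal(nrow(td), 56)
  expect_equal(td$dpte[td$source == "F3" & td$target == "O1"],
               res$dpte["F3", "O1"])
  g <- glance(res)
  expect_equal(g$n_channels, 8)
})

test_that("an injected directed edge dominates the band's dPTE deviations", {
  hits <- 0
  for (s in 1:5) {
    spec <- sim_spec(1, duration_s = 30, fs = 500, osc_bands = character(0),
                     coupling = tibble::tibble(from = "F3", to = "O1",
                                               band = "alpha", k = 0.8,
                                               lag = 24))
    rec <- gen_recording(spec, "s", seed = s)
    res <- pte_matrix(rec, "alpha")
    dev <- abs(res$dpte - 0.5)
    hits <- hits + (dev["F3", "O1"] >= max(dev, na.rm = TRUE) - 1e-12 &&
                      res$dpte["F3", "O1"] > 0.5)
  }
  expect_gte(hits, 4)
})
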