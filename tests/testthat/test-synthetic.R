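test_that("white noise is uncorrelated, standardized, and seed-deterministic", {
  w <- gen_noise(1e4, "white", seed = 11)
  expect_equal(mean(w), 0, tolerance = 1e-12)
  expect_equal(sd(w), 1, tolerance = 1e-12)
  r1 <- cor(w[-1], w[-length(w)])
  expect_lt(abs(r1), 0.03)
  expect_identical(w, gen_noise(1e4, "white", seed = 11))
  expect_false(identical(w, gen_noise(1e4, "white", seed = 12)))
  expect_error(gen_noise(50, "white"), ">= 100")
})

test_that("pink noise has a log-log PSD slope near -1", {
  for (s in 1:3) {
    p <- gen_noise(1e4, "pink", seed = s)
    spec <- Mod(stats::fft(p))^2
    f <- seq_along(p) - 1
    idx <- which(f >= 5 & f <= length(p) / 4)  # away from DC and Nyquist
    fit <- stats::lm(log(spec[idx + 1]) ~ log(f[idx]))
    expect_gt(coef(fit)[2], -1.3)
    expect_lt(coef(fit)[2], -0.7)
  }
})

test_that("coupled pairs are deterministic and respect the exchangeable limit", {
  p <- gen_coupled_pair(5000, "alpha", k = 0.8, lag = 25, fs = 250, seed = 3)
  p2 <- gen_coupled_pair(5000, "alpha", k = 0.8, lag = 25, fs = 250, seed = 3)
  expect_identical(p, p2)
  expect_length(p$x, 5000)

  # k = 1, lag = 0: y is x plus weak white noise
  q <- gen_coupled_pair(5000, "alpha", k = 1, lag = 0, fs = 250, seed = 4,
                        noise_sd = 0.05)
  expect_gt(cor(q$x, q$y), 0.99)

  expect_error(gen_coupled_pair(1000, "alpha", k = 1.2, lag = 1), "\\[0, 1\\]")
  expect_error(gen_coupled_pair(1000, c(10, 200), k = 0.5, lag = 1, fs = 250),
               "Nyquist|fs/2")
})

test_that("lower complexity scale lowers sample entropy on every channel", {
  # generator calibration: small groups, short recordings
  saen_means <- function(cs, seeds) {
    rowMeans(vapply(seeds, function(s) {
      rec <- gen_recording(sim_spec(1, fs = 500, duration_s = 20,
                                    complexity_scale = cs), "x", seed = s)
      vapply(seq_along(rec$channels),
             function(i) sample_entropy(rec$data[i, ]), 0.0)
    }, numeric(8)))
  }
  lo <- saen_means(0.7, 1:5)
  hi <- saen_means(1.0, 101:105)
  expect_true(all(lo < hi))
})

test_that("artifact-free recordings stay within the background amplitude bound", {
  spec <- sim_spec(1, fs = 250, duration_s = 20, artifact_rate = 0)
  rec <- gen_recording(spec, "s", seed = 9)
  expect_null(attr(rec, "clean"))
  expect_lt(max(abs(rec$data)), 6 * spec$amp_uv)
  expect_identical(rec$data,
                   gen_recording(spec, "s", seed = 9)$data)
})

test_that("blink artifacts are frontal-weighted transients", {
  spec <- sim_spec(1, fs = 250, duration_s = 30, artifact_rate = 8)
  rec <- gen_recording(spec, "s", seed = 2)
  clean <- attr(rec, "clean")
  expect_s3_class(clean, "eeg_recording")
  contamination <- rowMeans((rec$data - clean$data)^2)
  frontal <- grepl("^F", rec$channels)
  expect_gt(min(contamination[frontal]), max(contamination[!frontal]))
})

test_that("cohort generation writes a usable manifest", {
  dir <- withr::local_tempdir()
  specs <- list(asd = sim_spec(3, fs = 100, duration_s = 10),
                td = sim_spec(3, fs = 100, duration_s = 10))
  man <- gen_cohort(specs, file.path(dir, "c1"), seed = 5)
  expect_equal(nrow(man), 6)
  expect_equal(sort(unique(man$group)), c("asd", "td"))
  expect_true(all(file.exists(man$path)))
  rec <- read_recording(man$path[1])
  expect_equal(rec$fs, 100)

  # refuses to clobber, obeys force
  expect_error(gen_cohort(specs, file.path(dir, "c1"), seed = 5), "force")
  expect_silent(suppressMessages(
    gen_cohort(specs, file.path(dir, "c1"), seed = 5, force = TRUE)))

  # paired design carries a pairing map of size n
  pm <- gen_cohort(list(pre = sim_spec(3, fs = 100, duration_s = 10),
                        post = sim_spec(3, fs = 100, duration_s = 10)),
                   file.path(dir, "c2"), seed = 5, paired = TRUE)
  expect_equal(length(unique(stats::na.omit(pm$pair_id))), 3)

  expect_error(gen_cohort(list(a = sim_spec(0), b = sim_spec(2)),
                          file.path(dir, "c3")), "at least one")
})
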