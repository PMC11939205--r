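test_that("BH adjustment equals brute-force step-up on random vectors", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(fdr_bh(p), brute_bh(p), tolerance = 1e-15)
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sensitivity analysis reproduces the exact noncentral-t solution", {
  d <- sensitivity_effect_size("independent", 24, 0.05, 0.80)
  expect_equal(d, 0.826, tolerance = 0.005)
  # self-consistency: the returned d gives back the requested power
  ncp <- d * sqrt(24 / 2)
  tcrit <- qt(0.975, 46)
  achieved <- pt(tcrit, 46, ncp, lower.tail = FALSE) + pt(-tcrit, 46, ncp)
  expect_equal(achieved, 0.80, tolerance = 1e-6)
  # monotone in power
  expect_gt(sensitivity_effect_size("independent", 24, power = 0.9), d)
  # paired design self-consistency
  dp <- sensitivity_effect_size("paired", 24, 0.05, 0.80)
  ncp_p <- dp * sqrt(24)
  tc <- qt(0.975, 23)
  expect_equal(pt(tc, 23, ncp_p, lower.tail = FALSE) + pt(-tc, 23, ncp_p),
               0.80, tolerance = 1e-6)
})

test_that("Pearson behaviour correlation handles exact linear relations", {
  x <- c(1, 3, 4, 6, 8, 9)
  expect_equal(correlate_behavior(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_behavior(x, -x)$r, -1)
  y <- c(2, 1, 5, 4, 8, 7)
  ct <- correlate_behavior(x, y)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_closed, tolerance = 1e-12)
  expect_error(correlate_behavior(x, rep(1, 6)), "zero variance")
  expect_error(correlate_behavior(1:2, 1:2), "n >= 3")
})

make_features <- function(a, b, feature = "f1", family = "fam") {
  tibble::tibble(
    subject_id = c(paste0("a", seq_along(a)), paste0("b", seq_along(b))),
    group = rep(c("g1", "g2"), c(length(a), length(b))),
    feature = feature, family = family, value = c(a, b))
}

test_that("group comparison matches closed-form t statistics", {
  cmp <- compare_groups(make_features(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(cmp$test, "independent_t")
  expect_equal(cmp$statistic, -3.674235, tolerance = 1e-6)
  # swapped groups negate t, p unchanged
  swapped <- make_features(c(4, 5, 6), c(1, 2, 3))
  cmp2 <- compare_groups(swapped)
  expect_equal(cmp2$statistic, -cmp$statistic, tolerance = 1e-12)
  expect_equal(cmp2$p_raw, cmp$p_raw, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- compare_groups(make_features(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
})

test_that("t-test operations match closed forms", {
  it <- independent_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(it$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(it$df, 4)
  expect_error(independent_t(c(1, 1), c(1, 1)), "zero pooled variance")

  pre <- c(10, 11, 12, 13)
  post <- pre + c(1, 1, 1, 2)      # differences with mean 1.25, sd 0.5
  pt_ <- paired_t(pre, post)
  expect_equal(pt_$statistic, 5.0, tolerance = 1e-12)  # 1.25 / (0.5 / 2)
  expect_equal(pt_$df, 3)
  # shift invariance: adding a constant to both arms leaves t unchanged
  expect_equal(paired_t(pre + 100, post + 100)$statistic, 5.0,
               tolerance = 1e-10)
  expect_error(paired_t(pre, pre), "zero difference variance")

  sw <- shapiro_wilk(qnorm(seq(0.02, 0.98, length.out = 24)))
  expect_gt(sw$W, 0.99)    # exact normal quantiles are almost perfectly linear
  expect_lt(shapiro_wilk(c(rep(-1, 12), rep(1, 12)) +
                           rnorm(24, sd = 1e-3))$p_value, 0.05)
  expect_error(shapiro_wilk(rep(2, 10)), "zero variance")
})

test_that("paired comparison gates on difference normality with shift invariance", {
  set.seed(88)
  pre <- rnorm(12, mean = 10)
  post <- pre + rnorm(12, mean = 1, sd = 0.5)
  feats <- tibble::tibble(
    subject_id = rep(paste0("s", 1:12), 2),
    pair_id = rep(paste0("s", 1:12), 2),
    group = rep(c("g1_pre", "g2_post"), each = 12),
    feature = "f1", value = c(pre, post))
  cmp <- compare_groups(feats, design = "paired")
  expect_equal(cmp$test, "paired_t")
  expect_equal(cmp$statistic, paired_t(pre, post)$statistic, tolerance = 1e-12)
  # shifting both arms leaves the statistic unchanged
  feats2 <- feats
  feats2$value <- feats2$value + 100
  expect_equal(compare_groups(feats2, design = "paired")$statistic,
               cmp$statistic, tolerance = 1e-9)
  # zero-difference degenerate case: flagged, p = 1
  feats3 <- feats
  feats3$value <- rep(pre, 2)
  cmp3 <- compare_groups(feats3, design = "paired")
  expect_equal(cmp3$p_raw, 1)
})

test_that("the normality gate routes non-normal data to rank tests", {
  set.seed(33)
  a <- rnorm(24); b <- rnorm(24)
  cmp_norm <- compare_groups(make_features(a, b))
  expect_true(cmp_norm$normality_ok)
  expect_equal(cmp_norm$test, "independent_t")
  # heavily bimodal data fails Shapiro-Wilk
  bi <- c(rep(-1, 12), rep(1, 12)) + rnorm(24, sd = 1e-3)
  cmp_bi <- compare_groups(make_features(bi, b))
  expect_false(cmp_bi$normality_ok)
  expect_equal(cmp_bi$test, "mann_whitney")
  expect_lt(shapiro.test(bi)$p.value, 0.05)
})

test_that("FDR families are adjusted separately and tidy/glance summarize", {
  set.seed(7)
  feats <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_features(rnorm(10), rnorm(10, mean = ifelse(i <= 2, 3, 0)),
                  feature = paste0("f", i),
                  family = ifelse(i <= 2, "shifted", "null"))
  }))
  cmp <- compare_groups(feats)
  expect_equal(nrow(cmp), 4)
  within_fam <- split(cmp, cmp$family)
  for (fam in within_fam) {
    expect_equal(fam$p_fdr, brute_bh(fam$p_raw), tolerance = 1e-12)
  }
  g <- glance(cmp)
  expect_equal(sort(g$family), c("null", "shifted"))
  expect_equal(g$n_significant[g$family == "shifted"], 2)
  td <- tidy(cmp)
  expect_false(inherits(td, "eeg_group_comparison"))
})

test_that("type-I error under the global null stays near nominal", {
  # moderate replication here; the full calibration runs in the acceptance suite
  set.seed(202)
  n_rep <- 100
  hits <- 0; total <- 0
  for (i in seq_len(n_rep)) {
    feats <- dplyr::bind_rows(lapply(1:5, function(k) {
      make_features(rnorm(24), rnorm(24), feature = paste0("f", k))
    }))
    cmp <- compare_groups(feats)
    hits <- hits + sum(cmp$p_raw < 0.05)
    total <- total + nrow(cmp)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.09)
})

test_that("permuting group labels destroys an injected difference", {
  set.seed(55)
  feats <- dplyr::bind_rows(lapply(1:6, function(k) {
    make_features(rnorm(12), rnorm(12, mean = 2), feature = paste0("f", k))
  }))
  expect_equal(sum(compare_groups(feats)$significant), 6)
  n_sig <- vapply(1:10, function(i) {
    perm <- feats |>
      dplyr::group_by(.data$feature) |>
      dplyr::mutate(group = sample(.data$group)) |>
      dplyr::ungroup()
    sum(compare_groups(perm)$significant)
  }, 0L)
  expect_equal(median(n_sig), 0)
})
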