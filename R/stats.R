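#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, delegated to
#' [stats::p.adjust()] with `method = "BH"`: sorted p-values are multiplied
#' by `n / rank`, a running minimum is taken from the largest down, and the
#' result is capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Minimal detectable effect size (sensitivity analysis)
#'
#' Solves for the Cohen's d at which a two-sided t-test reaches the
#' requested power, using the exact noncentral-t distribution: for the
#' independent design `df = 2n - 2` and noncentrality `d * sqrt(n / 2)`;
#' for the paired design `df = n - 1` and noncentrality `d * sqrt(n)`.
#' The root is located to a power error below 1e-6. With 24 subjects per
#' group, alpha 0.05 and power 0.80 the independent design gives d = 0.826.
#'
#' @param design `"independent"` or `"paired"`.
#' @param n Subjects per group (independent) or pairs (paired), >= 3.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return The minimal detectable Cohen's d.
#' @examples
#' sensitivity_effect_size("independent", 24)
#' @export
sensitivity_effect_size <- function(design = c("independent", "paired"),
                                    n, alpha = 0.05, power = 0.80) {
  design <- match.arg(design)
  stopifnot(n >= 3, alpha > 0, alpha < 1, power > 0, power < 1)
  df <- if (design == "independent") 2 * n - 2 else n - 1
  ncp_of_d <- if (design == "independent") {
    function(d) d * sqrt(n / 2)
  } else {
    function(d) d * sqrt(n)
  }
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- ncp_of_d(d)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
  }
  if (pow(10) < power) stop("no root in (0, 10): power unattainable", call. = FALSE)
  stats::uniroot(function(d) pow(d) - power, c(1e-6, 10), tol = 1e-10)$root
}

#' Correlate behavioural scores with connectivity features
#'
#' Pearson correlation with a two-sided p-value from the t-transform, for
#' relating per-subject behavioural-scale scores to dPTE (or any other
#' per-subject feature).
#'
#' @param scores,features Numeric vectors of equal length >= 3.
#' @return A tibble with columns `r`, `statistic`, `p_value`, `n`.
#' @export
correlate_behavior <- function(scores, features) {
  if (length(scores) != length(features) || length(scores) < 3L) {
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(scores) == 0 || stats::sd(features) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(scores, features, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 p_value = ct$p.value, n = length(scores))
}

#' Two-sample t-tests
#'
#' `independent_t()` is the two-sided Student (pooled-variance) t-test with
#' `df = n_a + n_b - 2`; `paired_t()` is the one-sample t on the
#' within-pair differences `post - pre` with `df = n - 1`. Both delegate to
#' [stats::t.test()]. These are the raw tests; [compare_groups()] adds the
#' normality gate, rank fallback and FDR adjustment around them.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return A tibble with columns `statistic`, `df`, `p_value`.
#' @examples
#' independent_t(c(1, 2, 3), c(4, 5, 6))
#' @export
independent_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group", call. = FALSE)
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' @rdname independent_t
#' @param pre,post Numeric vectors of equal length (pairs).
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  }
  if (stats::sd(post - pre) == 0) {
    stop("zero difference variance", call. = FALSE)
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (Royston's algorithm),
#' returning the W statistic and p-value used by the normality gate of
#' [compare_groups()].
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A tibble with columns `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("zero variance", call. = FALSE)
  ht <- stats::shapiro.test(x)
  tibble::tibble(W = unname(ht$statistic), p_value = ht$p.value)
}

# one feature's comparison: Shapiro-Wilk gate on both groups, then a Student
# (pooled-variance) t-test or the rank fallback
compare_one <- function(a, b, paired = FALSE, welch = FALSE) {
  normal_ok <- function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= 0.05
  }
  if (paired) {
    d <- b - a
    norm <- normal_ok(d)
    if (norm && stats::sd(d) > 0) {
      ht <- stats::t.test(b, a, paired = TRUE)
      return(list(test = "paired_t", statistic = unname(ht$statistic),
                  p = ht$p.value, normality_ok = TRUE))
    }
    if (stats::sd(d) == 0) {
      return(list(test = "paired_t", statistic = 0, p = 1,
                  normality_ok = norm, note = "zero difference variance"))
    }
    ht <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE, exact = FALSE))
    return(list(test = "wilcoxon", statistic = unname(ht$statistic),
                p = ht$p.value, normality_ok = FALSE))
  }
  norm <- normal_ok(a) && normal_ok(b)
  if (norm) {
    ht <- stats::t.test(a, b, var.equal = !welch)
    return(list(test = "independent_t", statistic = unname(ht$statistic),
                p = ht$p.value, normality_ok = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(test = "mann_whitney", statistic = unname(ht$statistic),
       p = ht$p.value, normality_ok = FALSE)
}

#' Group comparison with a normality gate and FDR control
#'
#' For every feature: Shapiro-Wilk on each group's values (or the paired
#' differences); when normality holds, a Student t-test (pooled variance;
#' set `welch = TRUE` for the unpooled variant), otherwise the rank fallback
#' (Mann-Whitney / Wilcoxon signed-rank), whose results are flagged
#' exploratory by `normality_ok = FALSE`. Benjamini-Hochberg adjustment is
#' applied within each feature family (`family` column, e.g. one metric
#' across channels or one band across edges), not globally.
#'
#' @param features A tidy tibble with columns `subject_id`, `group`,
#'   `feature`, `value`, and optionally `family` (defaults to a single
#'   family) and `pair_id` for paired designs.
#' @param design `"independent"` or `"paired"`. Paired designs compare the
#'   two groups within `pair_id`; the first group level (alphabetical, or
#'   factor order) is the baseline.
#' @param alpha Significance level for `significant = p_fdr < alpha`
#'   (default 0.05).
#' @param welch Use Welch's t instead of pooled variance (default FALSE).
#' @return A tibble of class `eeg_group_comparison` with one row per
#'   feature: `family`, `feature`, `test`, `statistic`, `p_raw`, `p_fdr`,
#'   `normality_ok`, `significant`, `n_a`, `n_b`.
#' @export
compare_groups <- function(features, design = c("independent", "paired"),
                           alpha = 0.05, welch = FALSE) {
  design <- match.arg(design)
  stopifnot(all(c("subject_id", "group", "feature", "value") %in% names(features)))
  if (!"family" %in% names(features)) features$family <- "all"
  groups <- sort(unique(as.character(features$group)))
  if (length(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  paired <- design == "paired"
  if (paired && !"pair_id" %in% names(features)) {
    stop("paired design requires a pair_id column", call. = FALSE)
  }

  rows <- features |>
    dplyr::group_by(.data$family, .data$feature) |>
    dplyr::group_map(function(df, key) {
      if (paired) {
        wide <- df |>
          dplyr::select("pair_id", "group", "value") |>
          tidyr::pivot_wider(names_from = "group", values_from = "value") |>
          tidyr::drop_na()
        a <- wide[[groups[1]]]; b <- wide[[groups[2]]]
      } else {
        a <- df$value[df$group == groups[1]]
        b <- df$value[df$group == groups[2]]
      }
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L || (paired && length(a) != length(b))) {
        warning(sprintf("feature '%s': fewer than 2 observations per group; test skipped",
                        key$feature))
        return(tibble::tibble(family = key$family, feature = key$feature,
                              test = NA_character_, statistic = NA_real_,
                              p_raw = NA_real_, normality_ok = NA,
                              n_a = length(a), n_b = length(b)))
      }
      res <- compare_one(a, b, paired = paired, welch = welch)
      tibble::tibble(family = key$family, feature = key$feature,
                     test = res$test, statistic = res$statistic,
                     p_raw = res$p, normality_ok = res$normality_ok,
                     n_a = length(a), n_b = length(b))
    }) |>
    dplyr::bind_rows()

  out <- rows |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = {
      p <- .data$p_raw
      ok <- !is.na(p)
      p[ok] <- fdr_bh(p[ok])
      p
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p_fdr) & .data$p_fdr < alpha) |>
    dplyr::relocate("p_fdr", .after = "p_raw")
  attr(out, "alpha") <- alpha
  attr(out, "design") <- design
  attr(out, "groups") <- groups
  class(out) <- c("eeg_group_comparison", class(out))
  out
}
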