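#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a directed-connectivity result
#'
#' One row per ordered channel pair with the directed PTE and its dPTE
#' normalization.
#'
#' @param x A `pte_result` from [pte_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `band`, `source`, `target`,
#'   `pte`, `dpte`.
#' @exportS3Method generics::tidy
tidy.pte_result <- function(x, ...) {
  ch <- rownames(x$pte)
  grid <- expand.grid(source = ch, target = ch, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  tibble::tibble(
    subject_id = x$subject_id,
    band = x$band,
    source = grid$source,
    target = grid$target,
    pte = x$pte[cbind(grid$source, grid$target)],
    dpte = x$dpte[cbind(grid$source, grid$target)]
  )
}

# node-strength table for a single pte_result
glance_nodes <- function(x) {
  tibble::tibble(subject_id = x$subject_id, band = x$band,
                 channel = names(x$in_strength),
                 in_strength = unname(x$in_strength),
                 out_strength = unname(x$out_strength))
}

#' Summarize a directed-connectivity result
#'
#' @param x A `pte_result`.
#' @param ... Unused.
#' @return A one-row tibble: band, channel count, delay, bin count, total
#'   directed PTE mass, and the largest |dPTE - 0.5| deviation.
#' @exportS3Method generics::glance
glance.pte_result <- function(x, ...) {
  tibble::tibble(
    band = x$band,
    n_channels = length(x$in_strength),
    delay = x$delay,
    n_bins = x$n_bins,
    total_pte = sum(x$pte, na.rm = TRUE),
    max_dpte_dev = max(abs(x$dpte - 0.5), na.rm = TRUE)
  )
}

#' Tidy a group-comparison table
#'
#' `eeg_group_comparison` objects are already tidy; this strips the class
#' so the result is a plain tibble.
#'
#' @param x An `eeg_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eeg_group_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Summarize a group comparison
#'
#' @param x An `eeg_group_comparison`.
#' @param ... Unused.
#' @return One row per feature family: number of features tested, number
#'   FDR-significant, smallest adjusted p, and the fraction of features that
#'   passed the normality gate.
#' @exportS3Method generics::glance
glance.eeg_group_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_significant = sum(.data$significant, na.rm = TRUE),
      min_p_fdr = suppressWarnings(min(.data$p_fdr, na.rm = TRUE)),
      prop_normal = mean(.data$normality_ok, na.rm = TRUE),
      .groups = "drop"
    )
}
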