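#' Plot stacked channel traces
#'
#' @param object An [eeg_recording()].
#' @param max_s Plot at most this many seconds (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_recording <- function(object, max_s = 10, ...) {
  df <- as_tibble.eeg_recording(object) |>
    dplyr::filter(.data$time_s <= max_s) |>
    dplyr::mutate(channel = factor(.data$channel, levels = object$channels))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)",
                  title = object$subject_id) +
    ggplot2::theme_minimal()
}

#' Plot multiscale entropy curves per channel
#'
#' @param profiles An `eeg_complexity` tibble from [complexity_profile()],
#'   or several row-bound together (optionally with a `group` column, which
#'   is mapped to colour).
#' @return A ggplot object: MSE value against scale factor, one facet per
#'   channel.
#' @export
plot_mse_curves <- function(profiles) {
  df <- profiles |>
    dplyr::filter(grepl("^mse_s", .data$metric)) |>
    dplyr::mutate(scale = as.integer(sub("^mse_s", "", .data$metric)))
  has_group <- "group" %in% names(df)
  if (has_group) {
    df <- df |>
      dplyr::group_by(.data$group, .data$channel, .data$scale) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$scale, .data$value,
                                          colour = .data$group))
  } else {
    df <- df |>
      dplyr::group_by(.data$channel, .data$scale) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$scale, .data$value))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "scale factor", y = "sample entropy") +
    ggplot2::theme_minimal()
}

#' Heatmap of a directed connectivity matrix
#'
#' @param object A `pte_result` from [pte_matrix()].
#' @param what `"dpte"` (default) or `"pte"`.
#' @param ... Unused.
#' @return A ggplot tile plot, sources on rows and targets on columns; for
#'   dPTE the fill diverges around the balanced value 0.5.
#' @exportS3Method ggplot2::autoplot
autoplot.pte_result <- function(object, what = c("dpte", "pte"), ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tidy.pte_result(object)
  df$value <- if (what == "dpte") df$dpte else df$pte
  df$source <- factor(df$source, levels = rownames(m))
  df$target <- factor(df$target, levels = rownames(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(title = sprintf("%s, band %s", what, object$band),
                  x = "target", y = "source") +
    ggplot2::theme_minimal()
  if (what == "dpte") {
    p <- p + ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                                           mid = "white", high = "firebrick")
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot a group comparison
#'
#' @param object An `eeg_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object: -log10 FDR-adjusted p per feature, faceted by
#'   family, with the significance level marked.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_group_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::filter(!is.na(.data$p_fdr))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, -log10(.data$p_fdr),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p[FDR]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
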