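#' Run the full analysis pipeline over a cohort
#'
#' For every recording in the manifest: preprocess (notch, band-pass,
#' optional EEMD-ICA, segment rejection, common-average re-reference), then
#' per the configured modules compute the per-channel complexity profile
#' and/or the band-wise directed-connectivity results, assemble tidy
#' per-subject tables, and compare the two groups feature by feature
#' (Shapiro-Wilk gate, t-test or rank fallback, BH-FDR within each
#' metric/band family). Deterministic given `config$seed`.
#'
#' @param manifest Manifest tibble (see [read_manifest()] / [gen_cohort()])
#'   with columns `subject_id`, `group`, `path`, optional `pair_id`.
#' @param config An [eeg_config()].
#' @param design `"independent"` or `"paired"`; default infers `"paired"`
#'   when the manifest carries complete pair ids.
#' @param reject_uv Segment-rejection threshold, NULL to disable.
#' @param quiet Suppress per-stage progress messages on stderr.
#' @return A list of class `eeg_pipeline_result` with `tables` (tibbles:
#'   `complexity`, `edges`, `nodes`, and the comparison tables
#'   `comparison_complexity`, `comparison_edges`, `comparison_nodes` as
#'   applicable) and `summary` (run metadata).
#' @export
run_pipeline <- function(manifest, config = eeg_config(), design = NULL,
                         reject_uv = 150, quiet = FALSE) {
  validate_manifest(manifest)
  groups <- unique(manifest$group)
  if (is.null(design)) {
    design <- if (!anyNA(manifest$pair_id)) "paired" else "independent"
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  comp_rows <- list(); edge_rows <- list(); node_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    rec <- read_recording(entry$path, subject_id = entry$subject_id)
    rec <- preprocess(rec, config, reject_uv = reject_uv)
    key <- tibble::tibble(subject_id = entry$subject_id, group = entry$group,
                          pair_id = entry$pair_id)
    if ("complexity" %in% config$modules) {
      prof <- complexity_profile(rec, m = config$m, r_factor = config$r_factor,
                                 scales = config$scales)
      comp_rows[[i]] <- dplyr::bind_cols(
        key[rep(1, nrow(prof)), ],
        prof |> dplyr::select("channel", "metric", "value"))
    }
    if ("connectivity" %in% config$modules) {
      for (b in config$bands) {
        res <- pte_matrix(rec, b)
        td <- tidy(res)
        edge_rows[[paste(i, b)]] <- dplyr::bind_cols(
          key[rep(1, nrow(td)), ], td |> dplyr::select(-"subject_id"))
        ns <- glance_nodes(res)
        node_rows[[paste(i, b)]] <- dplyr::bind_cols(
          key[rep(1, nrow(ns)), ], ns |> dplyr::select(-"subject_id"))
      }
    }
    say("processed %s (%s) [%d/%d]", entry$subject_id, entry$group, i,
        nrow(manifest))
  }

  tables <- list()
  comparisons <- list()
  enough <- all(table(manifest$group) >= 2) && length(groups) == 2
  if (!enough) warning("fewer than 2 subjects in a group: statistics skipped")

  if (length(comp_rows)) {
    complexity <- dplyr::bind_rows(comp_rows)
    tables$complexity <- complexity
    if (enough) {
      feats <- complexity |>
        dplyr::rename(family = "metric") |>
        dplyr::mutate(feature = .data$channel, .keep = "unused")
      comparisons$comparison_complexity <-
        compare_groups(feats, design = design, alpha = config$fdr_alpha)
    }
  }
  if (length(edge_rows)) {
    edges <- dplyr::bind_rows(edge_rows)
    nodes <- dplyr::bind_rows(node_rows)
    tables$edges <- edges
    tables$nodes <- nodes
    if (enough) {
      efeat <- edges |>
        dplyr::mutate(family = paste0("pte_", .data$band),
                      feature = paste(.data$source, .data$target, sep = "->"),
                      value = .data$pte)
      nfeat <- nodes |>
        tidyr::pivot_longer(c("in_strength", "out_strength"),
                            names_to = "direction", values_to = "value") |>
        dplyr::mutate(family = paste(.data$direction, .data$band, sep = "_"),
                      feature = .data$channel)
      comparisons$comparison_edges <-
        compare_groups(efeat, design = design, alpha = config$fdr_alpha)
      comparisons$comparison_nodes <-
        compare_groups(nfeat, design = design, alpha = config$fdr_alpha)
    }
  }
  tables <- c(tables, comparisons)
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  structure(list(
    tables = tables,
    summary = list(
      n_subjects = nrow(manifest),
      groups = as.list(table(manifest$group)),
      design = design,
      modules = config$modules,
      bands = if ("connectivity" %in% config$modules) config$bands else character(0),
      m = config$m, r_factor = config$r_factor,
      scales = range(config$scales), fdr_alpha = config$fdr_alpha,
      seed = config$seed,
      n_significant = lapply(comparisons, function(cc) sum(cc$significant))
    )
  ), class = "eeg_pipeline_result")
}

#' @export
print.eeg_pipeline_result <- function(x, ...) {
  cat(sprintf("<eeg_pipeline_result> %d subjects (%s), design %s\n",
              x$summary$n_subjects,
              paste(names(x$summary$groups), unlist(x$summary$groups),
                    sep = "=", collapse = ", "),
              x$summary$design))
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
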