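#' Read a multichannel recording from disk
#'
#' Supports two on-disk layouts. `csv`: a comma-separated matrix with a
#' header row of channel labels followed by one row per channel (columns are
#' samples); the sampling rate comes from a leading `# fs=<Hz>` comment line
#' written by [write_recording()] or from the `fs` argument. `edf`: European
#' Data Format, 16-bit; labels, sampling rate and samples are taken from the
#' file (samples are subject to EDF's 16-bit quantization).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`; default guesses from the extension.
#' @param fs Sampling rate in Hz, required for csv files lacking the
#'   `# fs=` sidecar line. Ignored for EDF.
#' @param subject_id Subject identifier; defaults to the file stem (csv) or
#'   the EDF patient field.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           fs = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path, subject_id = subject_id))

  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^#\\s*fs\\s*=", lines[1])) {
    fs_file <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", lines[1]))
    if (is.null(fs)) fs <- fs_file
    lines <- lines[-1]
  }
  if (is.null(fs)) {
    stop("sampling rate missing: csv has no '# fs=' line and `fs` not given",
         call. = FALSE)
  }
  if (length(lines) < 2L) stop("csv must contain a header row and data rows", call. = FALSE)
  channels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (length(body) != length(channels)) {
    stop(sprintf("csv has %d channel labels but %d data rows",
                 length(channels), length(body)), call. = FALSE)
  }
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("non-numeric cell in csv data row", call. = FALSE)
    v
  })
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("csv data rows have unequal lengths", call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eeg_recording(do.call(rbind, rows), channels, fs, subject_id)
}

#' Write a recording to disk
#'
#' Round-trips through [read_recording()]: csv exactly, EDF within the
#' resolution of its 16-bit integer scaling.
#'
#' @param rec An [eeg_recording()].
#' @param path Destination path.
#' @param format `"csv"` or `"edf"`; default guesses from the extension.
#' @param digits Significant digits for csv output (default 10, ample for a
#'   numerically exact round trip of microvolt-scale data).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf"),
                            digits = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(rec$channels, collapse = ","), con)
  for (i in seq_len(nrow(rec$data))) {
    writeLines(paste(format(rec$data[i, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = ","), con)
  }
  invisible(path)
}

# --- minimal EDF (16-bit European Data Format), single data record ---------
# 256-byte fixed header, 256 bytes per signal, then samples as little-endian
# int16 scaled channel-wise from [physical_min, physical_max] onto
# [-32768, 32767].

pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- length(rec$channels)
  n <- ncol(rec$data)
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad("synthetic", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(1, 8),
    pad(format(rec$duration_s, digits = 10), 8), pad(ns, 4),
    paste0(pad(rec$channels, 16), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad("uV", 8), ns), collapse = ""),
    paste0(pad(format(pmin_, digits = 7), 8), collapse = ""),
    paste0(pad(format(pmax_, digits = 7), 8), collapse = ""),
    paste0(rep(pad(-32768, 8), ns), collapse = ""),
    paste0(rep(pad(32767, 8), ns), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad(n, 8), ns), collapse = ""),
    paste0(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!isTRUE(ns >= 1)) stop("corrupt EDF header", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # units
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  data <- matrix(NA_real_, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i])
      data[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
    }
  }
  fs <- nsamp[1] / (dur / 1)
  if (is.null(subject_id)) subject_id <- if (nzchar(patient)) patient else "subject"
  eeg_recording(data, labels, fs, subject_id)
}

#' Read / write a cohort manifest
#'
#' A manifest lists the recordings of a study: one row per recording with
#' `subject_id`, `group`, and `path`, plus an optional `pair_id` linking the
#' pre/post recordings of the same subject in a paired design. Stored as
#' YAML so it can carry the generator spec alongside.
#'
#' @param path Manifest file path (YAML).
#' @return `read_manifest()` returns a tibble with columns `subject_id`,
#'   `group`, `path`, and `pair_id` (NA when unpaired).
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  m <- dplyr::bind_rows(lapply(y$entries, tibble::as_tibble))
  if (!"pair_id" %in% names(m)) m$pair_id <- NA_character_
  validate_manifest(m)
  # resolve paths relative to the manifest location
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  entries <- lapply(seq_len(nrow(manifest)), function(i) as.list(manifest[i, ]))
  yaml::write_yaml(list(entries = entries), path)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns subject_id, group, path", call. = FALSE)
  }
  dup <- m |>
    dplyr::count(.data$group, .data$subject_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate subject_id within a group: ",
         paste(dup$subject_id, collapse = ", "), call. = FALSE)
  }
  if ("pair_id" %in% names(m)) {
    k <- m$pair_id[!is.na(m$pair_id)]
    bad <- names(which(table(k) != 2L))
    if (length(bad)) {
      stop("pair_id values must link exactly two entries: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(m)
}

#' Write pipeline result tables
#'
#' Writes each tidy table of a pipeline result as TSV (floating point at six
#' significant digits) plus a JSON run summary.
#'
#' @param result A result list from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    df
  }
  for (nm in names(result$tables)) {
    utils::write.table(fmt(result$tables[[nm]]),
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
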