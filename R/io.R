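#' Read a sampled signal
#'
#' Values are returned exactly as stored — no filtering or preprocessing of
#' any kind is applied; the model denoises through the sparsity of its
#' changepoints. The CSV dialect is comma-separated, UTF-8, `.` decimal,
#' with a required `sample,value` header; lines starting with `#` are
#' metadata comments. WFDB records are a recognised kind but require a
#' waveform reader that this package does not bundle; requesting
#' `kind = "wfdb"` raises an informative error.
#'
#' @param path File path.
#' @param kind `"csv"` or `"wfdb"`.
#' @param channel Channel name for waveform records (e.g. `"MLII"`); unused
#'   for CSV.
#' @param sampling_rate Sampling rate in Hz to associate with CSV data
#'   (default 360, the MIT-BIH convention).
#' @return A tibble with columns `sample` and `value`; the sampling rate is
#'   attached as the `sampling_rate` attribute.
#' @export
read_signal <- function(path, kind = c("csv", "wfdb"), channel = NULL,
                        sampling_rate = 360) {
  kind <- match.arg(kind)
  if (kind == "wfdb") {
    abort("WFDB record reading is optional and not available in this build; convert the record (and its annotations) to CSV instead")
  }
  read_signal_csv(path, sampling_rate = sampling_rate)
}

#' @rdname read_signal
#' @export
read_signal_csv <- function(path, sampling_rate = 360) {
  if (!file.exists(path)) abort(sprintf("signal file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#")
  blank <- which(keep & trimws(lines) == "")
  if (length(blank) > 0) {
    abort(sprintf("%s: blank line at line %d", path, blank[1]))
  }
  body <- lines[keep]
  if (length(body) < 1) abort(sprintf("%s: missing 'sample,value' header", path))
  header <- tolower(gsub("[[:space:]]", "", body[1]))
  if (header != "sample,value") {
    abort(sprintf("%s: header must be 'sample,value' (found '%s')", path, body[1]))
  }
  rows <- body[-1]
  if (length(rows) == 0) {
    out <- tibble(sample = integer(), value = double())
    attr(out, "sampling_rate") <- sampling_rate
    return(out)
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_n <- which(vapply(parts, length, 1L) != 2L)
  line_no <- which(keep)[-1]  # original line numbers of data rows
  if (length(bad_n) > 0) {
    abort(sprintf("%s: expected two comma-separated fields at line %d",
                  path, line_no[bad_n[1]]))
  }
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(s) | is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric row at line %d", path, line_no[bad[1]]))
  }
  out <- tibble(sample = as.integer(s), value = v)
  attr(out, "sampling_rate") <- sampling_rate
  out
}

meta_header <- function(seed = NULL, config_hash = NULL) {
  sprintf("# gccd %s seed=%s config=%s",
          as.character(utils::packageVersion("gccd")),
          if (is.null(seed)) "NA" else format(seed),
          if (is.null(config_hash)) "NA" else config_hash)
}

write_table_csv <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(seed, config_hash), con)
  writeLines(sub("\n$", "", readr::format_csv(df)), con)
  invisible(path)
}

#' Write a signal, peak list, label set or segmentation to CSV
#'
#' All writers emit a leading `#` metadata comment recording the package
#' version, the seed and a hash of the run configuration, followed by a
#' regular CSV header and rows. [read_signal_csv()], [read_peaks_csv()] and
#' [read_labels_csv()] skip such comments.
#'
#' @param signal A tibble with `sample`, `value`.
#' @param path Output path.
#' @param seed,config_hash Optional metadata recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, seed = NULL, config_hash = NULL) {
  write_table_csv(signal[c("sample", "value")], path, seed, config_hash)
}

#' @rdname write_signal_csv
#' @param peaks A tibble with a `sample` column, or an integer vector.
#' @export
write_peaks_csv <- function(peaks, path, seed = NULL, config_hash = NULL) {
  write_table_csv(tibble(sample = peak_positions(peaks)), path, seed, config_hash)
}

#' @rdname write_signal_csv
#' @param labels A tibble with `start`, `end`.
#' @export
write_labels_csv <- function(labels, path, seed = NULL, config_hash = NULL) {
  write_table_csv(label_regions(labels)[c("start", "end")], path, seed, config_hash)
}

#' @rdname write_signal_csv
#' @param fit A `gccd_fit`; segments go to `path`, and if `changes_path` is
#'   given the change list (`position`, `edge_id`) is written there.
#' @param changes_path Optional path for the changes CSV.
#' @export
write_segmentation_csv <- function(fit, path, changes_path = NULL,
                                   seed = NULL, config_hash = NULL) {
  if (!inherits(fit, "gccd_fit")) abort("`fit` must be a gccd_fit object")
  write_table_csv(fit$segments, path, seed, config_hash)
  if (!is.null(changes_path)) {
    write_table_csv(fit$changes, changes_path, seed, config_hash)
  }
  invisible(path)
}

read_simple_csv <- function(path, cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, comment = "#", col_types = readr::cols(),
                        progress = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  as_tibble(df[cols])
}

#' Read peak positions, beat annotations, or label regions from CSV
#'
#' @param path File path. Peaks and annotations use a single `sample`
#'   column; labels use `start,end` half-open regions.
#' @return A tibble.
#' @export
read_peaks_csv <- function(path) read_simple_csv(path, "sample")

#' @rdname read_peaks_csv
#' @export
read_annotations_csv <- function(path) read_simple_csv(path, "sample")

#' @rdname read_peaks_csv
#' @export
read_labels_csv <- function(path) label_regions(read_simple_csv(path, c("start", "end")))
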