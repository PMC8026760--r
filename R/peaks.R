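#' Locate R-peaks in a fitted segmentation
#'
#' The center of each maximal run of peak-state segments is reported as one
#' R-peak: position `floor((start + end - 1) / 2)` of the run (floor
#' convention for even-length runs).
#'
#' @param x A `gccd_fit` from [gccd_solve()], or a segments data frame with
#'   columns `start`, `end`, `state`.
#' @param peak_state Name of the peak state. Defaults to the peak state of
#'   the fit's graph.
#' @return A tibble with one column `sample` (sorted peak positions).
#' @export
locate_peaks <- function(x, peak_state = NULL) {
  if (inherits(x, "gccd_fit")) {
    if (is.null(peak_state)) peak_state <- peak_state(x$graph)
    if (!peak_state %in% x$graph$vertices$name) {
      abort(sprintf("peak_state '%s' is not a vertex of the fitted graph", peak_state))
    }
    seg <- x$segments
  } else {
    seg <- as_tibble(x)
    if (is.null(peak_state)) abort("`peak_state` is required for a plain segments table")
  }
  is_peak <- seg$state == peak_state
  if (!any(is_peak)) return(tibble(sample = integer()))
  run_id <- cumsum(c(TRUE, diff(is_peak) != 0))
  runs <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(tibble(run_id, is_peak,
                                            start = seg$start, end = seg$end),
                                     .data$run_id),
                     is_peak = .data$is_peak[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop"),
    .data$is_peak)
  tibble(sample = as.integer(floor((runs$start + runs$end - 1) / 2)))
}

peak_positions <- function(peaks) {
  if (is.data.frame(peaks)) {
    col <- if ("sample" %in% names(peaks)) "sample" else names(peaks)[1]
    as.integer(peaks[[col]])
  } else {
    as.integer(peaks)
  }
}

label_regions <- function(labels) {
  labels <- as_tibble(labels)
  if (!all(c("start", "end") %in% names(labels))) {
    abort("`labels` needs columns `start` and `end`")
  }
  if (nrow(labels) > 0) {
    if (any(labels$end <= labels$start)) abort("label regions need start < end")
    labels <- dplyr::arrange(labels, .data$start)
    if (nrow(labels) > 1 && any(labels$start[-1] < labels$end[-nrow(labels)])) {
      abort("label regions must not overlap")
    }
  }
  labels
}

#' Count label errors of predicted peaks against weak label regions
#'
#' Each half-open region `[start, end)` is expected to contain exactly one
#' peak: a region with no predicted peak counts one false negative; a region
#' with `k >= 1` peaks counts `k - 1` false positives. Peaks outside every
#' region are ignored — the regions are sparse supervision covering only part
#' of the record, so silence about the rest of the signal is not evidence of
#' error. This is the training criterion minimized by [greedy_learn()].
#'
#' @param peaks Peak positions: an integer vector or a tibble with a `sample`
#'   column (from [locate_peaks()]).
#' @param labels A tibble of regions with columns `start`, `end`.
#' @return A one-row tibble with columns `fp`, `fn` and `total = fp + fn`.
#' @export
count_label_errors <- function(peaks, labels) {
  p <- peak_positions(peaks)
  labels <- label_regions(labels)
  fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(labels))) {
    k <- sum(p >= labels$start[i] & p < labels$end[i])
    if (k == 0L) fn <- fn + 1L else fp <- fp + (k - 1L)
  }
  tibble(fp = fp, fn = fn, total = fp + fn)
}

#' Match predicted peaks against reference annotations
#'
#' Greedy one-to-one matching in increasing position order: each predicted
#' peak is matched to the nearest still-unmatched reference beat within
#' `± tolerance_samples` (distance ties broken toward the earlier reference
#' beat). Matched predictions are true positives, unmatched predictions false
#' positives, unmatched reference beats false negatives.
#'
#' @param peaks Predicted peak positions (vector or tibble with `sample`).
#' @param truth Reference beat positions, sorted increasing (vector or tibble
#'   with `sample`).
#' @param tolerance_samples Matching half-window in samples, `>= 0`. The
#'   default 54 is 150 ms at 360 Hz, the conventional beat-matching window.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`.
#' @export
match_annotations <- function(peaks, truth, tolerance_samples = 54L) {
  p <- peak_positions(peaks)
  tr <- peak_positions(truth)
  if (!is.numeric(tolerance_samples) || tolerance_samples < 0) {
    abort("`tolerance_samples` must be >= 0")
  }
  p <- sort(p)
  if (length(tr) == 0) return(tibble(tp = 0L, fp = length(p), fn = 0L))
  matched <- rep(FALSE, length(tr))
  tp <- 0L; fp <- 0L
  for (x in p) {
    d <- abs(tr - x)
    d[matched] <- Inf
    j <- which(d == min(d))[1]  # tie -> earlier reference beat
    if (is.finite(d[j]) && d[j] <= tolerance_samples) {
      matched[j] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  tibble(tp = tp, fp = fp, fn = sum(!matched))
}

#' Detection metrics: sensitivity, positive predictivity, detection error rate
#'
#' From true positives, false positives and false negatives:
#' `Sen% = 100 * TP / (TP + FN)`, `PPR% = 100 * TP / (TP + FP)`, and
#' `DER% = 100 * (FN + FP) / (TP + FN)`. DER can exceed 100 when FP is large;
#' it is reported as printed, unclamped. Degenerate denominators give `NA`
#' with a warning.
#'
#' @param tp A one-row data frame with columns `tp`, `fp`, `fn` (as returned
#'   by [match_annotations()]), or the TP count.
#' @param fp,fn FP and FN counts when `tp` is given as a count.
#' @return A one-row tibble `tp`, `fp`, `fn`, `sen`, `ppr`, `der`
#'   (percentages).
#' @examples
#' compute_metrics(tp = 198, fp = 0, fn = 2)
#' @export
compute_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  }
  if (any(c(tp, fp, fn) < 0) || any(c(tp, fp, fn) != floor(c(tp, fp, fn)))) {
    abort("tp, fp, fn must be non-negative integers")
  }
  sen <- der <- ppr <- NA_real_
  if (tp + fn > 0) {
    sen <- 100 * tp / (tp + fn)
    der <- 100 * (fn + fp) / (tp + fn)
  } else {
    warn("TP + FN = 0: sensitivity and detection error rate are undefined")
  }
  if (tp + fp > 0) {
    ppr <- 100 * tp / (tp + fp)
  } else {
    warn("TP + FP = 0: positive predictivity is undefined")
  }
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         sen = sen, ppr = ppr, der = der)
}
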