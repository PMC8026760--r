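#' Solve the graph-constrained changepoint detection problem
#'
#' Computes the globally optimal piecewise-constant segmentation of a raw
#' signal under a constraint graph: it minimizes the sum of squared errors
#' between each sample and its segment mean, plus the penalty of every
#' changepoint used, subject to consecutive segments following the graph's
#' edges (direction and minimum amplitude gap on the change of mean). The
#' exact optimum over all changepoint positions, hidden-state paths and
#' segment means is found by a functional-pruning dynamic program over
#' piecewise quadratic cost functions.
#'
#' Any vertex may start the recording and any vertex may end it: a recording
#' window begins and ends at an arbitrary phase of the cardiac cycle.
#' Segment means are restricted to the finite interval
#' `[min(y) - m_margin, max(y) + m_margin]`; optimal means are convex
#' combinations of data values shifted by at most the edge gaps, so a small
#' margin is lossless in practice.
#'
#' Samples are 0-based and segments half-open `[start, end)`; a change
#' recorded at position `i` means the new segment starts at sample `i + 1`.
#' When the "no change" and "change" branches tie exactly, "no change" is
#' preferred (the sparser model).
#'
#' @param signal A numeric vector, or a data frame with a `value` column
#'   (as returned by [gen_ecg()] or [read_signal_csv()]).
#' @param graph A [constraint_graph()].
#' @param m_margin Margin added on both sides of the observed signal range to
#'   form the mean domain. Default: 10% of the signal range (or 1 for a
#'   constant signal).
#' @return A `gccd_fit` object with components `segments` (tibble `start`,
#'   `end`, `state`, `mean`), `changes` (tibble `position`, `edge_id`),
#'   `total_cost`, `graph`, `signal`, `m_domain` and per-sample, per-state
#'   quadratic `piece_counts`. Supports [tidy()], [glance()], [autoplot()]
#'   and [pruning_stats()].
#' @examples
#' sig <- c(0, 0, 0, 10, 10, 10)
#' g <- ecg_graph(gap = 1, penalty = 1)
#' fit <- gccd_solve(sig, g)
#' tidy(fit)
#' glance(fit)
#' @export
gccd_solve <- function(signal, graph, m_margin = NULL) {
  y <- signal_values(signal)
  check_graph(graph)
  if (length(y) < 1) abort("`signal` must contain at least one sample")
  if (!all(is.finite(y))) abort("`signal` values must all be finite")

  rng <- range(y)
  span <- rng[2] - rng[1]
  if (is.null(m_margin)) m_margin <- if (span > 0) 0.1 * span else 1
  if (!is.numeric(m_margin) || length(m_margin) != 1 || m_margin < 0 ||
      (span == 0 && m_margin == 0)) {
    abort("`m_margin` must be a non-negative number (positive for a constant signal)")
  }
  m0 <- rng[1] - m_margin
  m1 <- rng[2] + m_margin

  vn <- graph$vertices$name
  ed <- graph$edges
  res <- gccd_solve_cpp(
    y,
    edge_source = match(ed$source, vn) - 1L,
    edge_target = match(ed$target, vn) - 1L,
    edge_dir = ifelse(ed$direction == "non_decreasing", 1L, -1L),
    edge_gap = ed$gap,
    edge_penalty = ed$penalty,
    edge_id = ed$id,
    n_vertices = length(vn),
    m0 = m0, m1 = m1)

  segments <- tibble(start = res$start, end = res$end,
                     state = vn[res$state + 1L], mean = res$mean)
  changes <- tibble(position = as.integer(res$change_pos),
                    edge_id = as.integer(res$change_edge))
  colnames(res$piece_counts) <- vn
  structure(
    list(segments = segments, changes = changes,
         total_cost = res$total_cost, graph = graph,
         signal = tibble(sample = seq_along(y) - 1L, value = y),
         m_domain = c(m0, m1), piece_counts = res$piece_counts),
    class = "gccd_fit")
}

signal_values <- function(signal) {
  if (is.data.frame(signal)) {
    if (!"value" %in% names(signal)) {
      abort("a data-frame `signal` needs a `value` column")
    }
    as.numeric(signal$value)
  } else if (is.numeric(signal)) {
    as.numeric(signal)
  } else {
    abort("`signal` must be a numeric vector or a data frame with a `value` column")
  }
}

#' @export
print.gccd_fit <- function(x, ...) {
  cat(sprintf("<gccd_fit> %d samples, %d segment(s), %d change(s), total cost %.6g\n",
              nrow(x$signal), nrow(x$segments), nrow(x$changes), x$total_cost))
  print(x$segments, ...)
  invisible(x)
}

#' @rdname gccd_solve
#' @param x A `gccd_fit` object.
#' @param ... Unused.
#' @method tidy gccd_fit
#' @export
tidy.gccd_fit <- function(x, ...) x$segments

#' @rdname gccd_solve
#' @method glance gccd_fit
#' @export
glance.gccd_fit <- function(x, ...) {
  tibble(n = nrow(x$signal), n_segments = nrow(x$segments),
         n_changes = nrow(x$changes), total_cost = x$total_cost,
         m_min = x$m_domain[1], m_max = x$m_domain[2])
}

#' Per-sample quadratic piece counts of a solved model
#'
#' Diagnostic view of functional pruning: the number of quadratic pieces the
#' solver stored per hidden state at every sample. Average-case growth of the
#' median count is sublinear in the number of samples, which is what makes
#' the dynamic program fast on real signals.
#'
#' @param fit A `gccd_fit` from [gccd_solve()].
#' @return A tibble with columns `sample`, `state`, `pieces`.
#' @export
pruning_stats <- function(fit) {
  if (!inherits(fit, "gccd_fit")) abort("`fit` must be a gccd_fit object")
  pc <- fit$piece_counts
  tibble(sample = rep(seq_len(nrow(pc)) - 1L, times = ncol(pc)),
         state = rep(colnames(pc), each = nrow(pc)),
         pieces = as.integer(pc))
}

#' Check a segmentation against its defining invariants
#'
#' Verifies mechanically that a fitted segmentation (a) tiles the signal with
#' half-open segments and no gaps, (b) uses only declared edges, whose
#' direction/gap constraints the segment means satisfy, and (c) reports a
#' `total_cost` equal to the residual sum of squares plus the penalties of
#' the changes used.
#'
#' @param fit A `gccd_fit`.
#' @param tol Numerical tolerance.
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
validate_segmentation <- function(fit, tol = 1e-6) {
  if (!inherits(fit, "gccd_fit")) abort("`fit` must be a gccd_fit object")
  seg <- fit$segments
  n <- nrow(fit$signal)
  if (seg$start[1] != 0 || seg$end[nrow(seg)] != n) {
    abort("segments do not span [0, N)")
  }
  if (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)])) {
    abort("segments do not tile contiguously")
  }
  if (any(seg$end <= seg$start)) abort("empty segment found")
  ed <- fit$graph$edges
  if (nrow(seg) > 1) {
    for (k in seq_len(nrow(seg) - 1)) {
      e <- ed[ed$source == seg$state[k] & ed$target == seg$state[k + 1], ]
      if (nrow(e) != 1) {
        abort(sprintf("transition %s -> %s is not a declared edge",
                      seg$state[k], seg$state[k + 1]))
      }
      d <- if (e$direction == "non_decreasing") 1 else -1
      if (d * (seg$mean[k] - seg$mean[k + 1]) + e$gap > tol) {
        abort(sprintf("segment means %g -> %g violate edge %d (%s, gap %g)",
                      seg$mean[k], seg$mean[k + 1], e$id, e$direction, e$gap))
      }
    }
  }
  mean_of <- rep(seg$mean, times = seg$end - seg$start)
  rss <- sum((mean_of - fit$signal$value)^2)
  pen <- if (nrow(fit$changes) > 0) {
    sum(ed$penalty[match(fit$changes$edge_id, ed$id)])
  } else 0
  if (abs(rss + pen - fit$total_cost) > tol * (1 + abs(fit$total_cost))) {
    abort(sprintf("total_cost %.10g != RSS %.10g + penalties %.10g",
                  fit$total_cost, rss, pen))
  }
  invisible(TRUE)
}

#' Plot a fitted segmentation over the signal
#'
#' @param object A `gccd_fit`.
#' @param ... Unused.
#' @return A ggplot: raw samples, segment means, and detected R-peaks.
#' @method autoplot gccd_fit
#' @export
autoplot.gccd_fit <- function(object, ...) {
  seg <- object$segments
  pk <- locate_peaks(object)
  p <- ggplot2::ggplot(object$signal, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_point(colour = "grey60", size = 0.3) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start, xend = .data$end - 1,
                   y = .data$mean, yend = .data$mean, colour = .data$state),
      linewidth = 0.9) +
    ggplot2::labs(x = "sample", y = "amplitude", colour = "state")
  if (nrow(pk) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = pk$sample,
                                 linetype = "dotted", colour = "red")
  }
  p
}
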