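#' Graph edit kinds considered by the greedy search
#'
#' Eleven per-edge editing candidates: three ways of inserting one node, two
#' ways of deleting a node, one way of inserting two nodes, flipping the
#' direction of the change, and doubling/halving the edge's penalty and gap.
#' For an edge `Vi -> Vj` with direction `d`, the node insertions use the
#' direction patterns `(d, d)`, `(d, !d)` and `(!d, d)`, and the two-node
#' insertion uses `(d, !d, d)`; together with direction flips these span all
#' monotone-wave shapes. Newly created edges inherit the gap and penalty of
#' the edited edge; a deletion merges the neighbouring edge into the edited
#' edge, which keeps its own parameters.
#'
#' @format A character vector of length 11, in the deterministic enumeration
#'   order used to break ties between equal-error candidates.
#' @export
edit_kinds <- c("add_node_v1", "add_node_v2", "add_node_v3",
                "delete_source", "delete_target", "add_two_nodes",
                "flip_direction", "penalty_up", "penalty_down",
                "gap_up", "gap_down")

flip_dir <- function(d) {
  ifelse(d == "non_decreasing", "non_increasing", "non_decreasing")
}

fresh_names <- function(graph, k) {
  existing <- graph$vertices$name
  out <- character(0)
  i <- 1L
  while (length(out) < k) {
    nm <- sprintf("S%d", i)
    if (!nm %in% existing) out <- c(out, nm)
    i <- i + 1L
  }
  out
}

#' Apply one graph edit candidate
#'
#' Applies an edit of one of the 11 [edit_kinds] to the edge with id
#' `edge_id`, preserving the single-cycle structure. Edits that would delete
#' the peak state, or delete a node from a graph with two or fewer vertices,
#' are inapplicable and return `NULL` (they are skipped, not an error).
#'
#' @param graph A [constraint_graph()].
#' @param kind One of [edit_kinds].
#' @param edge_id Id of the edge to edit.
#' @return A new [constraint_graph()], or `NULL` if the edit is inapplicable.
#' @export
apply_edit <- function(graph, kind, edge_id) {
  check_graph(graph)
  kind <- match.arg(kind, edit_kinds)
  ed <- graph$edges
  i <- which(ed$id == edge_id)
  if (length(i) != 1) abort(sprintf("edge id %s does not exist", edge_id))
  e <- ed[i, ]
  pk <- peak_state(graph)
  nv <- nrow(graph$vertices)
  d <- e$direction

  new_edges <- switch(
    kind,
    add_node_v1 = ,
    add_node_v2 = ,
    add_node_v3 = {
      k <- fresh_names(graph, 1)
      dirs <- switch(kind,
                     add_node_v1 = c(d, d),
                     add_node_v2 = c(d, flip_dir(d)),
                     add_node_v3 = c(flip_dir(d), d))
      ins <- tibble(source = c(e$source, k), target = c(k, e$target),
                    direction = dirs, gap = e$gap, penalty = e$penalty)
      dplyr::bind_rows(ed[-i, names(ins)], ins)
    },
    add_two_nodes = {
      ks <- fresh_names(graph, 2)
      ins <- tibble(source = c(e$source, ks[1], ks[2]),
                    target = c(ks[1], ks[2], e$target),
                    direction = c(d, flip_dir(d), d),
                    gap = e$gap, penalty = e$penalty)
      dplyr::bind_rows(ed[-i, names(ins)], ins)
    },
    delete_source = {
      if (e$source == pk || nv <= 2) return(NULL)
      h <- which(ed$target == e$source)  # in-edge of the vertex to delete
      merged <- tibble(source = ed$source[h], target = e$target,
                       direction = d, gap = e$gap, penalty = e$penalty)
      dplyr::bind_rows(ed[-c(i, h), names(merged)], merged)
    },
    delete_target = {
      if (e$target == pk || nv <= 2) return(NULL)
      g <- which(ed$source == e$target)  # out-edge of the vertex to delete
      merged <- tibble(source = e$source, target = ed$target[g],
                       direction = d, gap = e$gap, penalty = e$penalty)
      dplyr::bind_rows(ed[-c(i, g), names(merged)], merged)
    },
    flip_direction = {
      ed$direction[i] <- flip_dir(d)
      ed[, c("source", "target", "direction", "gap", "penalty")]
    },
    penalty_up = ,
    penalty_down = {
      ed$penalty[i] <- ed$penalty[i] * if (kind == "penalty_up") 2 else 0.5
      ed[, c("source", "target", "direction", "gap", "penalty")]
    },
    gap_up = ,
    gap_down = {
      ed$gap[i] <- ed$gap[i] * if (kind == "gap_up") 2 else 0.5
      ed[, c("source", "target", "direction", "gap", "penalty")]
    })
  out <- constraint_graph(new_edges, peak_state = pk)
  attr(out, "edit") <- tibble(kind = kind, edge_id = as.integer(edge_id))
  out
}

#' Enumerate all applicable graph edit candidates
#'
#' Applies every one of the 11 [edit_kinds] to every edge, drops inapplicable
#' edits, and deduplicates the results by canonical graph serialization
#' (cycle order from the peak state), so at most `11 * |E|` candidates are
#' returned. Each candidate carries an `edit` attribute recording the kind
#' and edge that produced it.
#'
#' @param graph A [constraint_graph()].
#' @return A list of [constraint_graph()] objects.
#' @export
find_graph_candidates <- function(graph) {
  check_graph(graph)
  out <- list()
  seen <- character(0)
  for (eid in graph$edges$id) {
    for (kind in edit_kinds) {
      cand <- apply_edit(graph, kind, eid)
      if (is.null(cand)) next
      key <- graph_key(cand)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Training label error of a graph on a labeled signal
#'
#' Solves the segmentation problem for `signal` under `graph`, locates the
#' peaks, and counts label errors against the weak label regions (false
#' negatives plus in-region false positives; see [count_label_errors()]).
#' An infeasible solve yields `Inf`, so such a candidate is never selected.
#'
#' @param graph A [constraint_graph()].
#' @param signal Numeric vector or data frame with a `value` column.
#' @param labels Label regions (tibble `start`, `end`).
#' @param m_margin Passed to [gccd_solve()].
#' @return A single number: the total label error (possibly `Inf`).
#' @export
label_error <- function(graph, signal, labels, m_margin = NULL) {
  fit <- tryCatch(gccd_solve(signal, graph, m_margin = m_margin),
                  error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  pk <- locate_peaks(fit)
  count_label_errors(pk, labels)$total
}

#' Greedy constraint-graph structure learning
#'
#' Starting from an initial graph, repeatedly enumerates all edit candidates
#' of the current graph ([find_graph_candidates()]), evaluates the training
#' label error of each ([label_error()]), and accepts the best strictly
#' improving candidate; the search stops as soon as no candidate strictly
#' reduces the error. Ties between equally improving candidates are broken
#' by the deterministic enumeration order (edge id, then [edit_kinds] order),
#' so the result is reproducible. Because the integer error strictly
#' decreases at every accepted iteration, the search terminates in at most
#' `initial error + 1` iterations.
#'
#' @param signal Numeric vector or data frame with a `value` column.
#' @param labels Training label regions (tibble `start`, `end`); at least one.
#' @param init_graph Initial [constraint_graph()]; default [ecg_graph()] with
#'   `gap = 100`, `penalty = 1e5`.
#' @param val_labels Optional held-out label regions; their error is reported
#'   in the trace per accepted iteration but never used for selection.
#' @param m_margin Passed to [gccd_solve()].
#' @param max_iter Safety cap on accepted iterations.
#' @return A `gccd_learn` object: list with `graph` (the final graph),
#'   `trace` (tibble `iteration`, `train_error`, `val_error`, `n_vertices`,
#'   `edit_kind`, `edit_edge`), and `graphs` (accepted graph per iteration,
#'   including the initial graph at iteration 0). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
greedy_learn <- function(signal, labels, init_graph = ecg_graph(),
                         val_labels = NULL, m_margin = NULL, max_iter = 100L) {
  check_graph(init_graph)
  labels <- label_regions(labels)
  if (nrow(labels) < 1) abort("at least one training label region is required")

  val_err <- function(g) {
    if (is.null(val_labels)) NA_real_ else label_error(g, signal, val_labels, m_margin)
  }
  err <- label_error(init_graph, signal, labels, m_margin)
  if (!is.finite(err)) {
    abort("the initial graph is infeasible on this signal")
  }
  trace <- tibble(iteration = 0L, train_error = err, val_error = val_err(init_graph),
                  n_vertices = nrow(init_graph$vertices),
                  edit_kind = NA_character_, edit_edge = NA_integer_)
  graphs <- list(init_graph)
  g <- init_graph
  t <- 0L
  while (err > 0 && t < max_iter) {
    cands <- find_graph_candidates(g)
    best_err <- err
    best_g <- NULL
    for (cand in cands) {
      e <- label_error(cand, signal, labels, m_margin)
      if (e < best_err) {
        best_err <- e
        best_g <- cand
      }
    }
    if (is.null(best_g)) break
    t <- t + 1L
    g <- best_g
    err <- best_err
    edit <- attr(g, "edit")
    trace <- dplyr::bind_rows(trace, tibble(
      iteration = t, train_error = err, val_error = val_err(g),
      n_vertices = nrow(g$vertices),
      edit_kind = edit$kind, edit_edge = edit$edge_id))
    graphs <- c(graphs, list(g))
  }
  structure(list(graph = g, trace = trace, graphs = graphs),
            class = "gccd_learn")
}

#' @export
print.gccd_learn <- function(x, ...) {
  cat(sprintf("<gccd_learn> %d accepted iteration(s), final train error %g\n",
              max(x$trace$iteration), x$trace$train_error[nrow(x$trace)]))
  print(x$graph)
  invisible(x)
}

#' @rdname greedy_learn
#' @param x A `gccd_learn` object.
#' @param ... Unused.
#' @method tidy gccd_learn
#' @export
tidy.gccd_learn <- function(x, ...) x$trace

#' @rdname greedy_learn
#' @method glance gccd_learn
#' @export
glance.gccd_learn <- function(x, ...) {
  tibble(iterations = max(x$trace$iteration),
         initial_error = x$trace$train_error[1],
         final_error = x$trace$train_error[nrow(x$trace)],
         n_vertices = nrow(x$graph$vertices))
}

#' @rdname greedy_learn
#' @param object A `gccd_learn` object.
#' @method autoplot gccd_learn
#' @export
autoplot.gccd_learn <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train_error", "val_error"),
                            names_to = "set", values_to = "error")
  tr <- dplyr::filter(tr, !is.na(.data$error))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$error,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "label errors", colour = NULL)
}

#' Split label regions into cross-validation folds
#'
#' Randomly partitions the label regions into `k` folds of near-equal size
#' (sizes differ by at most one), deterministically for a given seed.
#'
#' @param labels Label regions (tibble `start`, `end`).
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed controlling the permutation.
#' @return The label tibble with an added integer `fold` column in `1..k`.
#' @export
split_folds <- function(labels, k, seed) {
  labels <- label_regions(labels)
  if (!is.numeric(k) || k < 2) abort("`k` must be at least 2")
  if (nrow(labels) < k) abort("fewer label regions than folds")
  n <- nrow(labels)
  fold <- integer(n)
  fold[withr::with_seed(seed, sample.int(n))] <- rep(seq_len(k), length.out = n)
  labels$fold <- fold
  labels
}
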