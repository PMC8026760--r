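#' Constraint graphs
#'
#' A constraint graph encodes prior knowledge about the expected sequence of
#' hidden states within one cardiac cycle. Vertices are hidden states (one of
#' them the distinguished R-peak state); edges are allowed transitions, each
#' carrying a direction (`non_decreasing`, shown as an "up" change, or
#' `non_increasing`), a minimum amplitude gap `gap >= 0` between the segment
#' means on either side of the change, and a non-negative `penalty` added to
#' the cost for using the transition. For a change from mean `m1` to mean
#' `m2`, a `non_decreasing` edge requires `m2 >= m1 + gap` and a
#' `non_increasing` edge requires `m2 <= m1 - gap`.
#'
#' The edges must form a single directed cycle visiting every vertex exactly
#' once, so the number of edges equals the number of vertices. As a
#' documented degenerate case, a graph with a single vertex and no edges is
#' allowed (a one-state model that can never change).
#'
#' Edges are stored canonically in cycle order starting from the peak state,
#' with ids `1..|E|`; id 0 is reserved for "no change" (penalty 0) and never
#' appears as an edge id.
#'
#' @param edges A data frame with columns `source`, `target`, `direction`,
#'   `gap`, `penalty` (one row per transition).
#' @param peak_state Name of the vertex whose segments mark R-peaks.
#' @return A `constraint_graph`: a list with tibbles `vertices`
#'   (`name`, `peak`) and `edges` (`id`, `source`, `target`, `direction`,
#'   `gap`, `penalty`).
#' @examples
#' g <- ecg_graph(gap = 100, penalty = 1e5)
#' g
#' @export
constraint_graph <- function(edges, peak_state) {
  edges <- as_tibble(edges)
  needed <- c("source", "target", "direction", "gap", "penalty")
  miss <- setdiff(needed, names(edges))
  if (length(miss) > 0) {
    abort(sprintf("`edges` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.character(peak_state) || length(peak_state) != 1) {
    abort("`peak_state` must be a single vertex name")
  }

  if (nrow(edges) == 0) {
    # single-state degenerate graph
    vertices <- tibble(name = peak_state, peak = TRUE)
    g <- structure(list(vertices = vertices,
                        edges = tibble(id = integer(), source = character(),
                                       target = character(),
                                       direction = character(),
                                       gap = double(), penalty = double())),
                   class = "constraint_graph")
    return(g)
  }

  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$direction <- as.character(edges$direction)
  bad_dir <- !edges$direction %in% c("non_decreasing", "non_increasing")
  if (any(bad_dir)) {
    abort(sprintf("edge %d: direction must be 'non_decreasing' or 'non_increasing' (got '%s')",
                  which(bad_dir)[1], edges$direction[which(bad_dir)[1]]))
  }
  if (any(!is.finite(edges$gap)) || any(edges$gap < 0)) {
    abort(sprintf("edge %d: gap must be finite and >= 0", which(!is.finite(edges$gap) | edges$gap < 0)[1]))
  }
  if (any(!is.finite(edges$penalty)) || any(edges$penalty < 0)) {
    abort(sprintf("edge %d: penalty must be finite and >= 0",
                  which(!is.finite(edges$penalty) | edges$penalty < 0)[1]))
  }

  vnames <- unique(c(edges$source, edges$target))
  if (!peak_state %in% vnames) {
    abort(sprintf("peak_state '%s' is not a vertex of the graph", peak_state))
  }
  # single circular path: every vertex exactly one outgoing and one incoming edge
  out_tab <- table(edges$source)
  in_tab <- table(edges$target)
  for (v in vnames) {
    n_out <- if (v %in% names(out_tab)) out_tab[[v]] else 0L
    n_in <- if (v %in% names(in_tab)) in_tab[[v]] else 0L
    if (n_out != 1L || n_in != 1L) {
      abort(sprintf("vertex '%s' must have exactly one outgoing and one incoming edge (single circular path); found %d out, %d in",
                    v, n_out, n_in))
    }
  }
  if (nrow(edges) != length(vnames)) {
    abort("the edges must form a single cycle visiting every vertex exactly once")
  }
  # walk the cycle from the peak state; it must visit every vertex
  ord <- character(0)
  v <- peak_state
  out_of <- function(v) which(edges$source == v)
  for (k in seq_len(length(vnames))) {
    ord <- c(ord, v)
    v <- edges$target[out_of(v)]
  }
  if (v != peak_state || length(unique(ord)) != length(vnames)) {
    abort("the edges must form a single cycle visiting every vertex exactly once")
  }

  # canonical edge order: cycle order starting at the peak state
  edges <- edges[match(ord, edges$source), needed]
  edges$gap <- as.numeric(edges$gap)
  edges$penalty <- as.numeric(edges$penalty)
  edges <- tibble(id = seq_len(nrow(edges)), edges)
  vertices <- tibble(name = ord, peak = ord == peak_state)
  structure(list(vertices = vertices, edges = edges), class = "constraint_graph")
}

#' @export
print.constraint_graph <- function(x, ...) {
  arrow <- ifelse(x$edges$direction == "non_decreasing", "↑", "↓")
  cat(sprintf("<constraint_graph> %d state(s), peak state '%s'\n",
              nrow(x$vertices), peak_state(x)))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  [%d] %s %s %s  gap=%g  penalty=%g\n", x$edges$id,
                x$edges$source, arrow, x$edges$target,
                x$edges$gap, x$edges$penalty), sep = "")
  }
  invisible(x)
}

#' Peak state of a constraint graph
#' @param graph A [constraint_graph()].
#' @return The name of the R-peak vertex.
#' @export
peak_state <- function(graph) {
  check_graph(graph)
  graph$vertices$name[graph$vertices$peak][1]
}

check_graph <- function(graph) {
  if (!inherits(graph, "constraint_graph")) {
    abort("`graph` must be a constraint_graph object")
  }
  graph
}

#' Two-state baseline/R-peak constraint graph
#'
#' The simplest useful graph for R-peak detection: an "A" state for whatever
#' the signal does between beats and an "R" state for the QRS upstroke, in a
#' cycle `A -> R` (up change of at least `gap`) and `R -> A` (down change of
#' at least `gap`), both penalized by `penalty`. It is also the standard
#' starting point for greedy graph learning.
#'
#' @param gap Minimum amplitude of the up/down change (signal units).
#' @param penalty Penalty per changepoint.
#' @return A [constraint_graph()].
#' @export
ecg_graph <- function(gap = 100, penalty = 1e5) {
  constraint_graph(
    tibble(source = c("A", "R"), target = c("R", "A"),
           direction = c("non_decreasing", "non_increasing"),
           gap = gap, penalty = penalty),
    peak_state = "R")
}

# Canonical serialization key used to deduplicate candidate graphs: the
# per-edge (direction, gap, penalty) sequence in cycle order from the peak
# state. Vertex names other than the peak are interchangeable.
graph_key <- function(graph) {
  if (nrow(graph$edges) == 0) return("singleton")
  paste(sprintf("%s:%.17g:%.17g", substr(graph$edges$direction, 5, 5),
                graph$edges$gap, graph$edges$penalty),
        collapse = "|")
}

#' Read or write a constraint graph as JSON
#'
#' The interchange schema is
#' `{"vertices": [{"name": "A"}, {"name": "R", "peak": true}],`
#' `"edges": [{"id": 1, "source": ..., "target": ..., "direction": ...,`
#' `"gap": ..., "penalty": ...}]}`. Round-trips are lossless after
#' canonicalization (edges in cycle order from the peak state).
#'
#' @param path File path.
#' @return `read_graph_json()` returns a [constraint_graph()];
#'   `write_graph_json()` returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$vertices) || is.null(x$vertices$name)) {
    abort("graph JSON: missing 'vertices' with 'name' fields")
  }
  vn <- as.character(x$vertices$name)
  peak <- x$vertices$peak
  if (is.null(peak)) peak <- rep(FALSE, length(vn))
  peak[is.na(peak)] <- FALSE
  if (sum(peak) != 1) {
    abort("graph JSON: exactly one vertex must have \"peak\": true")
  }
  if (is.null(x$edges)) {
    if (length(vn) == 1) {
      return(constraint_graph(tibble(source = character(), target = character(),
                                     direction = character(), gap = double(),
                                     penalty = double()),
                              peak_state = vn[peak]))
    }
    abort("graph JSON: missing 'edges'")
  }
  ed <- as_tibble(x$edges)
  for (fld in c("source", "target", "direction", "gap", "penalty")) {
    if (is.null(ed[[fld]])) abort(sprintf("graph JSON: edge field '%s' is missing", fld))
  }
  undeclared <- setdiff(unique(c(ed$source, ed$target)), vn)
  if (length(undeclared) > 0) {
    abort(sprintf("graph JSON: edge references undeclared vertex '%s'", undeclared[1]))
  }
  constraint_graph(ed, peak_state = vn[peak])
}

#' @rdname read_graph_json
#' @param graph A [constraint_graph()].
#' @export
write_graph_json <- function(graph, path) {
  check_graph(graph)
  verts <- lapply(seq_len(nrow(graph$vertices)), function(i) {
    v <- list(name = graph$vertices$name[i])
    if (graph$vertices$peak[i]) v$peak <- TRUE
    v
  })
  ed <- lapply(seq_len(nrow(graph$edges)), function(i) {
    as.list(graph$edges[i, ])
  })
  json <- jsonlite::toJSON(list(vertices = verts, edges = ed),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
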