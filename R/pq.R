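#' Piecewise quadratic cost functions
#'
#' The functional-pruning solver represents the optimal cost-to-go at each
#' sample and hidden state as a function of the current segment mean `m`.
#' Under squared-error loss every such function is piecewise quadratic:
#' an ordered set of half-open intervals `[lo, hi)` over `m`, each carrying
#' coefficients `(a, b, c)` of `a*m^2 + b*m + c`. Intervals of the domain not
#' covered by any piece are infeasible and carry the value `+Inf`.
#'
#' `piecewise_quadratic()` constructs such a function from a data frame of
#' pieces (columns `lo`, `hi`, `a`, `b`, `c`); with `pieces = NULL` it is the
#' zero function over the whole domain.
#'
#' @param pieces A data frame with columns `lo`, `hi`, `a`, `b`, `c`, ordered
#'   and non-overlapping, or `NULL` for the zero function.
#' @param domain Numeric length-2: the mean interval `[m_min, m_max]`.
#' @return An object of class `piecewise_quadratic` with fields `pieces`
#'   (a tibble) and `domain`.
#' @examples
#' f <- piecewise_quadratic(domain = c(-5, 5))
#' g <- pq_add_loss(f, y = 3)      # (m - 3)^2
#' pq_evaluate(g, c(0, 3))
#' @export
piecewise_quadratic <- function(pieces = NULL, domain) {
  if (!is.numeric(domain) || length(domain) != 2 || !all(is.finite(domain)) ||
      domain[2] <= domain[1]) {
    abort("`domain` must be a finite interval c(m_min, m_max) with m_min < m_max")
  }
  if (is.null(pieces)) {
    pieces <- tibble(lo = domain[1], hi = domain[2], a = 0, b = 0, c = 0)
  }
  pieces <- as_tibble(pieces)
  needed <- c("lo", "hi", "a", "b", "c")
  if (!all(needed %in% names(pieces))) {
    abort("`pieces` needs columns lo, hi, a, b, c")
  }
  pieces <- pieces[needed]
  if (nrow(pieces) > 0) {
    if (any(!is.finite(as.matrix(pieces)))) abort("piece fields must be finite")
    if (any(pieces$hi <= pieces$lo)) abort("every piece needs hi > lo")
    if (any(pieces$a < -1e-12)) abort("quadratic coefficient a must be >= 0")
    if (nrow(pieces) > 1 &&
        any(pieces$lo[-1] < pieces$hi[-nrow(pieces)] - 1e-12)) {
      abort("pieces must be ordered and non-overlapping")
    }
    if (any(pieces$lo < domain[1] - 1e-9) || any(pieces$hi > domain[2] + 1e-9)) {
      abort("pieces must lie within the domain")
    }
  }
  structure(list(pieces = pieces, domain = as.numeric(domain)),
            class = "piecewise_quadratic")
}

pq_mat <- function(f) {
  m <- as.matrix(f$pieces)
  storage.mode(m) <- "double"
  m
}

pq_from_mat <- function(m, domain) {
  piecewise_quadratic(as_tibble(m), domain)
}

check_pq <- function(f, arg = "f") {
  if (!inherits(f, "piecewise_quadratic")) {
    abort(sprintf("`%s` must be a piecewise_quadratic object", arg))
  }
  f
}

#' Add one squared-error data term to a cost function
#'
#' Returns `g(m) = f(m) + (m - y)^2`, the Gaussian negative log-likelihood
#' contribution (up to constants) of one observed sample `y`. Piece intervals
#' are unchanged.
#'
#' @param f A [piecewise_quadratic()] object.
#' @param y A single finite observation.
#' @return A `piecewise_quadratic`.
#' @export
pq_add_loss <- function(f, y) {
  check_pq(f)
  if (!is.numeric(y) || length(y) != 1 || !is.finite(y)) {
    abort("`y` must be a single finite number")
  }
  pq_from_mat(pq_add_loss_cpp(pq_mat(f), y), f$domain)
}

#' Pointwise minimum of two cost functions
#'
#' Returns `h(m) = min(f(m), g(m))` over the shared domain, inserting new
#' breakpoints at the real crossings of the piecewise quadratic difference.
#' Where the functions tie exactly, `f` wins (the solver passes the
#' "no change" branch as `f`, so ties yield the sparser model).
#'
#' @param f,g [piecewise_quadratic()] objects on the same domain.
#' @return A `piecewise_quadratic`.
#' @export
pq_pointwise_min <- function(f, g) {
  check_pq(f); check_pq(g, "g")
  if (!isTRUE(all.equal(f$domain, g$domain, tolerance = 1e-12))) {
    abort("`f` and `g` must share the same domain")
  }
  pq_from_mat(pq_pointwise_min_cpp(pq_mat(f), pq_mat(g),
                                   f$domain[1], f$domain[2]),
              f$domain)
}

#' Gap-constrained minimum transform of a cost function
#'
#' The change branch of the dynamic program. For a `non_decreasing` edge with
#' gap `gap` the new segment mean `m` must exceed the previous mean by at
#' least `gap`, so `out(m) = min over m' <= m - gap of f(m')`; for a
#' `non_increasing` edge `out(m) = min over m' >= m + gap of f(m')`. Where the
#' constrained region is empty the output is infeasible (no piece, `+Inf`).
#'
#' @param f A [piecewise_quadratic()] object.
#' @param direction `"non_decreasing"` or `"non_increasing"`.
#' @param gap Minimum magnitude of the mean change, `>= 0` (signal units).
#' @return A `piecewise_quadratic`, monotone non-increasing in `m` for
#'   `non_decreasing` edges (non-decreasing for `non_increasing` edges).
#' @export
pq_min_transform <- function(f, direction = c("non_decreasing", "non_increasing"),
                             gap = 0) {
  check_pq(f)
  direction <- match.arg(direction)
  if (!is.numeric(gap) || length(gap) != 1 || !is.finite(gap) || gap < 0) {
    abort("`gap` must be a single finite number >= 0")
  }
  dir <- if (direction == "non_decreasing") 1L else -1L
  pq_from_mat(pq_min_transform_cpp(pq_mat(f), dir, gap,
                                   f$domain[1], f$domain[2]),
              f$domain)
}

#' Evaluate a piecewise quadratic cost function
#'
#' @param f A [piecewise_quadratic()] object.
#' @param m Numeric vector of mean values; values in uncovered (infeasible)
#'   regions evaluate to `Inf`.
#' @return Numeric vector of the same length as `m`.
#' @export
pq_evaluate <- function(f, m) {
  check_pq(f)
  pq_eval_cpp(pq_mat(f), as.numeric(m))
}

#' Minimum (and argmin) of a piecewise quadratic over an interval
#'
#' @param f A [piecewise_quadratic()] object.
#' @param interval Numeric length-2 closed interval; defaults to the domain.
#' @return A list with `value` and `argmin` (leftmost minimizer).
#' @export
pq_minimum <- function(f, interval = f$domain) {
  check_pq(f)
  pq_min_on_cpp(pq_mat(f), interval[1], interval[2])
}

#' @export
print.piecewise_quadratic <- function(x, ...) {
  cat(sprintf("<piecewise_quadratic> %d piece(s) on [%g, %g]\n",
              nrow(x$pieces), x$domain[1], x$domain[2]))
  print(x$pieces, ...)
  invisible(x)
}
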