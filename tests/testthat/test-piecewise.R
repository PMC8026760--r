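# The piecewise-quadratic algebra underneath the functional-pruning solver.

# Random continuous piecewise quadratic (the solver only ever constructs
# continuous cost functions; continuity is part of the container's contract).
random_pq <- function(n_pieces, domain = c(-5, 5)) {
  bp <- sort(c(domain[1], runif(n_pieces - 1, domain[1], domain[2]), domain[2]))
  a <- runif(n_pieces, 0, 2)
  b <- runif(n_pieces, -3, 3)
  cc <- numeric(n_pieces)
  cc[1] <- runif(1, -3, 3)
  for (j in seq_len(n_pieces)[-1]) {
    x <- bp[j]
    prev <- a[j - 1] * x^2 + b[j - 1] * x + cc[j - 1]
    cc[j] <- prev - a[j] * x^2 - b[j] * x
  }
  piecewise_quadratic(
    tibble::tibble(lo = bp[-length(bp)], hi = bp[-1], a = a, b = b, c = cc),
    domain = domain)
}

test_that("adding a data term expands the square and keeps intervals", {
  f <- piecewise_quadratic(domain = c(-10, 10))
  g <- pq_add_loss(f, 3)
  expect_equal(nrow(g$pieces), 1)
  expect_equal(unlist(g$pieces[1, c("a", "b", "c")]), c(a = 1, b = -6, c = 9))

  # f(m) = (m-1)^2, add y = 1 -> 2(m-1)^2
  f2 <- pq_add_loss(f, 1)
  g2 <- pq_add_loss(f2, 1)
  expect_equal(unlist(g2$pieces[1, c("a", "b", "c")]), c(a = 2, b = -4, c = 2))
})

test_that("adding a data term adds (m - y)^2 pointwise on random functions", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      f <- random_pq(5)
      g <- pq_add_loss(f, 0.7)
      m <- seq(-4.99, 4.99, length.out = 100)
      expect_equal(pq_grid_eval(g, m) - pq_grid_eval(f, m), (m - 0.7)^2,
                   tolerance = 1e-9)
    }
  })
  expect_error(pq_add_loss(piecewise_quadratic(domain = c(0, 1)), Inf),
               "finite")
})

test_that("pointwise minimum crosses parabolas at their intersection", {
  dom <- c(-10, 10)
  f <- pq_add_loss(piecewise_quadratic(domain = dom), 0)   # m^2
  g <- pq_add_loss(piecewise_quadratic(domain = dom), 2)   # (m-2)^2
  h <- pq_pointwise_min(f, g)
  expect_equal(pq_evaluate(h, c(-1, 0, 0.5)), c(1, 0, 0.25))   # m^2 side
  expect_equal(pq_evaluate(h, c(1.5, 2, 5)), c(0.25, 0, 9))    # (m-2)^2 side
  expect_true(any(abs(h$pieces$lo - 1) < 1e-9))                # crossing at 1

  # constant dominance
  c5 <- piecewise_quadratic(tibble::tibble(lo = -1, hi = 1, a = 0, b = 0, c = 5),
                            domain = c(-1, 1))
  c7 <- piecewise_quadratic(tibble::tibble(lo = -1, hi = 1, a = 0, b = 0, c = 7),
                            domain = c(-1, 1))
  expect_equal(pq_evaluate(pq_pointwise_min(c5, c7), c(-0.5, 0.9)), c(5, 5))

  expect_error(pq_pointwise_min(c5, f), "domain")
})

test_that("pointwise minimum matches a dense grid on random functions", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      f <- random_pq(4)
      g <- random_pq(4)
      h <- pq_pointwise_min(f, g)
      m <- seq(-4.999, 4.999, length.out = 1000)
      expect_equal(pq_grid_eval(h, m),
                   pmin(pq_grid_eval(f, m), pq_grid_eval(g, m)),
                   tolerance = 1e-9)
    }
  })
})

test_that("constrained min transform is the running minimum, shifted by the gap", {
  dom <- c(-10, 10)
  f <- pq_add_loss(piecewise_quadratic(domain = dom), 3)  # (m-3)^2

  up0 <- pq_min_transform(f, "non_decreasing", gap = 0)
  m <- seq(-9.9, 9.9, length.out = 200)
  expect_equal(pq_grid_eval(up0, m), ifelse(m <= 3, (m - 3)^2, 0),
               tolerance = 1e-9)

  up2 <- pq_min_transform(f, "non_decreasing", gap = 2)
  m_ok <- m[m >= -8]  # below m0 + gap the constrained region is empty
  expect_equal(pq_grid_eval(up2, m_ok), ifelse(m_ok <= 5, (m_ok - 5)^2, 0),
               tolerance = 1e-9)
  expect_equal(pq_evaluate(up2, -9.5), Inf)

  expect_error(pq_min_transform(f, "non_decreasing", gap = -1), "gap")
})

test_that("constrained min transform matches a brute-force grid oracle", {
  withr::with_seed(11, {
    grid <- seq(-5, 5, length.out = 2000)
    for (rep in 1:5) {
      f <- random_pq(5)
      fg <- pq_grid_eval(f, grid)
      gap <- 1.5
      down <- pq_min_transform(f, "non_increasing", gap = gap)
      ref <- vapply(grid, function(m) {
        ok <- grid >= m + gap
        # include the exact boundary point so the oracle's only error is
        # the O(step^2) interior quantization
        min(pq_grid_eval(f, m + gap), if (any(ok)) min(fg[ok]) else Inf)
      }, numeric(1))
      got <- pq_grid_eval(down, grid)
      keep <- is.finite(ref) & is.finite(got)
      # the oracle can miss a kink minimizer by up to half a grid step
      expect_lt(max(abs(got[keep] - ref[keep])), 5e-3)
      expect_true(all(got[keep] <= ref[keep] + 1e-8))  # true min <= grid min
      # monotone non-decreasing output for a non_increasing edge
      expect_true(all(diff(got[is.finite(got)]) >= -1e-9))
    }
  })
})
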