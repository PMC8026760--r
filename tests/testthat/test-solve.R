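# Exactness and invariants of the graph-constrained segmentation solver.

test_that("a constant signal with prohibitive penalties stays one segment", {
  fit <- gccd_solve(rep(5, 4), ecg_graph(gap = 1, penalty = 1e6))
  expect_equal(nrow(fit$segments), 1)
  # ties over states are broken toward the first vertex in canonical cycle
  # order, which starts at the peak state
  expect_equal(fit$segments$state, "R")
  expect_equal(fit$segments$mean, 5)
  expect_equal(fit$total_cost, 0)
  validate_segmentation(fit)
})

test_that("a clean step is segmented at the true change with the true means", {
  g <- ecg_graph(gap = 1, penalty = 1)
  y <- c(0, 0, 0, 10, 10, 10)
  fit <- gccd_solve(y, g)
  expect_equal(fit$segments$start, c(0L, 3L))
  expect_equal(fit$segments$state, c("A", "R"))
  expect_equal(fit$segments$mean, c(0, 10))
  expect_equal(fit$changes$position, 2L)
  expect_equal(fit$total_cost, 1)
  expect_equal(fit$total_cost, oracle_solve(y, g), tolerance = 1e-9)
})

test_that("a binding gap constraint is honored exactly", {
  # the up edge demands a jump of >= 5 but the data only step by 2
  g <- ecg_graph(gap = 5, penalty = 0.1)
  y <- c(0, 0, 2, 2)
  fit <- gccd_solve(y, g)
  expect_equal(fit$total_cost, oracle_solve(y, g), tolerance = 1e-9)
  validate_segmentation(fit)
  # with a domain wide enough to fit the jump, the two-segment solution
  # must satisfy m2 - m1 >= 5
  fit2 <- gccd_solve(y, g, m_margin = 10)
  expect_equal(fit2$total_cost, oracle_solve(y, g, m_margin = 10),
               tolerance = 1e-9)
  if (nrow(fit2$segments) == 2) {
    expect_gte(diff(fit2$segments$mean), 5 - 1e-9)
  }
})

test_that("solver equals the exhaustive enumeration oracle on random instances", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      inst <- random_instance(n_max = 7)
      fit <- gccd_solve(inst$y, inst$graph, m_margin = inst$m_margin)
      expect_equal(fit$total_cost,
                   oracle_solve(inst$y, inst$graph, m_margin = inst$m_margin),
                   tolerance = 1e-6)
      validate_segmentation(fit)
    }
  })
})

test_that("with one state and no edges the fit is the sample mean", {
  y <- c(1, 2, 3, 4, 7)
  g1 <- constraint_graph(
    data.frame(source = character(), target = character(),
               direction = character(), gap = double(), penalty = double()),
    peak_state = "A")
  fit <- gccd_solve(y, g1)
  expect_equal(fit$segments$mean, mean(y), tolerance = 1e-12)
  expect_equal(fit$total_cost, sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("scaling all penalties up never increases the number of changes", {
  withr::with_seed(202, {
    for (rep in 1:15) {
      n <- sample(8:20, 1)
      y <- cumsum(rnorm(n))
      g <- random_graph(n_vertices = sample(2:3, 1), gap_max = 1, penalty_max = 2)
      n1 <- nrow(gccd_solve(y, g, m_margin = 5)$changes)
      g10 <- g
      g10$edges$penalty <- g10$edges$penalty * 10
      n2 <- nrow(gccd_solve(y, g10, m_margin = 5)$changes)
      expect_lte(n2, n1)
    }
  })
})

test_that("the optimum is insensitive to widening the mean domain", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      y <- rnorm(12)
      g <- random_graph(n_vertices = 2, gap_max = 0.5, penalty_max = 1)
      f1 <- gccd_solve(y, g, m_margin = 2)
      f2 <- gccd_solve(y, g, m_margin = 4)
      # optimal means lie strictly inside the narrower domain here
      expect_true(all(f1$segments$mean > min(y) - 2 + 1e-6 &
                        f1$segments$mean < max(y) + 2 - 1e-6))
      expect_equal(f1$total_cost, f2$total_cost, tolerance = 1e-9)
    }
  })
})

test_that("infeasible graphs and bad inputs are rejected with clear errors", {
  expect_error(gccd_solve(numeric(0), ecg_graph()), "at least one sample")
  expect_error(gccd_solve(c(1, NA, 2), ecg_graph()), "finite")
  # gap far beyond the mean domain: any R segment is unreachable, but the
  # cycle still permits the all-A (never change) path, so this must solve
  fit <- gccd_solve(c(0, 1, 0), ecg_graph(gap = 1e6, penalty = 1), m_margin = 1)
  expect_equal(nrow(fit$segments), 1)
})

test_that("pruning keeps per-sample piece counts small", {
  fit <- gccd_solve(rep(2, 50), ecg_graph(gap = 1, penalty = 5), m_margin = 1)
  ps <- pruning_stats(fit)
  expect_lte(max(ps$pieces), 5)
  expect_equal(sort(unique(ps$sample)), 0:49)

  # N = 1: exactly one piece per state
  f1 <- gccd_solve(3, ecg_graph(gap = 1, penalty = 1), m_margin = 1)
  expect_true(all(pruning_stats(f1)$pieces == 1))

  # sublinear growth of the median piece count on noise
  withr::with_seed(404, {
    y_long <- rnorm(2000)
    y_short <- y_long[1:500]
    g <- ecg_graph(gap = 0.5, penalty = 2)
    med_long <- stats::median(pruning_stats(gccd_solve(y_long, g))$pieces)
    med_short <- stats::median(pruning_stats(gccd_solve(y_short, g))$pieces)
    expect_lt(med_long, med_short * 4)  # far below the 4x of linear growth
  })
})
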