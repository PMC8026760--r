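# Independent oracles used across the suite. Nothing here touches the
# package's piecewise-quadratic machinery: costs are recomputed by exhaustive
# enumeration and closed-form algebra.

# Dense-grid evaluation of a piecewise_quadratic, straight from its pieces.
pq_grid_eval <- function(f, m) {
  vapply(m, function(x) {
    hit <- which(x >= f$pieces$lo - 1e-12 & x < f$pieces$hi)
    if (length(hit) == 0) {
      hit <- which(abs(x - f$pieces$hi) <= 1e-9)
      if (length(hit) == 0) return(Inf)
    }
    p <- f$pieces[hit[1], ]
    p$a * x^2 + p$b * x + p$c
  }, numeric(1))
}

# Exact minimum cost of the graph-constrained segmentation problem by
# exhaustive enumeration: every subset of change positions x every start
# vertex, with each fixed configuration's chain-constrained mean problem
# solved in closed form over all active sets of the gap constraints
# (means clamped to the solver's domain).
oracle_solve <- function(y, graph, m_margin = NULL) {
  n <- length(y)
  rng <- range(y)
  span <- rng[2] - rng[1]
  if (is.null(m_margin)) m_margin <- if (span > 0) 0.1 * span else 1
  m0 <- rng[1] - m_margin
  m1 <- rng[2] + m_margin

  vn <- graph$vertices$name
  ed <- graph$edges
  out_edge <- function(v) which(ed$source == v)

  best <- Inf
  positions <- if (n >= 2) 0:(n - 2) else integer(0)
  subsets <- unlist(lapply(0:length(positions), function(k) {
    if (k == 0) return(list(integer(0)))
    asplit(utils::combn(positions, k), 2)
  }), recursive = FALSE)

  for (chg in subsets) {
    k <- length(chg) + 1
    starts <- c(0, chg + 1)
    ends <- c(chg + 1, n)
    nseg <- ends - starts
    S <- vapply(seq_len(k), function(j) sum(y[(starts[j] + 1):ends[j]]), 0)
    Q <- vapply(seq_len(k), function(j) sum(y[(starts[j] + 1):ends[j]]^2), 0)
    for (v0 in vn) {
      # state path and traversed edges are forced by the single cycle
      states <- character(k)
      eidx <- integer(max(k - 1, 0))
      v <- v0
      ok <- TRUE
      for (j in seq_len(k)) {
        states[j] <- v
        if (j < k) {
          e <- out_edge(v)
          if (length(e) != 1) { ok <- FALSE; break }
          eidx[j] <- e
          v <- ed$target[e]
        }
      }
      if (!ok) next
      pen <- if (k > 1) sum(ed$penalty[eidx]) else 0
      delta <- if (k > 1) ifelse(ed$direction[eidx] == "non_decreasing", 1, -1) else numeric(0)
      gaps <- if (k > 1) ed$gap[eidx] else numeric(0)
      step <- delta * gaps  # m_{j+1} = m_j + step_j when constraint j is active

      n_active_sets <- 2^(k - 1)
      for (mask in 0:(n_active_sets - 1)) {
        active <- if (k > 1) bitwAnd(mask, 2^(0:(k - 2))) > 0 else logical(0)
        run_id <- cumsum(c(1, as.integer(!active)))
        offset <- numeric(k)
        for (j in seq_len(k - 1)) {
          offset[j + 1] <- if (active[j]) offset[j] + step[j] else 0
        }
        m <- numeric(k)
        feasible <- TRUE
        for (r in unique(run_id)) {
          jj <- which(run_id == r)
          lo_mu <- max(m0 - offset[jj])
          hi_mu <- min(m1 - offset[jj])
          if (hi_mu < lo_mu) { feasible <- FALSE; break }
          mu <- (sum(S[jj]) - sum(nseg[jj] * offset[jj])) / sum(nseg[jj])
          mu <- min(max(mu, lo_mu), hi_mu)
          m[jj] <- mu + offset[jj]
        }
        if (!feasible) next
        viol <- FALSE
        for (j in seq_len(k - 1)) {
          if (delta[j] * (m[j] - m[j + 1]) + gaps[j] > 1e-9) { viol <- TRUE; break }
        }
        if (viol) next
        cost <- sum(nseg * m^2 - 2 * S * m + Q) + pen
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# Random single-cycle graph with |V| in 1..3; V = 1 is the edgeless
# single-state degenerate graph.
random_graph <- function(n_vertices = sample(1:3, 1),
                         gap_max = 3, penalty_max = 5) {
  if (n_vertices == 1) {
    return(constraint_graph(
      data.frame(source = character(), target = character(),
                 direction = character(), gap = double(), penalty = double()),
      peak_state = "R"))
  }
  vn <- c("R", paste0("V", seq_len(n_vertices - 1)))
  constraint_graph(
    data.frame(source = vn,
               target = c(vn[-1], vn[1]),
               direction = sample(c("non_decreasing", "non_increasing"),
                                  n_vertices, replace = TRUE),
               gap = runif(n_vertices, 0, gap_max),
               penalty = runif(n_vertices, 0, penalty_max)),
    peak_state = "R")
}

random_instance <- function(n_max = 8) {
  n <- sample(3:n_max, 1)
  list(y = round(rnorm(n, sd = 2), 2), graph = random_graph(), m_margin = 4)
}

# Tiny deterministic 4-state cycle used in learning round-trips: an
# up-up-down-down wave through states B1 -> B2 -> R -> D, peaks in R.
four_state_graph <- function(gap = 8, penalty = 6) {
  constraint_graph(
    data.frame(source = c("B", "U", "R", "D"),
               target = c("U", "R", "D", "B"),
               direction = c("non_decreasing", "non_decreasing",
                             "non_increasing", "non_increasing"),
               gap = gap, penalty = penalty),
    peak_state = "R")
}
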