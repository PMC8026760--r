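# Greedy constraint-graph structure learning and its edit algebra.

test_that("single edits rewrite the cycle as specified", {
  g <- ecg_graph(gap = 100, penalty = 1e5)
  up_id <- g$edges$id[g$edges$source == "A"]  # the A -> R up edge

  flipped <- apply_edit(g, "flip_direction", up_id)
  expect_equal(nrow(flipped$vertices), 2)
  e <- flipped$edges
  expect_equal(e$direction[e$source == "A"], "non_increasing")
  expect_equal(e$direction[e$source == "R"], "non_increasing")

  # add_node_v2 inserts K with pattern (up, down), copying gap and penalty
  v2 <- apply_edit(g, "add_node_v2", up_id)
  expect_equal(nrow(v2$vertices), 3)
  k <- setdiff(v2$vertices$name, c("A", "R"))
  e <- v2$edges
  expect_equal(e$direction[e$source == "A" & e$target == k], "non_decreasing")
  expect_equal(e$direction[e$source == k & e$target == "R"], "non_increasing")
  expect_equal(e$gap[e$source == "A"], 100)
  expect_equal(e$penalty[e$source == k], 1e5)
  # the other edge is untouched
  expect_equal(e$direction[e$source == "R"], "non_increasing")

  # deleting the peak state is inapplicable
  expect_null(apply_edit(g, "delete_target", up_id))

  # parameter edits double or halve
  pu <- apply_edit(g, "penalty_up", up_id)
  expect_equal(sort(pu$edges$penalty), c(1e5, 2e5))
  gd <- apply_edit(g, "gap_down", up_id)
  expect_equal(sort(gd$edges$gap), c(50, 100))

  # add_two_nodes gives the (d, !d, d) pattern
  g2 <- apply_edit(g, "add_two_nodes", up_id)
  expect_equal(nrow(g2$vertices), 4)
  path_dirs <- g2$edges$direction[g2$edges$source != "R"]
  expect_equal(path_dirs, c("non_decreasing", "non_increasing", "non_decreasing"))
})

test_that("node deletion merges edges, keeping the edited edge's parameters", {
  g4 <- four_state_graph(gap = 8, penalty = 6)
  # delete the source of the U -> R edge: B -> R keeps (up, 8, 6)
  ur <- g4$edges$id[g4$edges$source == "U"]
  del <- apply_edit(g4, "delete_source", ur)
  expect_equal(nrow(del$vertices), 3)
  expect_false("U" %in% del$vertices$name)
  e <- del$edges[del$edges$target == "R", ]
  expect_equal(e$source, "B")
  expect_equal(e$direction, "non_decreasing")
  # deletions on a 2-vertex cycle are inapplicable (would leave a self-loop)
  g2 <- ecg_graph()
  for (id in g2$edges$id) {
    expect_null(apply_edit(g2, "delete_source", id))
  }
})

test_that("candidate enumeration respects the 11-per-edge bound and invariants", {
  expect_length(edit_kinds, 11)
  g <- ecg_graph(gap = 100, penalty = 1e5)
  cands <- find_graph_candidates(g)
  expect_lte(length(cands), 22)
  parent_key <- gccd:::graph_key(g)
  for (cand in cands) {
    expect_s3_class(cand, "constraint_graph")       # constructor validates
    expect_equal(nrow(cand$edges), nrow(cand$vertices))
    expect_true("R" %in% cand$vertices$name)
    expect_false(gccd:::graph_key(cand) == parent_key)
  }
  # no duplicates after canonical serialization
  keys <- vapply(cands, gccd:::graph_key, "")
  expect_equal(anyDuplicated(keys), 0L)

  g3 <- apply_edit(g, "add_node_v1", 1)
  expect_lte(length(find_graph_candidates(g3)), 33)
})

test_that("label error is zero on a round-trip and counts misses otherwise", {
  g <- ecg_graph(gap = 10, penalty = 10)
  sim <- gen_graph_walk(g, dwell_range = c(20, 40), noise_sd = 0.5,
                        n_cycles = 10, seed = 3)
  labels <- gen_labels(locate_peaks(sim$truth$segments, "R")$sample,
                       half_width = 5)
  expect_equal(label_error(g, sim$signal, labels), 0)
  expect_equal(label_error(g, sim$signal, labels[0, ]), 0)
  # a graph whose peak state is never entered leaves every region missed
  never <- ecg_graph(gap = 1e9, penalty = 10)
  expect_equal(label_error(never, sim$signal, labels[1:5, ]),
               5)
})

test_that("greedy learning strictly improves, terminates, and is reproducible", {
  sim <- walk4(0)
  labels <- walk4_labels(sim)
  init <- ecg_graph(gap = 100, penalty = 1e5)
  res <- greedy_learn(sim$signal, labels, init_graph = init, max_iter = 25)
  err <- res$trace$train_error
  expect_true(all(diff(err) < 0))
  expect_lte(max(res$trace$iteration), err[1] + 1)
  expect_equal(err[length(err)], 0)
  # structure grew beyond the 2-state init to express the 4-state wave
  expect_gte(nrow(res$graph$vertices), 3)

  res2 <- greedy_learn(sim$signal, labels, init_graph = init, max_iter = 25)
  expect_identical(gccd:::graph_key(res$graph), gccd:::graph_key(res2$graph))
  expect_identical(res$trace, res2$trace)

  # immediate convergence when the init graph already solves the labels
  g <- ecg_graph(gap = 10, penalty = 10)
  easy <- gen_graph_walk(g, dwell_range = c(20, 40), noise_sd = 0.5,
                         n_cycles = 5, seed = 3)
  easy_labs <- gen_labels(locate_peaks(easy$truth$segments, "R")$sample,
                          half_width = 5)
  res0 <- greedy_learn(easy$signal, easy_labs, init_graph = g)
  expect_equal(nrow(res0$trace), 1)
  expect_identical(gccd:::graph_key(res0$graph), gccd:::graph_key(g))
})

test_that("a richer initial graph does at least as well, at least as fast", {
  sim <- walk4(3)
  labels <- walk4_labels(sim)
  simple <- greedy_learn(sim$signal, labels,
                         init_graph = ecg_graph(gap = 100, penalty = 1e5),
                         max_iter = 25)
  rich <- greedy_learn(sim$signal, labels,
                       init_graph = four_state_graph(gap = 100, penalty = 1e5),
                       max_iter = 25)
  expect_lte(rich$trace$train_error[nrow(rich$trace)],
             simple$trace$train_error[nrow(simple$trace)])
  expect_lte(max(rich$trace$iteration), max(simple$trace$iteration))
})

test_that("fold splitting is balanced, disjoint, and seed-deterministic", {
  labs <- gen_labels(seq(50, by = 100, length.out = 10), half_width = 10)
  f <- split_folds(labs, k = 5, seed = 11)
  expect_equal(unname(as.vector(table(f$fold))), rep(2L, 5))
  labs11 <- gen_labels(seq(50, by = 100, length.out = 11), half_width = 10)
  f11 <- split_folds(labs11, k = 5, seed = 11)
  expect_equal(sort(as.vector(table(f11$fold))), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(f11, split_folds(labs11, k = 5, seed = 11))
  expect_false(identical(f11$fold, split_folds(labs11, k = 5, seed = 12)$fold))
  # the folds partition the input
  expect_identical(dplyr::arrange(f11[c("start", "end")], start), labs11)
  expect_error(split_folds(labs[1:3, ], k = 5, seed = 1), "fewer label")
})
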