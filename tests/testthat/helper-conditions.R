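# Study conditions for the learning round-trip: a known 4-state cycle
# (up-up-down-down wave) with strongly variable dwells and step sizes, so a
# two-state model cannot center every peak and the search must edit the
# graph. SNR (minimum step / noise sd) is 22.
walk4 <- function(seed) {
  gen_graph_walk(four_state_graph(gap = 100, penalty = 1e5),
                 dwell_range = c(5, 60), base_mean = 0, noise_sd = 5,
                 n_cycles = 8, seed = seed, excess_range = c(10, 80))
}

walk4_labels <- function(sim) {
  gen_labels(locate_peaks(sim$truth$segments, "R")$sample, half_width = 8)
}
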