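#' Simulate a piecewise-constant signal by walking a constraint graph
#'
#' Generative counterpart of the segmentation model: the walk starts in the
#' first vertex of the cycle, dwells in each state for a uniform-random
#' number of samples, and at each transition moves the latent mean in the
#' traversed edge's direction by that edge's gap plus a positive uniform
#' excess (so every traversed constraint holds with strict slack). I.i.d.
#' Gaussian noise is added on top. The generator is a pure function of its
#' arguments and `seed`.
#'
#' @param graph A [constraint_graph()].
#' @param dwell_range Integer length-2: min/max samples spent in one state
#'   (min `>= 1`).
#' @param base_mean Latent mean of the first segment.
#' @param noise_sd Standard deviation of the additive Gaussian noise (`>= 0`).
#' @param n_cycles Number of times the cycle is walked.
#' @param seed Integer seed.
#' @param excess_range Positive uniform range of the extra mean change beyond
#'   the edge gap (signal units).
#' @return A list with `signal` (tibble `sample`, `value`) and `truth`
#'   (list with `segments` — tibble `start`, `end`, `state`, `mean` — and
#'   `changepoints`, the 0-based indices of the last sample before each
#'   change).
#' @export
gen_graph_walk <- function(graph, dwell_range = c(20, 60), base_mean = 0,
                           noise_sd = 1, n_cycles = 10, seed = 1,
                           excess_range = c(0.5, 1.5)) {
  check_graph(graph)
  dwell_range <- as.integer(dwell_range)
  if (length(dwell_range) != 2 || dwell_range[1] < 1 ||
      dwell_range[2] < dwell_range[1]) {
    abort("`dwell_range` must be c(min, max) with 1 <= min <= max")
  }
  if (excess_range[1] <= 0 || excess_range[2] < excess_range[1]) {
    abort("`excess_range` must be positive and increasing")
  }
  vn <- graph$vertices$name
  ed <- graph$edges
  n_states <- if (nrow(ed) > 0) n_cycles * length(vn) else n_cycles

  withr::with_seed(seed, {
    dwell <- sample(seq(dwell_range[1], dwell_range[2]), n_states, replace = TRUE)
    states <- character(n_states)
    means <- numeric(n_states)
    v <- vn[1]
    m <- base_mean
    for (j in seq_len(n_states)) {
      states[j] <- v
      means[j] <- m
      if (nrow(ed) > 0) {
        e <- ed[ed$source == v, ]
        step <- e$gap + runif(1, excess_range[1], excess_range[2])
        m <- m + if (e$direction == "non_decreasing") step else -step
        v <- e$target
      }
    }
    ends <- cumsum(dwell)
    starts <- c(0L, head(ends, -1))
    n <- sum(dwell)
    latent <- rep(means, times = dwell)
    value <- latent + rnorm(n, 0, noise_sd)
    list(signal = tibble(sample = seq_len(n) - 1L, value = value),
         truth = list(
           segments = tibble(start = starts, end = ends,
                             state = states, mean = means),
           changepoints = as.integer(head(ends, -1) - 1L)))
  })
}

#' Configuration for the synthetic ECG generator
#'
#' Defaults describe a clean adult ECG at the MIT-BIH sampling rate: mean RR
#' interval 0.8 s (75 bpm) with 50 ms beat-to-beat jitter, Gaussian-shaped
#' P/Q/R/S/T waves (amplitudes in signal units, widths and offsets relative
#' to the R wave in seconds), additive Gaussian noise, and a low-frequency
#' sinusoidal baseline wander.
#'
#' @param n_beats Number of beats (`>= 1`).
#' @param sampling_rate Hz.
#' @param rr_mean,rr_jitter Mean and standard deviation of the RR interval
#'   (seconds).
#' @param waves A data frame with columns `wave`, `amp`, `width`, `offset`
#'   describing the per-beat Gaussian bumps (one of them must be `"R"`).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param baseline_amp,baseline_freq Amplitude (signal units) and frequency
#'   (Hz) of the baseline-wander sinusoid.
#' @param seed Integer seed.
#' @return A named list of class `ecg_sim_config`.
#' @export
ecg_sim_config <- function(n_beats = 200, sampling_rate = 360,
                           rr_mean = 0.8, rr_jitter = 0.05,
                           waves = NULL,
                           noise_sd = 0.05,
                           baseline_amp = 0.1, baseline_freq = 0.33,
                           seed = 1) {
  if (is.null(waves)) {
    waves <- tibble(
      wave = c("P", "Q", "R", "S", "T"),
      amp = c(0.15, -0.10, 1.00, -0.15, 0.30),
      width = c(0.025, 0.010, 0.012, 0.010, 0.050),
      offset = c(-0.200, -0.030, 0.000, 0.030, 0.250))
  }
  cfg <- list(n_beats = as.integer(n_beats), sampling_rate = sampling_rate,
              rr_mean = rr_mean, rr_jitter = rr_jitter,
              waves = as_tibble(waves), noise_sd = noise_sd,
              baseline_amp = baseline_amp, baseline_freq = baseline_freq,
              seed = as.integer(seed))
  if (cfg$n_beats < 1) abort("`n_beats` must be >= 1")
  if (cfg$sampling_rate <= 0) abort("`sampling_rate` must be > 0")
  if (any(cfg$waves$width <= 0)) abort("wave widths must be > 0")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!"R" %in% cfg$waves$wave) abort("`waves` must include an R wave")
  span <- max(cfg$waves$offset + 3 * cfg$waves$width) -
    min(cfg$waves$offset - 3 * cfg$waves$width)
  if (cfg$rr_mean < span) {
    abort(sprintf("rr_mean = %g s is too small to fit the wave complex (span %.3f s)",
                  cfg$rr_mean, span))
  }
  structure(cfg, class = "ecg_sim_config")
}

#' Simulate an ECG-like beat train with known R-peak ground truth
#'
#' Sums per-beat Gaussian bumps (P up, Q down, R up, S down, T up) at
#' jittered RR intervals, then adds a baseline-wander sinusoid and Gaussian
#' noise. The ground-truth R-peak of each beat is the sample at the centre
#' (argmax) of that beat's clean R bump; it does not depend on the baseline
#' or noise amplitude, so the truth is invariant to `baseline_amp`. The
#' generator is bit-reproducible for a given config (including its seed).
#'
#' @param config An [ecg_sim_config()].
#' @return A list with `signal` (tibble `sample`, `value`), `r_peaks`
#'   (integer vector of true R-peak samples, strictly increasing) and
#'   `config`.
#' @export
gen_ecg <- function(config = ecg_sim_config()) {
  if (!inherits(config, "ecg_sim_config")) {
    config <- do.call(ecg_sim_config, config)
  }
  fs <- config$sampling_rate
  withr::with_seed(config$seed, {
    rr <- rnorm(config$n_beats, config$rr_mean, config$rr_jitter)
    rr <- pmin(pmax(rr, 0.5 * config$rr_mean), 1.5 * config$rr_mean)
    r_time <- cumsum(c(0.5 * config$rr_mean, head(rr, -1)))
    duration <- r_time[length(r_time)] + 0.5 * config$rr_mean
    n <- as.integer(ceiling(duration * fs))
    t <- (seq_len(n) - 1L) / fs

    clean <- numeric(n)
    for (b in seq_along(r_time)) {
      for (w in seq_len(nrow(config$waves))) {
        tc <- r_time[b] + config$waves$offset[w]
        sd_w <- config$waves$width[w]
        lo <- max(1L, as.integer(floor((tc - 5 * sd_w) * fs)) + 1L)
        hi <- min(n, as.integer(ceiling((tc + 5 * sd_w) * fs)) + 1L)
        if (hi < lo) next
        idx <- lo:hi
        clean[idx] <- clean[idx] +
          config$waves$amp[w] * exp(-((t[idx] - tc)^2) / (2 * sd_w^2))
      }
    }
    baseline <- config$baseline_amp *
      sin(2 * pi * config$baseline_freq * t)
    value <- clean + baseline + rnorm(n, 0, config$noise_sd)
    r_peaks <- pmin(pmax(as.integer(round(r_time * fs)), 0L), n - 1L)
    list(signal = tibble(sample = seq_len(n) - 1L, value = value),
         r_peaks = r_peaks, config = config)
  })
}

#' Build weak label regions around true peaks
#'
#' One half-open region `[p - half_width, p + half_width)` per true peak.
#' Where regions of adjacent peaks would overlap, both are truncated at the
#' midpoint between the peaks so that every region stays disjoint and still
#' expects exactly one peak.
#'
#' @param truth True peak positions: an integer vector, a tibble with a
#'   `sample` column, or a list with an `r_peaks` component (as returned by
#'   [gen_ecg()]).
#' @param half_width Region half-width in samples (`>= 1`).
#' @return A tibble of disjoint regions `start`, `end`, one per peak.
#' @export
gen_labels <- function(truth, half_width) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$r_peaks)) {
    truth <- truth$r_peaks
  }
  p <- peak_positions(truth)
  if (half_width < 1) abort("`half_width` must be >= 1")
  if (length(p) == 0) return(tibble(start = integer(), end = integer()))
  p <- sort(p)
  mids <- if (length(p) > 1) as.integer(ceiling((head(p, -1) + p[-1]) / 2)) else integer(0)
  start <- pmax(p - as.integer(half_width), c(0L, mids))
  end <- pmin(p + as.integer(half_width), c(mids, p[length(p)] + as.integer(half_width)))
  tibble(start = as.integer(start), end = as.integer(end))
}
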