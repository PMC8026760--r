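---
title: "Graph-constrained changepoint detection for R-peak detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-constrained changepoint detection for R-peak detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gccd)
```

## The model

An ECG recording is a quasi-periodic, non-stationary signal. `gccd` treats
R-peak detection as a *constrained changepoint* problem: the raw signal
$y_1, \dots, y_N$ is modeled as piecewise constant, with a latent mean $m_i$
and a hidden state $s_i$ at every sample, and the fitted model minimizes

$$
\sum_{i=1}^{N} (m_i - y_i)^2 \;+\; \sum_{i=1}^{N-1} \lambda_{c_i},
$$

where $c_i \in \{0, 1, \dots, |E|\}$ assigns each gap between samples either
"no change" ($c_i = 0$, zero cost, $m_{i+1} = m_i$, $s_{i+1} = s_i$) or one
of the edges of a user-supplied **constraint graph** $G = (V, E)$. An edge
$e$ from state $u$ to state $v$ carries

* a **direction** $\delta_e \in \{+1, -1\}$ (non-decreasing / non-increasing
  change),
* a **gap** $\gamma_e \ge 0$, the minimum magnitude of the mean change, and
* a **penalty** $\lambda_e \ge 0$, the cost of using the transition,

and a change over $e$ requires
$\delta_e (m_i - m_{i+1}) + \gamma_e \le 0$ (weak inequality, so a change of
exactly $\gamma_e$ is allowed) together with $(s_i, s_{i+1}) = (u, v)$.
The squared-error term is the Gaussian negative log-likelihood up to
constants; no other loss is supported. Because the model exploits the
sparsity of changes to absorb noise, no filtering or preprocessing of the
signal is performed anywhere in the package.

Graphs are restricted to a **single directed cycle** that visits every state
exactly once (so $|E| = |V|$ and every state has exactly one incoming and
one outgoing edge). One state is distinguished as the R-peak state; after
fitting, the centre of each maximal run of peak-state segments is reported
as one R-peak. A single-vertex, zero-edge graph is admitted as a documented
degenerate case; it fits one global mean and is the closed-form limit used
in the tests (mean = sample average, cost = residual sum of squares).

## Exact solver

`gccd_solve()` computes the *global* optimum with a functional-pruning
dynamic program: for every sample $i$ and state $v$ it maintains the optimal
cost $C_{v,i}(m)$ of all histories ending at $i$ in $v$ with current segment
mean $m$, as a **piecewise quadratic function of $m$**. The update is

$$
C_{v,i} = \ell_{y_i} + \min\Big( C_{v,i-1},\;
  \lambda_e + T_e\, C_{u,i-1} \Big),
$$

where $e = (u \to v)$ is the unique edge targeting $v$ and $T_e$ is the
gap-constrained minimum transform
($T_e f(m) = \min_{m' \le m - \gamma_e} f(m')$ for an up edge, mirrored for
a down edge). All three operators — adding a squared loss, pointwise
minimum, and the constrained transform — map piecewise quadratics to
piecewise quadratics, and are exposed as `pq_add_loss()`,
`pq_pointwise_min()` and `pq_min_transform()` for inspection and testing.
Backtracking from the best final state/mean reproduces the changepoints,
states and means. The per-sample piece counts are retained
(`pruning_stats()`); their median grows sublinearly with $N$ on noisy
signals, which is what makes the solver fast in practice (tens of
milliseconds for $10^4$ samples on one core).

Design choices where the formulation is open:

* **Boundary states.** Every vertex may start the recording (cost 0 at
  sample 0 in all states) and every vertex may end it. A recording window
  begins and ends at an arbitrary phase of the cardiac cycle, so pinning a
  boundary state would be wrong for real records.
* **Mean domain.** Means are restricted to
  $[\min y - \texttt{m\_margin}, \max y + \texttt{m\_margin}]$ with a
  default margin of 10% of the signal range. Optimal segment means are
  convex combinations of data values shifted by at most the traversed gaps,
  so the restriction is lossless whenever the optimum lies inside; the
  tests verify invariance of the optimum under doubling the margin.
* **Indexing and ties.** Samples are 0-based; segments are half-open
  `[start, end)`; a change recorded at position $i$ starts a new segment at
  $i + 1$. When "change" and "no change" tie exactly, "no change" wins, so
  the sparser model is returned. Ties between final states go to the first
  vertex in canonical cycle order (which starts at the peak state).
* **Numerics.** Crossings between quadratic branches are found with the
  numerically stable quadratic formula; pieces narrower than $10^{-12}$ in
  $m$ are merged, adjacent pieces with coefficients equal to within a
  $10^{-9}$ relative tolerance are fused, and tie comparisons in
  backtracking use a $10^{-9}$ relative tolerance in cost units.
* **Infeasibility.** If at some sample no state has a feasible mean (the
  gaps demand excursions outside the mean domain in every state), the
  solver aborts naming the first such sample. During graph learning that
  error is caught and the candidate is scored $\infty$.

## Peak localization and evaluation

`locate_peaks()` reports `floor((start + end - 1) / 2)` of each maximal
peak-state run (floor convention for even runs — the formulation only says
"centre"). Two evaluation modes exist deliberately:

* **Weak labels** (`count_label_errors()`): disjoint half-open regions, each
  expected to contain exactly one peak. A region with no peak is one false
  negative; a region with $k$ peaks contributes $k - 1$ false positives;
  peaks outside every region are ignored, because the regions are sparse
  supervision that covers only part of the record. This is the training
  criterion of the graph learner.
* **Full annotations** (`match_annotations()`): greedy one-to-one matching
  of predicted peaks to reference beats within a tolerance window, in
  increasing position order, distance ties going to the earlier reference
  beat. The default window is 150 ms worth of samples (54 at 360 Hz), the
  conventional beat-matching window. Unmatched predictions count as false
  positives here.

`compute_metrics()` evaluates the three standard detection metrics,
$\mathrm{Sen} = 100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
$\mathrm{PPR} = 100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ and
$\mathrm{DER} = 100\,(\mathrm{FN}+\mathrm{FP})/(\mathrm{TP}+\mathrm{FN})$,
exactly as defined; DER is not clamped and can exceed 100 when false
positives dominate. Degenerate denominators yield `NA` with a warning.

## Greedy graph learning

`greedy_learn()` searches graph space with strictly improving greedy steps.
From the current graph it enumerates **11 edit kinds per edge**: three
single-node insertions with direction patterns $(d, d)$, $(d, \neg d)$,
$(\neg d, d)$; two node deletions (source / target of the edge, merging the
neighbouring edge); one two-node insertion with pattern $(d, \neg d, d)$;
flipping the edge direction; and doubling or halving the penalty and the
gap. The candidate with the lowest training label error is accepted only if
it is *strictly* better, so the integer error sequence is strictly
decreasing and the search terminates after at most initial-error + 1
accepted iterations; ties are broken by a fixed enumeration order (edge id,
then kind order), making the result reproducible. Candidates are
deduplicated by a canonical serialization (per-edge direction/gap/penalty
sequence in cycle order from the peak state), so the candidate set of a
2-edge graph has at most 22 members.

Choices where the procedure is open:

* **Step factors 2 and 0.5** for the penalty/gap edits: geometric steps
  cover orders of magnitude quickly and are exactly invertible, so the
  search can revisit a previous value.
* **Parameter inheritance.** Inserted edges copy the gap and penalty of the
  edited edge; a deletion's merged edge keeps the edited edge's parameters.
* **Deletions on 2-vertex cycles are inapplicable** (they would leave a
  self-loop, which the single-cycle contract for multi-vertex graphs does
  not admit), as is any deletion of the peak state.
* **Model selection uses training error only**; validation folds
  (`split_folds()`, near-equal random fold sizes, seed-deterministic) are
  reported in the trace for monitoring but never steer the search. The
  default initial graph is the 2-state cycle with gap 100 and penalty
  $10^5$, a scale appropriate for raw ADC-unit recordings; both are
  overridable.

Greedy search with strict improvement can stall in local optima — this is
inherent and intentional; richer initial graphs reach equal-or-better error
in equal-or-fewer iterations, which the tests assert on seeded synthetic
data.

## Synthetic data

Real annotated recordings cannot be bundled, so two generators make every
claim testable offline; both are pure functions of their configuration and
seed.

* **`gen_graph_walk()`** inverts the model: it walks the constraint cycle,
  dwelling a uniform-random number of samples per state and moving the
  latent mean at each transition by the edge's gap plus a positive uniform
  excess (every traversed constraint holds with strict slack), then adds
  i.i.d. Gaussian noise. The tests use step/noise ratios of at least 10 and
  recover changepoint positions to within ±2 samples.
* **`gen_ecg()`** produces an ECG-like beat train: per-beat Gaussian bumps
  (P up, Q down, R up, S down, T up) at jittered RR intervals, plus a
  low-frequency baseline-wander sinusoid and Gaussian noise. Defaults
  emulate a clean adult recording at 360 Hz: RR 0.8 ± 0.05 s, R amplitude
  1.0, P/T amplitudes 0.15/0.30, noise sd 0.05, wander amplitude 0.1 at
  0.33 Hz. The true R-peak of a beat is the centre sample of its clean R
  bump, which is independent of noise and wander by construction.
* **`gen_labels()`** builds the weak supervision regions: ±`half_width`
  samples around each true peak (default 0.1 s worth), truncated at
  midpoints between close peaks so regions stay disjoint and each still
  expects exactly one peak.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: arrhythmic morphology changes (negative QRS
complexes, ectopic beats), amplitude drift, electrode artifacts, muscle
noise with heavy-tailed distributions, and multi-morphology records that
would need a multi-path graph. Results on the simulator bound what to
expect from clean recordings, not from pathological ones.

### Study sizes used by the test-suite and acceptance script

Chosen to exercise each claim at full statistical strength while staying
desk-scale: 100 random instances of $N \le 10$ samples for exactness
against an exhaustive enumeration oracle (the oracle enumerates every
changepoint subset and start state and solves each chain-constrained mean
problem in closed form over all active sets); 100 seeded 20-cycle walks
(~3,900 changepoints) for recovery; one 200-beat simulated ECG
(~58,000 samples) for end-to-end detection with a hand 2-state graph
(gap 0.5, penalty 2 — roughly half the R amplitude and a penalty a few
times the per-beat noise energy); five learning round-trips from a known
4-state cycle with highly variable dwells (5–60 samples) and step sizes
(gap 100 plus 10–80 excess, noise sd 5), conditions under which a 2-state
model cannot centre every peak and the search must edit the structure; and
50 instances for penalty monotonicity.

## Known limitations

Single-path cyclic graphs only (no branching morphologies), Gaussian loss
only, batch solving only (no streaming), and a greedy structure search that
is sensitive to its initial graph. WFDB waveform records are not read
directly; convert records and annotations to the package's CSV schema
first.
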