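# gccd — graph-constrained changepoint detection for ECG R-peak detection

`gccd` detects R-peaks in **raw** electrocardiogram signals — no filtering,
no preprocessing — by solving a penalized, graph-constrained changepoint
problem exactly. It is aimed at physiological signal processing work where
beat detection must be robust to baseline wander and unusual QRS
morphologies, and at anyone who wants an exact, auditable segmentation
model rather than a threshold heuristic.

## The model

The signal $y_1,\dots,y_N$ is modeled as piecewise constant with hidden
states. A directed **constraint graph** $G=(V,E)$ — a single cycle through
the expected states of a cardiac cycle, one of them the R-peak state —
restricts the allowed sequence of changes. The fit minimizes

$$\sum_{i=1}^{N} (m_i - y_i)^2 + \sum_{i=1}^{N-1} \lambda_{c_i}$$

over means $m$, states $s$ and change assignments $c$, subject to: no
change keeps $m$ and $s$; a change over edge $e$ pays $\lambda_e$, moves to
the edge's target state, and must satisfy
$\delta_e(m_i - m_{i+1}) + \gamma_e \le 0$ (direction $\delta_e = \pm 1$,
minimum amplitude gap $\gamma_e \ge 0$). A functional-pruning dynamic
program over piecewise quadratic cost functions (implemented in C++)
returns the *global* optimum; the centre of each R-state segment run is an
R-peak. A greedy structure learner (`greedy_learn()`) edits the graph —
11 candidate edits per edge — to minimize errors against weakly labeled
peak regions, so the graph can be learned from data instead of written by
hand. Detection quality is summarized by sensitivity, positive predictivity
and detection error rate (`compute_metrics()`).

## Worked example

Simulate a 20-beat ECG (Gaussian P/QRS/T bumps, noise, baseline wander),
fit a hand-written two-state graph, and score the detected peaks against
the simulator's ground truth:

```r
library(gccd)

sim   <- gen_ecg(ecg_sim_config(n_beats = 20, seed = 42))
graph <- ecg_graph(gap = 0.5, penalty = 2)
graph
#> <constraint_graph> 2 state(s), peak state 'R'
#>   [1] R ↓ A  gap=0.5  penalty=2
#>   [2] A ↑ R  gap=0.5  penalty=2

fit <- gccd_solve(sim$signal, graph)
glance(fit)
#> # A tibble: 1 × 6
#>       n n_segments n_changes total_cost  m_min m_max
#>   <int>      <int>     <int>      <dbl>  <dbl> <dbl>
#> 1  5806         41        40       158. -0.461  1.28

head(tidy(fit), 5)
#> # A tibble: 5 × 4
#>   start   end state   mean
#>   <int> <int> <chr>  <dbl>
#> 1     0   139 A     0.0596
#> 2   139   150 R     0.856
#> 3   150   452 A     0.143
#> 4   452   462 R     0.832
#> 5   462   730 A     0.0364

peaks <- locate_peaks(fit)
compute_metrics(match_annotations(peaks, sim$r_peaks, tolerance_samples = 54))
#> # A tibble: 1 × 6
#>      tp    fp    fn   sen   ppr   der
#>   <int> <int> <int> <dbl> <dbl> <dbl>
#> 1    20     0     0   100   100     0
```

The fit alternates baseline segments (`A`) with short elevated segments
(`R`) around each QRS complex; all 20 beats are found within the 150 ms
matching window (54 samples at 360 Hz), giving Sen = PPR = 100% and
DER = 0 on this record. `autoplot(fit)` draws the segmentation over the
raw samples; `autoplot()` on a `greedy_learn()` result draws the training
curve.

A command-line interface with `detect`, `learn`, `eval` and `simulate`
subcommands wraps the same functions; see `?run_cli` and the launcher in
`inst/cli/gccd.R`.

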