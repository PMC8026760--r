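#include <Rcpp.h>
#include "pq.h"

using namespace Rcpp;
using gccd::PQ;
using gccd::Piece;
using gccd::kInf;

// Functional-pruning dynamic program for penalized, graph-constrained
// piecewise-constant segmentation under Gaussian (squared-error) loss.
//
// State: for each sample i and vertex v, C[i][v](m) is the optimal cost of
// all histories ending at sample i in state v with current segment mean m.
// Update:
//   C[i][v] = loss(y_i) + min( C[i-1][v],
//                              lambda_e + T_e(C[i-1][source(e)]) )
// where e is the unique edge targeting v (single circular path) and T_e is
// the gap-constrained min-transform in the edge's direction.
//
// Every vertex may start (C[0][v] = loss(y_0)) and every vertex may end.
//
// [[Rcpp::export]]
List gccd_solve_cpp(NumericVector y,
                    IntegerVector edge_source,  // 0-based vertex index
                    IntegerVector edge_target,
                    IntegerVector edge_dir,     // +1 non-decreasing, -1 non-increasing
                    NumericVector edge_gap,
                    NumericVector edge_penalty,
                    IntegerVector edge_id,
                    int n_vertices,
                    double m0, double m1) {
  const int N = y.size();
  const int V = n_vertices;
  const int E = edge_source.size();
  if (N < 1) stop("signal must contain at least one sample");
  if (V < 1) stop("graph must contain at least one vertex");
  if (!(m1 > m0)) stop("mean domain is empty");

  // unique incoming edge per vertex (or -1: no incoming edge)
  std::vector<int> in_edge(V, -1);
  for (int e = 0; e < E; ++e) {
    int t = edge_target[e];
    if (t < 0 || t >= V || edge_source[e] < 0 || edge_source[e] >= V)
      stop("edge endpoint out of range");
    if (in_edge[t] != -1) stop("vertex %d has two incoming edges", t + 1);
    in_edge[t] = e;
  }

  std::vector<std::vector<PQ> > C(N, std::vector<PQ>(V));
  IntegerMatrix piece_counts(N, V);

  for (int v = 0; v < V; ++v) {
    C[0][v] = gccd::pq_zero(m0, m1);
    gccd::pq_add_loss(C[0][v], y[0]);
    piece_counts(0, v) = C[0][v].size();
  }

  for (int i = 1; i < N; ++i) {
    bool any = false;
    for (int v = 0; v < V; ++v) {
      PQ best;
      int e = in_edge[v];
      if (e >= 0 && !C[i - 1][edge_source[e]].empty()) {
        PQ D = gccd::pq_min_transform(C[i - 1][edge_source[e]], edge_dir[e],
                                      edge_gap[e], m0, m1);
        gccd::pq_add_const(D, edge_penalty[e]);
        best = gccd::pq_pointwise_min(C[i - 1][v], D, m0, m1);
      } else {
        best = C[i - 1][v];
      }
      if (!best.empty()) {
        gccd::pq_add_loss(best, y[i]);
        any = true;
      }
      C[i][v] = best;
      piece_counts(i, v) = best.size();
    }
    if (!any)
      stop("infeasible constraint graph: no state is reachable at sample %d",
           i);  // 0-based sample index
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // final minimum over vertices and means (ties: first vertex)
  double best_val = kInf, best_m = 0.0;
  int best_v = -1;
  for (int v = 0; v < V; ++v) {
    double val, arg;
    gccd::pq_min_on(C[N - 1][v], m0, m1, &val, &arg);
    if (val < best_val) {
      best_val = val;
      best_m = arg;
      best_v = v;
    }
  }
  if (best_v < 0) stop("infeasible constraint graph: no feasible segmentation");

  // backtrack: ties prefer the no-change branch (sparser model)
  std::vector<int> seg_start, seg_state;
  std::vector<double> seg_mean;
  std::vector<int> chg_pos, chg_edge;
  int v = best_v;
  double m = best_m;
  for (int i = N - 1; i >= 1; --i) {
    double stay = gccd::pq_eval(C[i - 1][v], m);
    double change_val = kInf, change_arg = 0.0;
    int e = in_edge[v];
    if (e >= 0 && !C[i - 1][edge_source[e]].empty()) {
      double lo = m0, hi = m1;
      if (edge_dir[e] > 0) hi = m - edge_gap[e];  // previous mean <= m - gap
      else lo = m + edge_gap[e];                  // previous mean >= m + gap
      if (hi >= lo) {
        gccd::pq_min_on(C[i - 1][edge_source[e]], lo, hi, &change_val,
                        &change_arg);
        change_val += edge_penalty[e];
      }
    }
    double tol = 1e-9 * (1.0 + std::fabs(stay) + std::fabs(change_val));
    if (stay <= change_val + tol) continue;  // no change at this step
    if (!std::isfinite(change_val))
      stop("internal error: backtracking found no feasible branch at sample %d", i);
    seg_start.push_back(i);
    seg_state.push_back(v);
    seg_mean.push_back(m);
    chg_pos.push_back(i - 1);
    chg_edge.push_back(edge_id[e]);
    v = edge_source[e];
    m = change_arg;
  }
  seg_start.push_back(0);
  seg_state.push_back(v);
  seg_mean.push_back(m);

  const int K = seg_start.size();
  IntegerVector starts(K), ends(K), states(K);
  NumericVector means(K);
  for (int k = 0; k < K; ++k) {
    int src = K - 1 - k;  // reverse into forward order
    starts[k] = seg_start[src];
    ends[k] = (src == 0) ? N : seg_start[src - 1];
    states[k] = seg_state[src];
    means[k] = seg_mean[src];
  }
  std::reverse(chg_pos.begin(), chg_pos.end());
  std::reverse(chg_edge.begin(), chg_edge.end());

  return List::create(
      _["start"] = starts, _["end"] = ends, _["state"] = states,
      _["mean"] = means, _["change_pos"] = wrap(chg_pos),
      _["change_edge"] = wrap(chg_edge), _["total_cost"] = best_val,
      _["piece_counts"] = piece_counts);
}
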