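#pragma once

#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
#include <string>
#include <stdexcept>

namespace gccd {

const double kInf = std::numeric_limits<double>::infinity();
const double kWidthTol = 1e-12;  // pieces narrower than this (in m) are merged away
const double kCoefTol = 1e-9;    // adjacent pieces with coefficients this close are fused

// One quadratic piece a*m^2 + b*m + c on the half-open interval [lo, hi).
struct Piece {
  double lo, hi;
  double a, b, c;
  double at(double m) const { return (a * m + b) * m + c; }
};

// Piecewise quadratic function of the segment mean m: ordered, disjoint pieces.
// Intervals of the domain not covered by any piece carry the value +inf
// (infeasible mean values).
typedef std::vector<Piece> PQ;

double pq_eval(const PQ &f, double m);
PQ pq_zero(double m0, double m1);
void pq_add_loss(PQ &f, double y);           // f(m) += (m - y)^2
void pq_add_const(PQ &f, double v);          // f(m) += v
PQ pq_pointwise_min(const PQ &f, const PQ &g, double m0, double m1);
// dir = +1: out(m) = min_{m' <= m - gap} f(m')   (non-decreasing change)
// dir = -1: out(m) = min_{m' >= m + gap} f(m')   (non-increasing change)
PQ pq_min_transform(const PQ &f, int dir, double gap, double m0, double m1);
// Minimum and leftmost argmin of f over the closed interval [lo, hi].
void pq_min_on(const PQ &f, double lo, double hi, double *val, double *arg);
void pq_simplify(PQ &f);

}  // namespace gccd
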