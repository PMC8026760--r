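#include <Rcpp.h>
#include "pq.h"

using namespace Rcpp;
using gccd::PQ;
using gccd::Piece;

static PQ mat_to_pq(const NumericMatrix &m) {
  PQ f;
  for (int i = 0; i < m.nrow(); ++i) {
    Piece p;
    p.lo = m(i, 0); p.hi = m(i, 1);
    p.a = m(i, 2); p.b = m(i, 3); p.c = m(i, 4);
    if (!(p.hi > p.lo)) stop("piece %d has non-positive width", i + 1);
    if (p.a < -1e-12) stop("piece %d has negative quadratic coefficient", i + 1);
    if (!f.empty() && p.lo < f.back().hi - gccd::kWidthTol)
      stop("pieces must be ordered and non-overlapping");
    f.push_back(p);
  }
  return f;
}

static NumericMatrix pq_to_mat(const PQ &f) {
  NumericMatrix m(f.size(), 5);
  colnames(m) = CharacterVector::create("lo", "hi", "a", "b", "c");
  for (size_t i = 0; i < f.size(); ++i) {
    m(i, 0) = f[i].lo; m(i, 1) = f[i].hi;
    m(i, 2) = f[i].a; m(i, 3) = f[i].b; m(i, 4) = f[i].c;
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix pq_add_loss_cpp(NumericMatrix f, double y) {
  PQ g = mat_to_pq(f);
  gccd::pq_add_loss(g, y);
  return pq_to_mat(g);
}

// [[Rcpp::export]]
NumericMatrix pq_pointwise_min_cpp(NumericMatrix f, NumericMatrix g,
                                   double m0, double m1) {
  PQ a = mat_to_pq(f), b = mat_to_pq(g);
  return pq_to_mat(gccd::pq_pointwise_min(a, b, m0, m1));
}

// [[Rcpp::export]]
NumericMatrix pq_min_transform_cpp(NumericMatrix f, int dir, double gap,
                                   double m0, double m1) {
  PQ a = mat_to_pq(f);
  return pq_to_mat(gccd::pq_min_transform(a, dir, gap, m0, m1));
}

// [[Rcpp::export]]
NumericVector pq_eval_cpp(NumericMatrix f, NumericVector m) {
  PQ a = mat_to_pq(f);
  NumericVector out(m.size());
  for (int i = 0; i < m.size(); ++i) out[i] = gccd::pq_eval(a, m[i]);
  return out;
}

// [[Rcpp::export]]
List pq_min_on_cpp(NumericMatrix f, double lo, double hi) {
  PQ a = mat_to_pq(f);
  double val, arg;
  gccd::pq_min_on(a, lo, hi, &val, &arg);
  return List::create(_["value"] = val, _["argmin"] = arg);
}
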