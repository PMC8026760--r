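#include "pq.h"

namespace gccd {

double pq_eval(const PQ &f, double m) {
  for (size_t i = 0; i < f.size(); ++i) {
    const Piece &p = f[i];
    if (m >= p.lo - kWidthTol && m < p.hi) return p.at(m);
    // the function is evaluable at the top end of a piece whose upper
    // boundary is not shared with a following piece (e.g. the domain max)
    if (m >= p.lo - kWidthTol && m <= p.hi + kWidthTol) {
      bool shared = (i + 1 < f.size()) && (f[i + 1].lo <= p.hi + kWidthTol);
      if (!shared) return p.at(m);
    }
  }
  return kInf;
}

PQ pq_zero(double m0, double m1) {
  PQ f;
  Piece p;
  p.lo = m0; p.hi = m1; p.a = 0.0; p.b = 0.0; p.c = 0.0;
  f.push_back(p);
  return f;
}

void pq_add_loss(PQ &f, double y) {
  for (size_t i = 0; i < f.size(); ++i) {
    f[i].a += 1.0;
    f[i].b += -2.0 * y;
    f[i].c += y * y;
  }
}

void pq_add_const(PQ &f, double v) {
  for (size_t i = 0; i < f.size(); ++i) f[i].c += v;
}

static bool coef_close(double x, double y) {
  return std::fabs(x - y) <= kCoefTol * (1.0 + std::fabs(x) + std::fabs(y));
}

void pq_simplify(PQ &f) {
  PQ out;
  for (size_t i = 0; i < f.size(); ++i) {
    Piece p = f[i];
    if (p.hi - p.lo < kWidthTol) {
      // degenerate sliver: extend the previous piece over it if contiguous
      if (!out.empty() && out.back().hi >= p.lo - kWidthTol) out.back().hi = p.hi;
      continue;
    }
    if (!out.empty()) {
      Piece &q = out.back();
      if (q.hi >= p.lo - kWidthTol && coef_close(q.a, p.a) &&
          coef_close(q.b, p.b) && coef_close(q.c, p.c)) {
        q.hi = p.hi;
        continue;
      }
    }
    out.push_back(p);
  }
  f.swap(out);
}

// Real roots of a*x^2 + b*x + c strictly inside (lo, hi), ascending.
static void quad_roots(double a, double b, double c, double lo, double hi,
                       std::vector<double> *roots) {
  const double eps = 1e-300;
  double r1 = kInf, r2 = kInf;
  if (std::fabs(a) < 1e-14 * (std::fabs(b) + std::fabs(c) + 1.0)) {
    if (std::fabs(b) < eps) return;
    r1 = -c / b;
  } else {
    double disc = b * b - 4.0 * a * c;
    if (disc <= 0.0) return;  // tangency: no sign change
    double sd = std::sqrt(disc);
    double q = -0.5 * (b + (b >= 0.0 ? sd : -sd));
    r1 = q / a;
    r2 = (std::fabs(q) > eps) ? c / q : -b / a - r1;
    if (r1 > r2) std::swap(r1, r2);
  }
  if (r1 > lo && r1 < hi) roots->push_back(r1);
  if (r2 > lo && r2 < hi && std::fabs(r2 - r1) > kWidthTol) roots->push_back(r2);
}

static const Piece *covering(const PQ &f, double mid) {
  for (size_t i = 0; i < f.size(); ++i)
    if (mid >= f[i].lo && mid < f[i].hi) return &f[i];
  return NULL;
}

PQ pq_pointwise_min(const PQ &f, const PQ &g, double m0, double m1) {
  std::vector<double> bp;
  bp.push_back(m0);
  bp.push_back(m1);
  for (size_t i = 0; i < f.size(); ++i) { bp.push_back(f[i].lo); bp.push_back(f[i].hi); }
  for (size_t i = 0; i < g.size(); ++i) { bp.push_back(g[i].lo); bp.push_back(g[i].hi); }
  for (size_t i = 0; i < bp.size(); ++i) bp[i] = std::min(std::max(bp[i], m0), m1);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  PQ out;
  for (size_t i = 0; i + 1 < bp.size(); ++i) {
    double x0 = bp[i], x1 = bp[i + 1];
    if (x1 - x0 < kWidthTol) continue;
    double mid = 0.5 * (x0 + x1);
    const Piece *pf = covering(f, mid);
    const Piece *pg = covering(g, mid);
    if (!pf && !pg) continue;
    if (!pf || !pg) {
      const Piece *p = pf ? pf : pg;
      Piece q; q.lo = x0; q.hi = x1; q.a = p->a; q.b = p->b; q.c = p->c;
      out.push_back(q);
      continue;
    }
    double da = pf->a - pg->a, db = pf->b - pg->b, dc = pf->c - pg->c;
    std::vector<double> cuts;
    cuts.push_back(x0);
    quad_roots(da, db, dc, x0, x1, &cuts);
    cuts.push_back(x1);
    std::sort(cuts.begin(), cuts.end());
    for (size_t j = 0; j + 1 < cuts.size(); ++j) {
      double u0 = cuts[j], u1 = cuts[j + 1];
      if (u1 - u0 < kWidthTol) continue;
      double um = 0.5 * (u0 + u1);
      double d = (da * um + db) * um + dc;
      const Piece *p = (d <= 0.0) ? pf : pg;  // ties keep f (the no-change branch)
      Piece q; q.lo = u0; q.hi = u1; q.a = p->a; q.b = p->b; q.c = p->c;
      out.push_back(q);
    }
  }
  pq_simplify(out);
  return out;
}

// End of the decreasing run of a piece, scanning left-to-right.
static double decreasing_end(const Piece &p) {
  if (p.a > 0.0) {
    double v = -p.b / (2.0 * p.a);
    return std::min(std::max(v, p.lo), p.hi);
  }
  if (p.a == 0.0 && p.b < 0.0) return p.hi;
  return p.lo;  // non-decreasing throughout (includes constants)
}

static void emit(PQ *out, double lo, double hi, double a, double b, double c) {
  if (hi - lo < kWidthTol) return;
  Piece q; q.lo = lo; q.hi = hi; q.a = a; q.b = b; q.c = c;
  out->push_back(q);
}

// R(x) = min_{m' in [m0, x]} f(m'), monotone non-increasing.
static PQ running_min_left(const PQ &f, double m0, double m1) {
  PQ out;
  double mu = kInf;
  double cursor = m0;
  for (size_t i = 0; i < f.size(); ++i) {
    const Piece &p = f[i];
    if (p.lo > cursor && mu < kInf) emit(&out, cursor, p.lo, 0.0, 0.0, mu);
    double t = decreasing_end(p);
    if (t > p.lo) {  // decreasing on [lo, t): R = min(mu, q(x)) there
      double qlo = p.at(p.lo), qt = p.at(t);
      if (qlo <= mu) {
        emit(&out, p.lo, t, p.a, p.b, p.c);
      } else if (qt >= mu) {
        emit(&out, p.lo, t, 0.0, 0.0, mu);
      } else {
        std::vector<double> r;
        quad_roots(p.a, p.b, p.c - mu, p.lo, t, &r);
        double cut = r.empty() ? p.lo : r.front();
        emit(&out, p.lo, cut, 0.0, 0.0, mu);
        emit(&out, cut, t, p.a, p.b, p.c);
      }
      mu = std::min(mu, qt);
    } else {
      mu = std::min(mu, p.at(p.lo));
    }
    if (p.hi > t) emit(&out, t, p.hi, 0.0, 0.0, mu);
    cursor = p.hi;
  }
  if (mu < kInf && cursor < m1) emit(&out, cursor, m1, 0.0, 0.0, mu);
  pq_simplify(out);
  return out;
}

// Start of the increasing run of a piece, scanning right-to-left.
static double increasing_start(const Piece &p) {
  if (p.a > 0.0) {
    double v = -p.b / (2.0 * p.a);
    return std::min(std::max(v, p.lo), p.hi);
  }
  if (p.a == 0.0 && p.b > 0.0) return p.lo;
  return p.hi;  // non-increasing throughout
}

// R(x) = min_{m' in [x, m1]} f(m'), monotone non-decreasing.
static PQ running_min_right(const PQ &f, double m0, double m1) {
  PQ rev;  // collected right-to-left
  double mu = kInf;
  double cursor = m1;
  for (size_t k = f.size(); k-- > 0;) {
    const Piece &p = f[k];
    if (p.hi < cursor && mu < kInf) emit(&rev, p.hi, cursor, 0.0, 0.0, mu);
    double t = increasing_start(p);
    if (p.hi > t) {  // increasing on [t, hi): R = min(mu, q(x)) there
      double qhi = p.at(p.hi), qt = p.at(t);
      if (qhi <= mu) {
        emit(&rev, t, p.hi, p.a, p.b, p.c);
      } else if (qt >= mu) {
        emit(&rev, t, p.hi, 0.0, 0.0, mu);
      } else {
        std::vector<double> r;
        quad_roots(p.a, p.b, p.c - mu, t, p.hi, &r);
        double cut = r.empty() ? p.hi : r.back();
        emit(&rev, t, cut, p.a, p.b, p.c);
        emit(&rev, cut, p.hi, 0.0, 0.0, mu);
      }
      mu = std::min(mu, qt);
    } else {
      mu = std::min(mu, p.at(p.hi));
    }
    if (t > p.lo) emit(&rev, p.lo, t, 0.0, 0.0, mu);
    cursor = p.lo;
  }
  if (mu < kInf && cursor > m0) emit(&rev, m0, cursor, 0.0, 0.0, mu);
  std::sort(rev.begin(), rev.end(),
            [](const Piece &x, const Piece &y) { return x.lo < y.lo; });
  pq_simplify(rev);
  return rev;
}

PQ pq_min_transform(const PQ &f, int dir, double gap, double m0, double m1) {
  PQ out;
  if (dir > 0) {
    // out(m) = R_left(m - gap): shift right by gap, infeasible below m0 + gap
    PQ R = running_min_left(f, m0, m1);
    for (size_t i = 0; i < R.size(); ++i) {
      Piece p = R[i];
      double lo = p.lo + gap, hi = p.hi + gap;
      // q(m - gap) in terms of m
      double a = p.a, b = p.b - 2.0 * p.a * gap;
      double c = p.a * gap * gap - p.b * gap + p.c;
      lo = std::max(lo, m0);
      hi = std::min(hi, m1);
      emit(&out, lo, hi, a, b, c);
    }
  } else {
    // out(m) = R_right(m + gap): shift left by gap, infeasible above m1 - gap
    PQ R = running_min_right(f, m0, m1);
    for (size_t i = 0; i < R.size(); ++i) {
      Piece p = R[i];
      double lo = p.lo - gap, hi = p.hi - gap;
      double a = p.a, b = p.b + 2.0 * p.a * gap;
      double c = p.a * gap * gap + p.b * gap + p.c;
      lo = std::max(lo, m0);
      hi = std::min(hi, m1);
      emit(&out, lo, hi, a, b, c);
    }
  }
  pq_simplify(out);
  return out;
}

void pq_min_on(const PQ &f, double lo, double hi, double *val, double *arg) {
  *val = kInf;
  *arg = std::numeric_limits<double>::quiet_NaN();
  for (size_t i = 0; i < f.size(); ++i) {
    const Piece &p = f[i];
    double u0 = std::max(p.lo, lo), u1 = std::min(p.hi, hi);
    if (u1 < u0) continue;
    double cand_x[3];
    int nc = 0;
    cand_x[nc++] = u0;
    cand_x[nc++] = u1;
    if (p.a > 0.0) {
      double v = -p.b / (2.0 * p.a);
      if (v > u0 && v < u1) cand_x[nc++] = v;
    }
    for (int j = 0; j < nc; ++j) {
      double x = cand_x[j], fx = p.at(x);
      if (fx < *val - 1e-15 * (1.0 + std::fabs(fx))) {
        *val = fx;
        *arg = x;
      }
    }
  }
}

}  // namespace gccd
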