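// Exhaustive correlation search over ordered band tuples for the two-
// and three-band spectral-index formulas. Samples hitting a zero
// denominator (|den| < 1e-12) are masked out of that tuple's
// correlation; tuples with more than maxMaskFrac masked samples, or a
// degenerate index/response variance, are skipped; ties in |r| keep the
// lexicographically smallest (i, j, k) tuple. The three-band loops are
// specialized per formula so the per-sample division happens once per
// denominator pair, not once per tuple.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-12;

// ids: 1 DI, 2 OSI, 3 SASI, 4..10 TBI1..TBI7 (9 = TBI6 default reading),
// 11 = TBI6 literal transcription.
static inline double evalFormula(int f, double r1, double r2, double r3,
                                 bool &masked) {
  double den;
  switch (f) {
  case 1:
    return r1 - r2;
  case 2:
    den = r1 + 0.45;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return 1.45 * (2.0 * r2 + 1.0) / den;
  case 3:
    den = r1 + r2 + 0.5;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return 1.5 * (r1 - r2) / den;
  case 4:
    den = r2 * r3;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return r1 / den;
  case 5:
    den = r2 + r3;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return r1 / den;
  case 6:
    den = r1 + r3;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return (r1 - r2) / den;
  case 7:
    den = r1 - r3;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return (r1 - r2) / den;
  case 8:
    den = r3;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return (r1 + r2) / den;
  case 9:
    den = (r1 - r2) - (r1 - r3);
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return (r1 - r2) / den;
  case 10:
    return (r1 - r2) - (r1 - r3);
  case 11:
    den = r1 - r2;
    if (std::fabs(den) < EPS) { masked = true; return 0.0; }
    return (r1 - r2) / den - (r1 - r3);
  }
  masked = true;
  return 0.0;
}

// Pearson r of the formula values at one band tuple against y over
// unmasked samples; NA_REAL when the tuple is skipped.
static inline double tupleR(int f, const double *c1, const double *c2,
                            const double *c3, const double *y, int n,
                            int maxMasked) {
  int masked = 0, m = 0;
  double sv = 0, svv = 0, sy = 0, syy = 0, svy = 0;
  for (int s = 0; s < n; ++s) {
    bool bad = false;
    double v = evalFormula(f, c1[s], c2[s], c3 ? c3[s] : 0.0, bad);
    if (bad) {
      if (++masked > maxMasked) return NA_REAL;
      continue;
    }
    ++m;
    sv += v; svv += v * v;
    sy += y[s]; syy += y[s] * y[s];
    svy += v * y[s];
  }
  if (m < 3) return NA_REAL;
  double vv = m * svv - sv * sv;
  double vy = m * syy - sy * sy;
  if (vv < EPS || vy < EPS) return NA_REAL;
  return (m * svy - sv * sy) / std::sqrt(vv * vy);
}

struct Best {
  double absR = -1.0, r = NA_REAL;
  int i = -1, j = -1, k = -1;
  inline void consider(double rr, int ii, int jj, int kk) {
    double a = std::fabs(rr);
    if (a > absR ||
        (a == absR &&
         (ii < i || (ii == i && (jj < j || (jj == j && kk < k)))))) {
      absR = a; r = rr; i = ii; j = jj; k = kk;
    }
  }
};

// Build 1/den per sample for a denominator shared by many tuples;
// masked samples get recip = 0 so they contribute nothing to the
// accumulated sums. Returns false when the tuple family is skipped.
// mode: 0 den=d1*d2, 1 den=d1+d2, 2 den=d1-d2, 3 den=d1.
static inline bool buildRecip(const double *d1, const double *d2, int mode,
                              const double *y, int n, int maxMasked,
                              double *recip, int &m, double &sy,
                              double &syy) {
  int masked = 0;
  m = 0; sy = 0; syy = 0;
  for (int s = 0; s < n; ++s) {
    double den = mode == 0 ? d1[s] * d2[s]
               : mode == 1 ? d1[s] + d2[s]
               : mode == 2 ? d1[s] - d2[s]
                           : d1[s];
    if (std::fabs(den) < EPS) {
      recip[s] = 0.0;
      if (++masked > maxMasked) return false;
    } else {
      recip[s] = 1.0 / den;
      ++m;
      sy += y[s]; syy += y[s] * y[s];
    }
  }
  return m >= 3;
}

// r of v_s = num_s * recip_s against y; num op: 0 v=a, 1 v=a-b, 2 v=a+b.
static inline double accumR(const double *a, const double *b, int op,
                            const double *recip, const double *y, int n,
                            int m, double sy, double syy) {
  double sv = 0, svv = 0, svy = 0;
  for (int s = 0; s < n; ++s) {
    double num = op == 0 ? a[s] : op == 1 ? a[s] - b[s] : a[s] + b[s];
    double v = num * recip[s];
    sv += v; svv += v * v; svy += v * y[s];
  }
  double vv = m * svv - sv * sv;
  double vy = m * syy - sy * sy;
  if (vv < EPS || vy < EPS) return NA_REAL;
  return (m * svy - sv * sy) / std::sqrt(vv * vy);
}

// [[Rcpp::export(name = ".cppSearch2")]]
List cppSearch2(NumericMatrix X, NumericVector y, int formulaId,
                double maxMaskFrac) {
  int n = X.nrow(), B = X.ncol();
  int maxMasked = (int)std::floor(maxMaskFrac * n);
  Best best;
  long long skipped = 0, total = (long long)B * B;
  for (int i = 0; i < B; ++i) {
    const double *c1 = &X(0, i);
    for (int j = 0; j < B; ++j) {
      double r = tupleR(formulaId, c1, &X(0, j), NULL, y.begin(), n,
                        maxMasked);
      if (ISNA(r)) { ++skipped; continue; }
      best.consider(r, i, j, 0);
    }
  }
  return List::create(_["i"] = best.i + 1, _["j"] = best.j + 1,
                      _["r"] = best.r, _["nSkipped"] = (double)skipped,
                      _["nTuples"] = (double)total);
}

// [[Rcpp::export(name = ".cppSearch3")]]
List cppSearch3(NumericMatrix X, NumericVector y, int formulaId,
                double maxMaskFrac) {
  int n = X.nrow(), B = X.ncol();
  int maxMasked = (int)std::floor(maxMaskFrac * n);
  const double *yp = y.begin();
  Best best;
  long long skipped = 0, total = (long long)B * B * B;
  std::vector<double> recip(n);
  int m; double sy, syy;

  if (formulaId == 4 || formulaId == 5) {
    // TBI1 r1/(r2*r3), TBI2 r1/(r2+r3): denominator pair (j, k)
    int mode = formulaId == 4 ? 0 : 1;
    for (int j = 0; j < B; ++j) {
      for (int k = 0; k < B; ++k) {
        if (!buildRecip(&X(0, j), &X(0, k), mode, yp, n, maxMasked,
                        recip.data(), m, sy, syy)) {
          skipped += B;
          continue;
        }
        for (int i = 0; i < B; ++i) {
          double r = accumR(&X(0, i), NULL, 0, recip.data(), yp, n, m,
                            sy, syy);
          if (ISNA(r)) { ++skipped; continue; }
          best.consider(r, i, j, k);
        }
      }
      checkUserInterrupt();
    }
  } else if (formulaId == 6 || formulaId == 7) {
    // TBI3 (r1-r2)/(r1+r3), TBI4 (r1-r2)/(r1-r3): denominator (i, k)
    int mode = formulaId == 6 ? 1 : 2;
    for (int i = 0; i < B; ++i) {
      const double *c1 = &X(0, i);
      for (int k = 0; k < B; ++k) {
        if (!buildRecip(c1, &X(0, k), mode, yp, n, maxMasked,
                        recip.data(), m, sy, syy)) {
          skipped += B;
          continue;
        }
        for (int j = 0; j < B; ++j) {
          double r = accumR(c1, &X(0, j), 1, recip.data(), yp, n, m,
                            sy, syy);
          if (ISNA(r)) { ++skipped; continue; }
          best.consider(r, i, j, k);
        }
      }
      checkUserInterrupt();
    }
  } else if (formulaId == 8) {
    // TBI5 (r1+r2)/r3: denominator is band k alone
    for (int k = 0; k < B; ++k) {
      if (!buildRecip(&X(0, k), NULL, 3, yp, n, maxMasked, recip.data(),
                      m, sy, syy)) {
        skipped += (long long)B * B;
        continue;
      }
      for (int i = 0; i < B; ++i) {
        const double *c1 = &X(0, i);
        for (int j = 0; j < B; ++j) {
          double r = accumR(c1, &X(0, j), 2, recip.data(), yp, n, m,
                            sy, syy);
          if (ISNA(r)) { ++skipped; continue; }
          best.consider(r, i, j, k);
        }
      }
      checkUserInterrupt();
    }
  } else if (formulaId == 9) {
    // TBI6 default reading (r1-r2)/((r1-r2)-(r1-r3)) = (r1-r2)/(r3-r2):
    // denominator pair (k, j)
    for (int j = 0; j < B; ++j) {
      const double *c2 = &X(0, j);
      for (int k = 0; k < B; ++k) {
        if (!buildRecip(&X(0, k), c2, 2, yp, n, maxMasked, recip.data(),
                        m, sy, syy)) {
          skipped += B;
          continue;
        }
        for (int i = 0; i < B; ++i) {
          double r = accumR(&X(0, i), c2, 1, recip.data(), yp, n, m,
                            sy, syy);
          if (ISNA(r)) { ++skipped; continue; }
          best.consider(r, i, j, k);
        }
      }
      checkUserInterrupt();
    }
  } else if (formulaId == 10) {
    // TBI7 (r1-r2)-(r1-r3) = r3-r2: independent of band i, so each
    // (j, k) yields one correlation shared by all B i-tuples; the
    // lexicographic rule selects the first grid band as i.
    for (int j = 0; j < B; ++j) {
      const double *c2 = &X(0, j);
      for (int k = 0; k < B; ++k) {
        double r = tupleR(1, &X(0, k), c2, NULL, yp, n, maxMasked);
        if (ISNA(r)) { skipped += B; continue; }
        best.consider(r, 0, j, k);
      }
    }
  } else {
    // generic fallback (TBI6 literal transcription, id 11)
    for (int i = 0; i < B; ++i) {
      const double *c1 = &X(0, i);
      for (int j = 0; j < B; ++j) {
        const double *c2 = &X(0, j);
        for (int k = 0; k < B; ++k) {
          double r = tupleR(formulaId, c1, c2, &X(0, k), yp, n,
                            maxMasked);
          if (ISNA(r)) { ++skipped; continue; }
          best.consider(r, i, j, k);
        }
      }
      checkUserInterrupt();
    }
  }
  return List::create(_["i"] = best.i + 1, _["j"] = best.j + 1,
                      _["k"] = best.k + 1, _["r"] = best.r,
                      _["nSkipped"] = (double)skipped,
                      _["nTuples"] = (double)total);
}

// Full 2-band correlation surface (NA where skipped).
// [[Rcpp::export(name = ".cppSurface2")]]
NumericMatrix cppSurface2(NumericMatrix X, NumericVector y, int formulaId,
                          double maxMaskFrac) {
  int n = X.nrow(), B = X.ncol();
  int maxMasked = (int)std::floor(maxMaskFrac * n);
  NumericMatrix out(B, B);
  for (int i = 0; i < B; ++i) {
    const double *c1 = &X(0, i);
    for (int j = 0; j < B; ++j) {
      out(i, j) = tupleR(formulaId, c1, &X(0, j), NULL, y.begin(), n,
                         maxMasked);
    }
  }
  return out;
}
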