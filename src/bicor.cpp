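#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Median of a vector (contents are reordered in place).
static double med_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double m2 = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + m2);
  }
  return m;
}

struct RowPrep {
  bool has_na;
  bool pearson;               // MAD == 0 on the observed entries
  std::vector<double> t;      // transformed (biweight or mean-centered) values
  double norm;                // sqrt(sum(t^2))
};

// Biweight transform of a complete vector x:
//   u_i = (x_i - med) / (9 * MAD),  w_i = (1 - u_i^2)^2 * 1[|u_i| < 1],
//   t_i = (x_i - med) * w_i.
// MAD is the unscaled median absolute deviation. If MAD == 0 the caller
// falls back to plain mean-centering (Pearson).
static void transform_vec(const std::vector<double> &x, std::vector<double> &t,
                          bool &pearson, double &norm) {
  const size_t n = x.size();
  std::vector<double> tmp(x);
  const double med = med_inplace(tmp);
  for (size_t i = 0; i < n; ++i) tmp[i] = std::fabs(x[i] - med);
  const double mad = med_inplace(tmp);
  t.resize(n);
  norm = 0.0;
  if (mad == 0.0) {
    pearson = true;
    double mean = 0.0;
    for (size_t i = 0; i < n; ++i) mean += x[i];
    mean /= (double)n;
    for (size_t i = 0; i < n; ++i) { t[i] = x[i] - mean; norm += t[i] * t[i]; }
  } else {
    pearson = false;
    const double denom = 9.0 * mad;
    for (size_t i = 0; i < n; ++i) {
      const double u = (x[i] - med) / denom;
      double w = 0.0;
      if (std::fabs(u) < 1.0) { const double a = 1.0 - u * u; w = a * a; }
      t[i] = (x[i] - med) * w;
      norm += t[i] * t[i];
    }
  }
  norm = std::sqrt(norm);
}

static void mean_center(const std::vector<double> &x, std::vector<double> &t,
                        double &norm) {
  const size_t n = x.size();
  double mean = 0.0;
  for (size_t i = 0; i < n; ++i) mean += x[i];
  mean /= (double)n;
  t.resize(n);
  norm = 0.0;
  for (size_t i = 0; i < n; ++i) { t[i] = x[i] - mean; norm += t[i] * t[i]; }
  norm = std::sqrt(norm);
}

static RowPrep prep_row(const NumericMatrix &M, int row) {
  RowPrep p;
  const int nc = M.ncol();
  p.has_na = false;
  for (int j = 0; j < nc; ++j)
    if (NumericMatrix::is_na(M(row, j))) { p.has_na = true; break; }
  if (!p.has_na) {
    std::vector<double> x(nc);
    for (int j = 0; j < nc; ++j) x[j] = M(row, j);
    transform_vec(x, p.t, p.pearson, p.norm);
  } else {
    p.pearson = false;
    p.norm = 0.0;
  }
  return p;
}

// Correlation for one pair, restricted to pairwise-complete positions.
// Returns NA_REAL if fewer than 4 complete observations (recorded by caller)
// or if either restricted vector has zero norm.
static double pair_cor(const NumericMatrix &X, int i, const NumericMatrix &Y,
                       int j, bool &deficient) {
  const int nc = X.ncol();
  std::vector<double> x, y;
  x.reserve(nc); y.reserve(nc);
  for (int k = 0; k < nc; ++k) {
    const double a = X(i, k), b = Y(j, k);
    if (!NumericMatrix::is_na(a) && !NumericMatrix::is_na(b)) {
      x.push_back(a); y.push_back(b);
    }
  }
  deficient = ((int)x.size() < 4);
  if (deficient) return NA_REAL;
  std::vector<double> tx, ty;
  bool px, py;
  double nx, ny;
  transform_vec(x, tx, px, nx);
  transform_vec(y, ty, py, ny);
  if (px || py) {  // either side constant in robust scale -> Pearson for the pair
    mean_center(x, tx, nx);
    mean_center(y, ty, ny);
  }
  if (nx == 0.0 || ny == 0.0) return NA_REAL;
  double s = 0.0;
  for (size_t k = 0; k < x.size(); ++k) s += tx[k] * ty[k];
  return s / (nx * ny);
}

static double complete_pair(const RowPrep &a, const RowPrep &b,
                            const std::vector<double> &rawa,
                            const std::vector<double> &rawb) {
  // If either row is a Pearson-fallback row, the whole pair uses Pearson.
  const std::vector<double> *ta = &a.t, *tb = &b.t;
  double na = a.norm, nb = b.norm;
  std::vector<double> ca, cb;
  if (a.pearson != b.pearson) {
    if (!a.pearson) { mean_center(rawa, ca, na); ta = &ca; }
    if (!b.pearson) { mean_center(rawb, cb, nb); tb = &cb; }
  }
  if (na == 0.0 || nb == 0.0) return NA_REAL;
  double s = 0.0;
  for (size_t k = 0; k < ta->size(); ++k) s += (*ta)[k] * (*tb)[k];
  return s / (na * nb);
}

// [[Rcpp::export]]
List cpp_bicor(NumericMatrix X, Nullable<NumericMatrix> Yopt) {
  const bool sym = Yopt.isNull();
  NumericMatrix Y = sym ? X : NumericMatrix(Yopt);
  if (X.ncol() != Y.ncol()) stop("matrices must share the condition axis");
  const int nx = X.nrow(), ny = Y.nrow(), nc = X.ncol();

  std::vector<RowPrep> px(nx), py0;
  std::vector<std::vector<double> > rawx(nx), rawy0;
  for (int i = 0; i < nx; ++i) {
    px[i] = prep_row(X, i);
    if (!px[i].has_na) {
      rawx[i].resize(nc);
      for (int k = 0; k < nc; ++k) rawx[i][k] = X(i, k);
    }
  }
  const std::vector<RowPrep> *py = &px;
  const std::vector<std::vector<double> > *rawy = &rawx;
  if (!sym) {
    py0.resize(ny); rawy0.resize(ny);
    for (int i = 0; i < ny; ++i) {
      py0[i] = prep_row(Y, i);
      if (!py0[i].has_na) {
        rawy0[i].resize(nc);
        for (int k = 0; k < nc; ++k) rawy0[i][k] = Y(i, k);
      }
    }
    py = &py0; rawy = &rawy0;
  }

  NumericMatrix R(nx, ny);
  std::vector<int> bad_i, bad_j;
  for (int i = 0; i < nx; ++i) {
    const int j0 = sym ? i : 0;
    for (int j = j0; j < ny; ++j) {
      double r;
      if (sym && i == j) {
        r = 1.0;
      } else if (!px[i].has_na && !(*py)[j].has_na) {
        r = complete_pair(px[i], (*py)[j], rawx[i], (*rawy)[j]);
      } else {
        bool deficient = false;
        r = pair_cor(X, i, Y, j, deficient);
        if (deficient && bad_i.size() < 100) {
          bad_i.push_back(i + 1); bad_j.push_back(j + 1);
        }
      }
      R(i, j) = r;
      if (sym) R(j, i) = r;
    }
  }

  // rows whose observed entries have MAD == 0 (Pearson fallback), for logging
  std::vector<int> fb;
  for (int i = 0; i < nx; ++i) if (!px[i].has_na && px[i].pearson) fb.push_back(i + 1);
  return List::create(_["r"] = R,
                      _["pearson_rows_x"] = wrap(fb),
                      _["bad_i"] = wrap(bad_i),
                      _["bad_j"] = wrap(bad_j));
}
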