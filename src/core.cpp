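#include <Rcpp.h>
#include <chrono>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Per-stage wall-clock accounting for the sifting pipeline. Counters are
// process-global and only touched when profiling is switched on, so the hot
// path pays a single branch per stage otherwise.
// ---------------------------------------------------------------------------

enum Stage {
  ST_EXTREMA = 0,
  ST_TRIDIAG = 1,
  ST_COEF = 2,
  ST_INTERP = 3,
  ST_ENVMEAN = 4,
  ST_RESIDUE = 5,
  ST_N = 6
};

static bool g_prof_on = false;
static double g_prof[ST_N] = {0, 0, 0, 0, 0, 0};

struct StageTimer {
  int stage;
  bool active;
  std::chrono::steady_clock::time_point t0;
  explicit StageTimer(int s) : stage(s), active(g_prof_on) {
    if (active) t0 = std::chrono::steady_clock::now();
  }
  ~StageTimer() {
    if (active)
      g_prof[stage] +=
          std::chrono::duration<double>(std::chrono::steady_clock::now() - t0)
              .count();
  }
};

// [[Rcpp::export]]
void cpp_profile_enable(bool on) { g_prof_on = on; }

// [[Rcpp::export]]
void cpp_profile_reset() {
  for (int i = 0; i < ST_N; ++i) g_prof[i] = 0;
}

// [[Rcpp::export]]
NumericVector cpp_profile_read() {
  NumericVector out(ST_N);
  out.attr("names") = CharacterVector::create(
      "extrema", "tridiagonal_solve", "coefficients", "interpolation",
      "envelope_mean", "residue_update");
  for (int i = 0; i < ST_N; ++i) out[i] = g_prof[i];
  return out;
}

// ---------------------------------------------------------------------------
// Extrema detection. Strict neighbour comparison; a run of equal samples
// (plateau) counts as a single extremum at the run's first index. Boundary
// samples are never extrema.
// ---------------------------------------------------------------------------

static void extrema_scan(const double* x, int n, std::vector<int>& mx,
                         std::vector<int>& mn) {
  StageTimer t(ST_EXTREMA);
  mx.clear();
  mn.clear();
  if (n < 3) return;
  double prev = x[0];
  int i = 1;
  while (i < n - 1) {
    int j = i;
    while (j < n - 1 && x[j + 1] == x[i]) ++j;
    if (j == n - 1) break;  // plateau reaches the right boundary
    double right = x[j + 1];
    if (x[i] > prev && x[i] > right)
      mx.push_back(i);
    else if (x[i] < prev && x[i] < right)
      mn.push_back(i);
    prev = x[i];
    i = j + 1;
  }
}

// [[Rcpp::export]]
List cpp_find_extrema(NumericVector x) {
  std::vector<int> mx, mn;
  extrema_scan(REAL(x), x.size(), mx, mn);
  return List::create(_["max_positions"] = IntegerVector(mx.begin(), mx.end()),
                      _["min_positions"] = IntegerVector(mn.begin(), mn.end()));
}

// ---------------------------------------------------------------------------
// Thomas algorithm for tridiagonal systems. The natural-spline systems built
// here are strictly diagonally dominant, so no pivoting is required.
// ---------------------------------------------------------------------------

static int thomas_solve(const std::vector<double>& sub,
                        std::vector<double> diag,
                        const std::vector<double>& super,
                        std::vector<double>& rhs) {
  StageTimer t(ST_TRIDIAG);
  const int n = (int)diag.size();
  for (int i = 1; i < n; ++i) {
    if (diag[i - 1] == 0.0) return i - 1;  // zero pivot at row i-1
    double w = sub[i - 1] / diag[i - 1];
    diag[i] -= w * super[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  if (diag[n - 1] == 0.0) return n - 1;
  rhs[n - 1] /= diag[n - 1];
  for (int i = n - 2; i >= 0; --i)
    rhs[i] = (rhs[i] - super[i] * rhs[i + 1]) / diag[i];
  return -1;
}

// [[Rcpp::export]]
NumericVector cpp_solve_tridiagonal(NumericVector sub, NumericVector diag,
                                    NumericVector super, NumericVector rhs) {
  std::vector<double> a(sub.begin(), sub.end());
  std::vector<double> d(diag.begin(), diag.end());
  std::vector<double> c(super.begin(), super.end());
  std::vector<double> b(rhs.begin(), rhs.end());
  int bad = thomas_solve(a, d, c, b);
  if (bad >= 0)
    stop("zero pivot encountered in tridiagonal solve at row %d", bad + 1);
  return NumericVector(b.begin(), b.end());
}

// ---------------------------------------------------------------------------
// Natural cubic spline: second derivatives from the classic tridiagonal
// system (zero curvature at the end knots), then per-segment coefficients
// a + b*dx + c*dx^2 + d*dx^3 measured from the left knot.
// ---------------------------------------------------------------------------

static void natural_spline(const std::vector<double>& t,
                           const std::vector<double>& y,
                           std::vector<double>& A, std::vector<double>& B,
                           std::vector<double>& C, std::vector<double>& D) {
  const int m = (int)t.size();
  const int ns = m - 1;
  A.assign(ns, 0.0);
  B.assign(ns, 0.0);
  C.assign(ns, 0.0);
  D.assign(ns, 0.0);
  std::vector<double> h(ns);
  for (int i = 0; i < ns; ++i) h[i] = t[i + 1] - t[i];

  std::vector<double> sigma(m, 0.0);  // second derivatives at knots
  if (m > 2) {
    const int k = m - 2;
    std::vector<double> sub(k - 1), diag(k), super(k - 1), rhs(k);
    for (int i = 0; i < k; ++i) {
      diag[i] = 2.0 * (h[i] + h[i + 1]);
      rhs[i] = 6.0 * ((y[i + 2] - y[i + 1]) / h[i + 1] -
                      (y[i + 1] - y[i]) / h[i]);
      if (i < k - 1) {
        super[i] = h[i + 1];
        sub[i] = h[i + 1];
      }
    }
    int bad = thomas_solve(sub, diag, super, rhs);
    if (bad >= 0)
      stop("zero pivot in natural-spline tridiagonal system at row %d",
           bad + 1);
    for (int i = 0; i < k; ++i) sigma[i + 1] = rhs[i];
  }

  StageTimer tc(ST_COEF);
  for (int i = 0; i < ns; ++i) {
    A[i] = y[i];
    C[i] = sigma[i] / 2.0;
    D[i] = (sigma[i + 1] - sigma[i]) / (6.0 * h[i]);
    B[i] = (y[i + 1] - y[i]) / h[i] -
           h[i] * (2.0 * sigma[i] + sigma[i + 1]) / 6.0;
  }
}

// policy: 0 = "extend" (end segments extrapolate), 1 = "nearest" (clamp to
// the knot span, i.e. constant continuation of the end-knot values)
static void eval_spline(const std::vector<double>& t,
                        const std::vector<double>& A,
                        const std::vector<double>& B,
                        const std::vector<double>& C,
                        const std::vector<double>& D, const double* q, int nq,
                        double* out, int policy) {
  StageTimer ti(ST_INTERP);
  const int m = (int)t.size();
  for (int i = 0; i < nq; ++i) {
    double u = q[i];
    if (policy == 1) {
      if (u < t[0]) u = t[0];
      if (u > t[m - 1]) u = t[m - 1];
    }
    int seg;
    if (u <= t[0])
      seg = 0;
    else if (u >= t[m - 1])
      seg = m - 2;
    else
      seg = (int)(std::upper_bound(t.begin(), t.end(), u) - t.begin()) - 1;
    double dx = u - t[seg];
    out[i] = A[seg] + dx * (B[seg] + dx * (C[seg] + dx * D[seg]));
  }
}

// [[Rcpp::export]]
List cpp_spline_coefficients(NumericVector knot_positions,
                             NumericVector knot_values) {
  std::vector<double> t(knot_positions.begin(), knot_positions.end());
  std::vector<double> y(knot_values.begin(), knot_values.end());
  std::vector<double> A, B, C, D;
  natural_spline(t, y, A, B, C, D);
  const int ns = (int)A.size();
  NumericMatrix coef(ns, 4);
  for (int i = 0; i < ns; ++i) {
    coef(i, 0) = A[i];
    coef(i, 1) = B[i];
    coef(i, 2) = C[i];
    coef(i, 3) = D[i];
  }
  colnames(coef) =
      CharacterVector::create("constant", "linear", "quadratic", "cubic");
  return List::create(_["knots"] = knot_positions, _["coefficients"] = coef);
}

// [[Rcpp::export]]
NumericVector cpp_eval_spline(NumericVector knot_positions, NumericMatrix coef,
                              NumericVector query, int policy) {
  std::vector<double> t(knot_positions.begin(), knot_positions.end());
  const int ns = coef.nrow();
  std::vector<double> A(ns), B(ns), C(ns), D(ns);
  for (int i = 0; i < ns; ++i) {
    A[i] = coef(i, 0);
    B[i] = coef(i, 1);
    C[i] = coef(i, 2);
    D[i] = coef(i, 3);
  }
  NumericVector out(query.size());
  eval_spline(t, A, B, C, D, REAL(query), query.size(), REAL(out), policy);
  return out;
}

// ---------------------------------------------------------------------------
// Envelope construction. The two extrema nearest each end are mirrored
// across the signal boundary before spline fitting to tame end effects.
// ---------------------------------------------------------------------------

static void mirrored_knots(const std::vector<int>& pos, const double* x, int n,
                           bool mirror, std::vector<double>& t,
                           std::vector<double>& y) {
  const int k = (int)pos.size();
  t.clear();
  y.clear();
  if (mirror && k >= 2) {
    // reflect across the left boundary (sample 0); keep knots strictly
    // increasing (drop the mirror of an extremum sitting exactly at 0)
    t.push_back(-(double)pos[1]);
    y.push_back(x[pos[1]]);
    if (pos[0] > 0) {
      t.push_back(-(double)pos[0]);
      y.push_back(x[pos[0]]);
    }
  }
  for (int i = 0; i < k; ++i) {
    t.push_back((double)pos[i]);
    y.push_back(x[pos[i]]);
  }
  if (mirror && k >= 2) {
    const double R = 2.0 * (n - 1);
    if (pos[k - 1] < n - 1) {
      t.push_back(R - (double)pos[k - 1]);
      y.push_back(x[pos[k - 1]]);
    }
    t.push_back(R - (double)pos[k - 2]);
    y.push_back(x[pos[k - 2]]);
  }
}

static bool envelope_pair(const double* x, int n, const std::vector<int>& mx,
                          const std::vector<int>& mn, bool mirror,
                          std::vector<double>& upper,
                          std::vector<double>& lower) {
  if ((int)mx.size() < 2 || (int)mn.size() < 2) return false;
  std::vector<double> q(n);
  for (int i = 0; i < n; ++i) q[i] = (double)i;
  std::vector<double> t, y, A, B, C, D;

  mirrored_knots(mx, x, n, mirror, t, y);
  natural_spline(t, y, A, B, C, D);
  upper.resize(n);
  eval_spline(t, A, B, C, D, q.data(), n, upper.data(), 0);

  mirrored_knots(mn, x, n, mirror, t, y);
  natural_spline(t, y, A, B, C, D);
  lower.resize(n);
  eval_spline(t, A, B, C, D, q.data(), n, lower.data(), 0);
  return true;
}

// [[Rcpp::export]]
List cpp_envelope_pair(NumericVector x, IntegerVector max_positions,
                       IntegerVector min_positions, bool mirror) {
  std::vector<int> mx(max_positions.begin(), max_positions.end());
  std::vector<int> mn(min_positions.begin(), min_positions.end());
  std::vector<double> u, l;
  bool ok = envelope_pair(REAL(x), x.size(), mx, mn, mirror, u, l);
  if (!ok)
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true,
                      _["upper"] = NumericVector(u.begin(), u.end()),
                      _["lower"] = NumericVector(l.begin(), l.end()));
}

// ---------------------------------------------------------------------------
// Sifting: repeat (extrema -> envelopes -> mean -> subtract) on a working
// copy. stop_mode 0 runs exactly S passes; stop_mode 1 additionally stops
// when the relative squared change of the candidate drops below `tol`
// (Cauchy-style criterion), with S as the iteration cap. If at any round
// fewer than 2 maxima or 2 minima remain, the current working copy is
// returned and flagged monotonic.
// ---------------------------------------------------------------------------

static inline void fp32_round(double* w, int n) {
  for (int i = 0; i < n; ++i) w[i] = (double)(float)w[i];
}

static void sift_inplace(double* w, int n, int S, int stop_mode, double tol,
                         bool fp32, bool& monotonic, int& iters) {
  monotonic = false;
  iters = 0;
  std::vector<int> mx, mn;
  std::vector<double> upper, lower, m(n);
  for (int s = 0; s < S; ++s) {
    extrema_scan(w, n, mx, mn);
    if (!envelope_pair(w, n, mx, mn, true, upper, lower)) {
      monotonic = true;
      return;
    }
    {
      StageTimer te(ST_ENVMEAN);
      for (int i = 0; i < n; ++i) m[i] = 0.5 * (upper[i] + lower[i]);
    }
    double num = 0.0, den = 0.0;
    if (stop_mode == 1) {
      for (int i = 0; i < n; ++i) {
        num += m[i] * m[i];
        den += w[i] * w[i];
      }
    }
    {
      StageTimer tr(ST_RESIDUE);
      for (int i = 0; i < n; ++i) w[i] -= m[i];
    }
    if (fp32) fp32_round(w, n);
    ++iters;
    if (stop_mode == 1 && den > 0.0 && num / den < tol) return;
  }
}

// [[Rcpp::export]]
List cpp_sift(NumericVector x, int S, int stop_mode, double tol, bool fp32) {
  const int n = x.size();
  NumericVector w = clone(x);
  bool monotonic;
  int iters;
  sift_inplace(REAL(w), n, S, stop_mode, tol, fp32, monotonic, iters);
  return List::create(_["mode"] = w, _["monotonic"] = monotonic,
                      _["iterations"] = iters);
}

static bool has_enough_extrema(const double* x, int n) {
  std::vector<int> mx, mn;
  extrema_scan(x, n, mx, mn);
  return (int)mx.size() >= 2 && (int)mn.size() >= 2;
}

// [[Rcpp::export]]
bool cpp_has_enough_extrema(NumericVector x) {
  return has_enough_extrema(REAL(x), x.size());
}

// ---------------------------------------------------------------------------
// Full EMD: extract up to K modes; stop when the running residue has fewer
// than 2 maxima or 2 minima. Completeness (sum of modes + residue == input)
// holds by telescoping subtraction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_emd(NumericVector x, int K, int S, int stop_mode, double tol,
             bool fp32) {
  const int n = x.size();
  std::vector<double> residue(REAL(x), REAL(x) + n);
  std::vector<std::vector<double> > modes;
  bool monotonic;
  int iters;
  for (int k = 0; k < K; ++k) {
    if (!has_enough_extrema(residue.data(), n)) break;
    std::vector<double> w(residue);
    sift_inplace(w.data(), n, S, stop_mode, tol, fp32, monotonic, iters);
    {
      StageTimer tr(ST_RESIDUE);
      for (int i = 0; i < n; ++i) residue[i] -= w[i];
    }
    if (fp32) fp32_round(residue.data(), n);
    modes.push_back(w);
  }
  const int k = (int)modes.size();
  NumericMatrix M(k, n);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) M(j, i) = modes[j][i];
  return List::create(_["modes"] = M,
                      _["residue"] = NumericVector(residue.begin(),
                                                   residue.end()),
                      _["n_modes"] = k);
}

// ---------------------------------------------------------------------------
// Batch local mean: row i of the result is M(row i) = row - sift(row).
// Rows are processed independently with the same scalar kernel, so the batch
// result is bit-identical to a per-row loop.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_batch_local_mean(NumericMatrix X, int S, int stop_mode,
                                   double tol, bool fp32) {
  const int I = X.nrow(), n = X.ncol();
  NumericMatrix out(I, n);
  std::vector<double> row(n), w(n);
  bool monotonic;
  int iters;
  for (int r = 0; r < I; ++r) {
    for (int i = 0; i < n; ++i) row[i] = X(r, i);
    w = row;
    sift_inplace(w.data(), n, S, stop_mode, tol, fp32, monotonic, iters);
    for (int i = 0; i < n; ++i) out(r, i) = row[i] - w[i];
  }
  return out;
}
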