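#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// LMS adaptive noise canceller over an N-stage tapped delay line.
// Per-sample recursion:
//   y_k = w_k' x_k;  e_k = d_k - y_k;  w_{k+1} = w_k + step * e_k * x_k
// x_k holds the N most recent reference samples (most recent first),
// zero-padded before k = 0.  Weights start at zero.
// `pre` holds the reference pre-history x[-1], x[-2], ... (most recent
// first) used to seed the delay line; shorter than N-1 means the remaining
// taps start at zero.
// [[Rcpp::export(name = ".lms_cpp")]]
List lms_cpp(NumericVector d, NumericVector x, int N, double step,
             double guard, NumericVector pre) {
  const int n = d.size();
  NumericVector y(n), e(n);
  std::vector<double> w(N, 0.0), tdl(N, 0.0);
  // tdl is shifted before the first insertion, so seed positions 0..N-2
  // with x[-1], x[-2], ...: after inserting x[0] the line reads
  // [x[0], x[-1], x[-2], ...]
  for (int j = 0; j < std::min<int>(pre.size(), N - 1); ++j)
    tdl[j] = pre[j];
  int diverged_at = -1;
  for (int k = 0; k < n; ++k) {
    // shift the delay line: tdl[0] is the newest reference sample
    for (int j = N - 1; j > 0; --j) tdl[j] = tdl[j - 1];
    tdl[0] = x[k];
    double yk = 0.0;
    for (int j = 0; j < N; ++j) yk += w[j] * tdl[j];
    double ek = d[k] - yk;
    y[k] = yk;
    e[k] = ek;
    const double g = step * ek;
    for (int j = 0; j < N; ++j) w[j] += g * tdl[j];
    if ((k & 127) == 0 || k == n - 1) {
      double nrm2 = 0.0;
      for (int j = 0; j < N; ++j) nrm2 += w[j] * w[j];
      if (!std::isfinite(nrm2) || nrm2 > guard * guard) {
        diverged_at = k + 1;  // 1-based sample index for R
        break;
      }
    }
  }
  return List::create(_["output"] = e, _["interference"] = y,
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["diverged_at"] = diverged_at);
}

// Robust locally weighted polynomial regression on a uniform grid.
// At each point the window is the `span` nearest samples (contiguous on a
// uniform grid; slides to stay in bounds at the edges).  Tricube distance
// weights, optionally multiplied by bisquare robustness weights; local
// degree-d polynomial fit by weighted least squares (normal equations,
// Gaussian elimination with partial pivoting - the systems are (d+1)x(d+1)).
static void local_fit(const std::vector<double> &yy,
                      const std::vector<double> &rw, bool use_rw,
                      int n, int span, int degree, std::vector<double> &out) {
  const int p = degree + 1;
  std::vector<double> A(p * p), b(p), pw(2 * degree + 1);
  for (int i = 0; i < n; ++i) {
    int lo = i - (span - 1) / 2;
    lo = std::max(0, std::min(lo, n - span));
    const int hi = lo + span - 1;
    const double dmax = std::max(double(i - lo), double(hi - i));
    std::fill(pw.begin(), pw.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    for (int k = lo; k <= hi; ++k) {
      const double u = dmax > 0 ? std::fabs(double(k - i)) / dmax : 0.0;
      double wt = 1.0 - u * u * u;
      wt = wt * wt * wt;          // tricube
      if (wt <= 0.0) continue;
      if (use_rw) wt *= rw[k];
      const double dx = double(k - i);
      double xp = 1.0;
      for (int m = 0; m < 2 * degree + 1; ++m) { pw[m] += wt * xp; xp *= dx; }
      xp = 1.0;
      for (int m = 0; m < p; ++m) { b[m] += wt * xp * yy[k]; xp *= dx; }
    }
    for (int r = 0; r < p; ++r)
      for (int c = 0; c < p; ++c) A[r * p + c] = pw[r + c];
    // solve A beta = b (partial pivoting)
    std::vector<double> M(A), rhs(b);
    for (int c = 0; c < p; ++c) {
      int piv = c;
      for (int r = c + 1; r < p; ++r)
        if (std::fabs(M[r * p + c]) > std::fabs(M[piv * p + c])) piv = r;
      if (std::fabs(M[piv * p + c]) < 1e-300)
        stop("singular local weighted least-squares system at sample %d",
             i + 1);
      if (piv != c) {
        for (int cc = c; cc < p; ++cc) std::swap(M[c * p + cc], M[piv * p + cc]);
        std::swap(rhs[c], rhs[piv]);
      }
      for (int r = c + 1; r < p; ++r) {
        const double f = M[r * p + c] / M[c * p + c];
        for (int cc = c; cc < p; ++cc) M[r * p + cc] -= f * M[c * p + cc];
        rhs[r] -= f * rhs[c];
      }
    }
    for (int r = p - 1; r >= 0; --r) {
      double s = rhs[r];
      for (int c = r + 1; c < p; ++c) s -= M[r * p + c] * rhs[c];
      rhs[r] = s / M[r * p + r];
    }
    out[i] = rhs[0];  // fitted value at dx = 0
  }
}

// [[Rcpp::export(name = ".lowess_cpp")]]
NumericVector lowess_cpp(NumericVector y, int span, int degree,
                         int robust_iters) {
  const int n = y.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> fit(n), rw(n, 1.0);
  local_fit(yy, rw, false, n, span, degree, fit);
  for (int it = 0; it < robust_iters; ++it) {
    std::vector<double> absr(n);
    for (int i = 0; i < n; ++i) absr[i] = std::fabs(yy[i] - fit[i]);
    std::vector<double> srt(absr);
    std::nth_element(srt.begin(), srt.begin() + n / 2, srt.end());
    double med = srt[n / 2];
    if (n % 2 == 0) {
      std::nth_element(srt.begin(), srt.begin() + n / 2 - 1, srt.end());
      med = 0.5 * (med + srt[n / 2 - 1]);
    }
    const double s = 6.0 * med;
    if (s <= 0.0) break;  // perfect fit: nothing to downweight
    for (int i = 0; i < n; ++i) {
      const double u = absr[i] / s;
      rw[i] = u < 1.0 ? (1.0 - u * u) * (1.0 - u * u) : 0.0;  // bisquare
    }
    local_fit(yy, rw, true, n, span, degree, fit);
  }
  return NumericVector(fit.begin(), fit.end());
}
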