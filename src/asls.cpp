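#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Asymmetric least squares baseline estimation (Whittaker smoother with
// asymmetric weights). The normal matrix M = W + lambda * D2' D2 is
// symmetric positive definite and pentadiagonal, so each reweighting
// iteration is a banded Cholesky solve, O(n) per spectrum.

// second-difference penalty bands: k0 = diag, k1 = first, k2 = second
static void d2td2_bands(int n, std::vector<double>& k0,
                        std::vector<double>& k1, std::vector<double>& k2) {
  k0.assign(n, 0.0);
  k1.assign(n, 0.0);  // k1[i] = K[i, i+1]
  k2.assign(n, 0.0);  // k2[i] = K[i, i+2]
  const double c[3] = {1.0, -2.0, 1.0};
  for (int r = 0; r + 2 < n; ++r) {
    for (int a = 0; a < 3; ++a) {
      k0[r + a] += c[a] * c[a];
      if (a + 1 < 3) k1[r + a] += c[a] * c[a + 1];
      if (a + 2 < 3) k2[r + a] += c[a] * c[a + 2];
    }
  }
}

// solve (diag(w) + lambda*K) z = w .* y, K pentadiagonal from bands
static void banded_solve(const std::vector<double>& k0,
                         const std::vector<double>& k1,
                         const std::vector<double>& k2,
                         const std::vector<double>& w,
                         const double* y, double lambda, double* z,
                         std::vector<double>& al, std::vector<double>& be,
                         std::vector<double>& ga, std::vector<double>& u) {
  int n = (int) k0.size();
  for (int i = 0; i < n; ++i) {
    double gi = 0.0, bi = 0.0;
    if (i >= 2) gi = lambda * k2[i - 2] / al[i - 2];
    if (i >= 1) bi = (lambda * k1[i - 1] - (i >= 2 ? gi * be[i - 1] : 0.0))
                     / al[i - 1];
    double di = w[i] + lambda * k0[i] - bi * bi - gi * gi;
    if (di <= 0.0) stop("AsLS banded Cholesky failed (matrix not SPD)");
    al[i] = std::sqrt(di);
    be[i] = bi;
    ga[i] = gi;
    double rhs = w[i] * y[i];
    if (i >= 1) rhs -= be[i] * u[i - 1];
    if (i >= 2) rhs -= ga[i] * u[i - 2];
    u[i] = rhs / al[i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = u[i];
    if (i + 1 < n) v -= be[i + 1] * z[i + 1];
    if (i + 2 < n) v -= ga[i + 2] * z[i + 2];
    z[i] = v / al[i];
  }

  // one step of iterative refinement: the system is ill-conditioned for
  // large lambda and plain substitution leaves ~1e-7 relative error
  std::vector<double> r(n), dz(n);
  for (int i = 0; i < n; ++i) {
    double mv = (w[i] + lambda * k0[i]) * z[i];
    if (i >= 1) mv += lambda * k1[i - 1] * z[i - 1];
    if (i + 1 < n) mv += lambda * k1[i] * z[i + 1];
    if (i >= 2) mv += lambda * k2[i - 2] * z[i - 2];
    if (i + 2 < n) mv += lambda * k2[i] * z[i + 2];
    r[i] = w[i] * y[i] - mv;
  }
  for (int i = 0; i < n; ++i) {
    double rhs = r[i];
    if (i >= 1) rhs -= be[i] * u[i - 1];
    if (i >= 2) rhs -= ga[i] * u[i - 2];
    u[i] = rhs / al[i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double v = u[i];
    if (i + 1 < n) v -= be[i + 1] * dz[i + 1];
    if (i + 2 < n) v -= ga[i + 2] * dz[i + 2];
    dz[i] = v / al[i];
    z[i] += dz[i];
  }
}

static void asls_core(const double* y, int n, double lambda, double p,
                      int maxit, double* z,
                      const std::vector<double>& k0,
                      const std::vector<double>& k1,
                      const std::vector<double>& k2) {
  std::vector<double> w(n, 1.0), al(n), be(n), ga(n), u(n);
  for (int it = 0; it < maxit; ++it) {
    banded_solve(k0, k1, k2, w, y, lambda, z, al, be, ga, u);
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double wi = (y[i] > z[i]) ? p : 1.0 - p;
      if (wi != w[i]) { w[i] = wi; changed = true; }
    }
    if (!changed) break;
  }
}

// [[Rcpp::export(name = ".asls_baseline_cpp")]]
NumericVector asls_baseline_cpp(NumericVector y, double lambda, double p,
                                int maxit) {
  int n = y.size();
  std::vector<double> k0, k1, k2;
  d2td2_bands(n, k0, k1, k2);
  NumericVector z(n);
  asls_core(y.begin(), n, lambda, p, maxit, z.begin(), k0, k1, k2);
  return z;
}

// rows of Y are spectra; returns the baseline of each row
// [[Rcpp::export(name = ".asls_baseline_mat_cpp")]]
NumericMatrix asls_baseline_mat_cpp(NumericMatrix Y, double lambda, double p,
                                    int maxit) {
  int nr = Y.nrow(), nc = Y.ncol();
  std::vector<double> k0, k1, k2;
  d2td2_bands(nc, k0, k1, k2);
  NumericMatrix Z(nr, nc);
  std::vector<double> y(nc), z(nc);
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < nc; ++j) y[j] = Y(r, j);
    asls_core(y.data(), nc, lambda, p, maxit, z.data(), k0, k1, k2);
    for (int j = 0; j < nc; ++j) Z(r, j) = z[j];
  }
  return Z;
}
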