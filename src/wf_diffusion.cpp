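#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tridiagonal (Thomas) solve; overwrites d with the solution.
static void thomas_solve(int n, const double* a, const double* b,
                         const double* c, double* d, double* cp, double* dp) {
  cp[0] = c[0] / b[0];
  dp[0] = d[0] / b[0];
  for (int i = 1; i < n; ++i) {
    double m = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / m;
    dp[i] = (d[i] - a[i] * dp[i - 1]) / m;
  }
  d[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = dp[i] - cp[i] * d[i + 1];
}

// Interface flux F_{j+1/2} = alpha_j phi_j + beta_j phi_{j+1} for
// F = M phi - d(V phi)/dx / 2.  Central weighting of the advective term
// where the cell Peclet number allows, first-order upwind otherwise
// (the upwind branch is what carries density off a V = 0 boundary line
// when migration points inward).
static void flux_coefs(int P, double h, const double* V, const double* Mint,
                       double* alpha, double* beta) {
  double inv2h = 1.0 / (2.0 * h);
  for (int i = 0; i < P - 1; ++i) {
    double vface = 0.5 * (V[i] + V[i + 1]);
    double M = Mint[i];
    if (std::fabs(M) * 2.0 * h <= vface) {
      alpha[i] = 0.5 * M + V[i] * inv2h;
      beta[i] = 0.5 * M - V[i + 1] * inv2h;
    } else if (M > 0) {
      alpha[i] = M + V[i] * inv2h;
      beta[i] = -V[i + 1] * inv2h;
    } else {
      alpha[i] = V[i] * inv2h;
      beta[i] = M - V[i + 1] * inv2h;
    }
  }
}

// One backward-Euler step of dphi/dt = -dF/dx on a uniform grid with
// half-width cells at the two boundaries (finite-volume form).
static void implicit_step(int P, double h, double dt, const double* alpha,
                          const double* beta, double* phi, double* a,
                          double* b, double* c, double* cp, double* dp) {
  for (int j = 0; j < P; ++j) {
    double dj = (j == 0 || j == P - 1) ? 0.5 * h : h;
    double sub = 0.0, dia = 0.0, sup = 0.0;
    if (j > 0) {
      sub = alpha[j - 1] / dj;
      dia += beta[j - 1] / dj;
    }
    if (j < P - 1) {
      dia -= alpha[j] / dj;
      sup = -beta[j] / dj;
    }
    a[j] = -dt * sub;
    b[j] = 1.0 - dt * dia;
    c[j] = -dt * sup;
  }
  thomas_solve(P, a, b, c, phi, cp, dp);
}

// [[Rcpp::export(name = ".wf_integrate_1d")]]
NumericVector wf_integrate_1d(NumericVector phi0, NumericVector xx,
                              NumericVector nu, NumericVector dt,
                              double theta) {
  int P = phi0.size(), S = dt.size();
  if (nu.size() != S) stop("nu and dt must have one value per time step");
  NumericVector phi = clone(phi0);
  double h = xx[1] - xx[0];
  std::vector<double> V(P), Mint(P - 1, 0.0), alpha(P - 1), beta(P - 1),
      a(P), b(P), c(P), cp(P), dp(P);
  double inj = theta / (2.0 * h * h);  // source at first interior point
  for (int k = 0; k < S; ++k) {
    for (int j = 0; j < P; ++j) V[j] = xx[j] * (1.0 - xx[j]) / nu[k];
    flux_coefs(P, h, V.data(), Mint.data(), alpha.data(), beta.data());
    phi[1] += dt[k] * inj;
    implicit_step(P, h, dt[k], alpha.data(), beta.data(), REAL(phi), a.data(),
                  b.data(), c.data(), cp.data(), dp.data());
  }
  for (int j = 0; j < P; ++j)
    if (!std::isfinite(phi[j]))
      stop("diffusion solver produced a non-finite value at grid point %d", j + 1);
  return phi;
}

// Two-population integration by direction-split implicit stepping (one
// tridiagonal sweep per row and per column each time step).  phi(i, j) is
// the density at x1 = xx[i], x2 = xx[j]; migration enters as drift
// m12 (x2 - x1) along x1 and m21 (x1 - x2) along x2.
// [[Rcpp::export(name = ".wf_integrate_2d")]]
NumericMatrix wf_integrate_2d(NumericMatrix phi0, NumericVector xx,
                              NumericVector nu1, NumericVector nu2,
                              double m12, double m21, NumericVector dt,
                              double theta) {
  int P = phi0.nrow(), S = dt.size();
  if (phi0.ncol() != P) stop("phi must be square");
  if (nu1.size() != S || nu2.size() != S)
    stop("nu1, nu2 and dt must have one value per time step");
  NumericMatrix phi = clone(phi0);
  double h = xx[1] - xx[0];
  std::vector<double> V(P), Mint(P - 1), alpha(P - 1), beta(P - 1), a(P),
      b(P), c(P), cp(P), dp(P), col(P), xmid(P - 1);
  for (int i = 0; i < P - 1; ++i) xmid[i] = 0.5 * (xx[i] + xx[i + 1]);
  double inj = theta / (h * h * h);  // axis sources, one point in from corner
  for (int k = 0; k < S; ++k) {
    phi(1, 0) += dt[k] * inj;
    phi(0, 1) += dt[k] * inj;
    // sweep along x1 for every column (fixed x2)
    for (int j = 0; j < P; ++j) V[j] = xx[j] * (1.0 - xx[j]) / nu1[k];
    for (int j2 = 0; j2 < P; ++j2) {
      double x2 = xx[j2];
      for (int i = 0; i < P - 1; ++i) Mint[i] = m12 * (x2 - xmid[i]);
      flux_coefs(P, h, V.data(), Mint.data(), alpha.data(), beta.data());
      for (int i = 0; i < P; ++i) col[i] = phi(i, j2);
      implicit_step(P, h, dt[k], alpha.data(), beta.data(), col.data(),
                    a.data(), b.data(), c.data(), cp.data(), dp.data());
      for (int i = 0; i < P; ++i) phi(i, j2) = col[i];
    }
    // sweep along x2 for every row (fixed x1)
    for (int j = 0; j < P; ++j) V[j] = xx[j] * (1.0 - xx[j]) / nu2[k];
    for (int i1 = 0; i1 < P; ++i1) {
      double x1 = xx[i1];
      for (int i = 0; i < P - 1; ++i) Mint[i] = m21 * (x1 - xmid[i]);
      flux_coefs(P, h, V.data(), Mint.data(), alpha.data(), beta.data());
      for (int i = 0; i < P; ++i) col[i] = phi(i1, i);
      implicit_step(P, h, dt[k], alpha.data(), beta.data(), col.data(),
                    a.data(), b.data(), c.data(), cp.data(), dp.data());
      for (int i = 0; i < P; ++i) phi(i1, i) = col[i];
    }
  }
  for (int j2 = 0; j2 < P; ++j2)
    for (int i = 0; i < P; ++i)
      if (!std::isfinite(phi(i, j2)))
        stop("diffusion solver produced a non-finite value at cell (%d, %d)",
             i + 1, j2 + 1);
  return phi;
}
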