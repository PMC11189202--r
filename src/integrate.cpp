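// Stiff integration of the antibody-receptor mass-action networks.
//
// The networks are small (4 or 6 species) but span ~10 orders of magnitude in
// rate scales (sub-picomolar cross-linking K_D against nM-scale first-step
// binding), so an L-stable method with an analytic Jacobian is used:
// RODAS3, a 4-stage stiffly-accurate Rosenbrock method of order 3 with an
// embedded order-2 error estimate (Sandu et al. 1997, as implemented in KPP).
//
// Within a phase the systems are autonomous; washout is handled by the R
// layer as a state reset between phases, so no time-derivative terms appear
// in the stage equations.
//
// State layouts (receptors and complexes in #/cell, free antibody in nM):
//   heterobivalent (type 0): Ab, R1, R2, Ab.R1, Ab.R2, R1.Ab.R2
//   homobivalent   (type 1): Ab, R,  Ab.R, R.Ab.R

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAXN = 6;

struct Network {
  int type;       // 0 hetero, 1 homo
  int n;          // number of species
  bool clamp_ab;  // hold free antibody fixed (clamped washout)
  // hetero: kon1, kon2, kon1s, kon2s, koff1, koff2, alpha
  // homo:   kon, konstar, koff, alpha, statfactor
  double p[8];

  void rhs(const double* y, double* f) const {
    if (type == 0) {
      const double kon1 = p[0], kon2 = p[1], kon1s = p[2], kon2s = p[3],
                   koff1 = p[4], koff2 = p[5], alpha = p[6];
      const double Ab = y[0], R1 = y[1], R2 = y[2], C1 = y[3], C2 = y[4],
                   T = y[5];
      const double v1 = kon1 * Ab * R1;   // Ab + R1 -> Ab.R1     [#/cell/s]
      const double v2 = kon2 * Ab * R2;   // Ab + R2 -> Ab.R2
      const double v3 = kon1s * C2 * R1;  // Ab.R2 + R1 -> ternary
      const double v4 = kon2s * C1 * R2;  // Ab.R1 + R2 -> ternary
      f[0] = clamp_ab ? 0.0
                      : alpha * (-v1 - v2 + koff1 * C1 + koff2 * C2);
      f[1] = -v1 - v3 + koff1 * C1 + koff1 * T;
      f[2] = -v2 - v4 + koff2 * C2 + koff2 * T;
      f[3] = v1 - koff1 * C1 - v4 + koff2 * T;
      f[4] = v2 - koff2 * C2 - v3 + koff1 * T;
      f[5] = v3 + v4 - (koff1 + koff2) * T;
    } else {
      const double kon = p[0], konstar = p[1], koff = p[2], alpha = p[3],
                   sf = p[4];
      const double Ab = y[0], R = y[1], C = y[2], T = y[3];
      const double v1 = sf * kon * Ab * R;  // statistical factor on 1st step
      const double v2 = konstar * C * R;
      const double dT = sf * koff * T;      // and on ternary -> binary
      f[0] = clamp_ab ? 0.0 : alpha * (-v1 + koff * C);
      f[1] = -v1 - v2 + koff * C + dT;
      f[2] = v1 - koff * C - v2 + dT;
      f[3] = v2 - dT;
    }
  }

  void jac(const double* y, double J[MAXN][MAXN]) const {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) J[i][j] = 0.0;
    if (type == 0) {
      const double kon1 = p[0], kon2 = p[1], kon1s = p[2], kon2s = p[3],
                   koff1 = p[4], koff2 = p[5], alpha = p[6];
      const double Ab = y[0], R1 = y[1], R2 = y[2], C1 = y[3], C2 = y[4];
      if (!clamp_ab) {
        J[0][0] = alpha * (-kon1 * R1 - kon2 * R2);
        J[0][1] = -alpha * kon1 * Ab;
        J[0][2] = -alpha * kon2 * Ab;
        J[0][3] = alpha * koff1;
        J[0][4] = alpha * koff2;
      }
      J[1][0] = -kon1 * R1;
      J[1][1] = -kon1 * Ab - kon1s * C2;
      J[1][3] = koff1;
      J[1][4] = -kon1s * R1;
      J[1][5] = koff1;
      J[2][0] = -kon2 * R2;
      J[2][2] = -kon2 * Ab - kon2s * C1;
      J[2][3] = -kon2s * R2;
      J[2][4] = koff2;
      J[2][5] = koff2;
      J[3][0] = kon1 * R1;
      J[3][1] = kon1 * Ab;
      J[3][2] = -kon2s * C1;
      J[3][3] = -koff1 - kon2s * R2;
      J[3][5] = koff2;
      J[4][0] = kon2 * R2;
      J[4][1] = -kon1s * C2;
      J[4][2] = kon2 * Ab;
      J[4][4] = -koff2 - kon1s * R1;
      J[4][5] = koff1;
      J[5][1] = kon1s * C2;
      J[5][2] = kon2s * C1;
      J[5][3] = kon2s * R2;
      J[5][4] = kon1s * R1;
      J[5][5] = -(koff1 + koff2);
    } else {
      const double kon = p[0], konstar = p[1], koff = p[2], alpha = p[3],
                   sf = p[4];
      const double Ab = y[0], R = y[1], C = y[2];
      if (!clamp_ab) {
        J[0][0] = -alpha * sf * kon * R;
        J[0][1] = -alpha * sf * kon * Ab;
        J[0][2] = alpha * koff;
      }
      J[1][0] = -sf * kon * R;
      J[1][1] = -sf * kon * Ab - konstar * C;
      J[1][2] = koff - konstar * R;
      J[1][3] = sf * koff;
      J[2][0] = sf * kon * R;
      J[2][1] = sf * kon * Ab - konstar * C;
      J[2][2] = -koff - konstar * R;
      J[2][3] = sf * koff;
      J[3][1] = konstar * C;
      J[3][2] = konstar * R;
      J[3][3] = -sf * koff;
    }
  }
};

// Dense LU with partial pivoting for n <= 6.
static bool lu_decomp(double A[MAXN][MAXN], int n, int piv[MAXN]) {
  for (int k = 0; k < n; ++k) {
    int imax = k;
    double amax = std::fabs(A[k][k]);
    for (int i = k + 1; i < n; ++i)
      if (std::fabs(A[i][k]) > amax) { amax = std::fabs(A[i][k]); imax = i; }
    if (amax == 0.0) return false;
    piv[k] = imax;
    if (imax != k)
      for (int j = 0; j < n; ++j) std::swap(A[k][j], A[imax][j]);
    const double inv = 1.0 / A[k][k];
    for (int i = k + 1; i < n; ++i) {
      A[i][k] *= inv;
      const double m = A[i][k];
      for (int j = k + 1; j < n; ++j) A[i][j] -= m * A[k][j];
    }
  }
  return true;
}

static void lu_solve(const double A[MAXN][MAXN], int n, const int piv[MAXN],
                     double* b) {
  for (int k = 0; k < n; ++k)
    if (piv[k] != k) std::swap(b[k], b[piv[k]]);
  for (int k = 0; k < n; ++k)
    for (int i = k + 1; i < n; ++i) b[i] -= A[i][k] * b[k];
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) b[i] -= A[i][j] * b[j];
    b[i] /= A[i][i];
  }
}

// RODAS3 coefficients (gamma = 1/2), autonomous form.
static const double R3_GAMMA = 0.5;
static const double R3_A31 = 2.0, R3_A41 = 2.0, R3_A43 = 1.0;
static const double R3_C21 = 4.0;
static const double R3_C31 = 1.0, R3_C32 = -1.0;
static const double R3_C41 = 1.0, R3_C42 = -1.0, R3_C43 = -8.0 / 3.0;
static const double R3_M1 = 2.0, R3_M3 = 1.0, R3_M4 = 1.0;
// embedded error = k4 (E = {0,0,0,1})

// Advance y in place from t0 to t1 with adaptive RODAS3 steps. `h_inout`
// carries the step size across segments of one trajectory.
static void advance(const Network& net, double* y, double t0, double t1,
                    double rtol, const double* atol, long& steps,
                    int max_steps, double& h_inout) {
  const int n = net.n;
  double ynew[MAXN], f0[MAXN], ftmp[MAXN], ytmp[MAXN];
  double k1[MAXN], k2[MAXN], k3[MAXN], k4[MAXN];
  double A[MAXN][MAXN], J[MAXN][MAXN];
  int piv[MAXN];
  double t = t0;
  double h = h_inout;
  if (h <= 0 || h > (t1 - t0)) h = (t1 - t0) * 1e-6;
  const double hmin = (t1 - t0) * 1e-14;

  while (t < t1 - hmin) {
    if (++steps > max_steps)
      stop("ODE integrator exceeded max_steps at t = %f", t);
    if (t + h > t1) h = t1 - t;

    net.rhs(y, f0);
    net.jac(y, J);
    const double hg = 1.0 / (h * R3_GAMMA);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) A[i][j] = (i == j ? hg : 0.0) - J[i][j];
    if (!lu_decomp(A, n, piv)) stop("singular iteration matrix at t = %f", t);

    // stage 1
    for (int i = 0; i < n; ++i) k1[i] = f0[i];
    lu_solve(A, n, piv, k1);
    // stage 2 (Y2 = y)
    for (int i = 0; i < n; ++i) k2[i] = f0[i] + (R3_C21 / h) * k1[i];
    lu_solve(A, n, piv, k2);
    // stage 3: Y3 = y + 2 k1
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + R3_A31 * k1[i];
    net.rhs(ytmp, ftmp);
    for (int i = 0; i < n; ++i)
      k3[i] = ftmp[i] + (R3_C31 * k1[i] + R3_C32 * k2[i]) / h;
    lu_solve(A, n, piv, k3);
    // stage 4: Y4 = y + 2 k1 + k3
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + R3_A41 * k1[i] + R3_A43 * k3[i];
    net.rhs(ytmp, ftmp);
    for (int i = 0; i < n; ++i)
      k4[i] = ftmp[i] + (R3_C41 * k1[i] + R3_C42 * k2[i] + R3_C43 * k3[i]) / h;
    lu_solve(A, n, piv, k4);

    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + R3_M1 * k1[i] + R3_M3 * k3[i] + R3_M4 * k4[i];
      const double sc =
          atol[i] + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = k4[i] / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);

    bool bad = false;
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(ynew[i])) bad = true;

    if (!bad && errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        if (ynew[i] < -100.0 * atol[i])
          stop("species %d dropped below the negativity guard (%.3e) at t = %f",
               i + 1, ynew[i], t);
        y[i] = ynew[i];
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0);
      if (fac > 6.0) fac = 6.0;
      h *= fac;
    } else {
      double fac = bad ? 0.1 : 0.9 * std::pow(errnorm, -1.0 / 3.0);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) stop("step size underflow at t = %f", t);
    }
  }
  h_inout = h;
}

// Integrate one network, recording the state at every entry of `times`.
// [[Rcpp::export(name = ".ode_solve_cpp")]]
NumericMatrix ode_solve_cpp(int type, NumericVector params, NumericVector y0,
                            NumericVector times, double rtol,
                            NumericVector atol, bool clamp_ab = false,
                            int max_steps = 2000000) {
  Network net;
  net.type = type;
  net.clamp_ab = clamp_ab;
  net.n = (type == 0) ? 6 : 4;
  if ((int)params.size() < ((type == 0) ? 7 : 5))
    stop("parameter vector too short for network type");
  for (int i = 0; i < (int)params.size() && i < 8; ++i) net.p[i] = params[i];
  const int n = net.n;
  if ((int)y0.size() != n) stop("y0 has wrong length for network type");
  if ((int)atol.size() != n) stop("atol must have one entry per species");
  const int nt = times.size();
  if (nt < 2) stop("need at least two output times");
  for (int k = 1; k < nt; ++k)
    if (times[k] <= times[k - 1]) stop("output times must be increasing");

  NumericMatrix out(nt, n);
  double y[MAXN], at[MAXN];
  for (int i = 0; i < n; ++i) { y[i] = y0[i]; at[i] = atol[i]; out(0, i) = y0[i]; }
  long steps = 0;
  double h = -1.0;
  for (int k = 1; k < nt; ++k) {
    advance(net, y, times[k - 1], times[k], rtol, at, steps, max_steps, h);
    for (int i = 0; i < n; ++i) out(k, i) = y[i];
  }
  return out;
}

// Batched terminal bound-antibody evaluation for a whole fitting design:
// one row per design point; integrate 0 -> t_split, optionally reset free
// antibody (washout), continue to t_end, and return the total complex count.
// [[Rcpp::export(name = ".design_bound_cpp")]]
NumericVector design_bound_cpp(IntegerVector type, NumericMatrix params,
                               NumericMatrix y0, NumericMatrix atol,
                               double t_split, double t_end, double rtol,
                               bool washout, bool clamp_after,
                               int max_steps = 2000000) {
  const int m = type.size();
  if (params.nrow() != m || y0.nrow() != m || atol.nrow() != m)
    stop("design matrices must have one row per point");
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    Network net;
    net.type = type[r];
    net.clamp_ab = false;
    net.n = (net.type == 0) ? 6 : 4;
    for (int i = 0; i < params.ncol() && i < 8; ++i) net.p[i] = params(r, i);
    double y[MAXN], at[MAXN];
    for (int i = 0; i < net.n; ++i) { y[i] = y0(r, i); at[i] = atol(r, i); }
    long steps = 0;
    double h = -1.0;
    try {
      if (washout && t_split < t_end) {
        advance(net, y, 0.0, t_split, rtol, at, steps, max_steps, h);
        y[0] = 0.0;
        net.clamp_ab = clamp_after;
        h = -1.0;
        advance(net, y, t_split, t_end, rtol, at, steps, max_steps, h);
      } else {
        advance(net, y, 0.0, t_end, rtol, at, steps, max_steps, h);
      }
      out[r] = (net.type == 0) ? (y[3] + y[4] + y[5]) : (y[2] + y[3]);
    } catch (std::exception& e) {
      // per-point failure: report NA, let the caller assign a penalty
      out[r] = NA_REAL;
    }
  }
  return out;
}
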