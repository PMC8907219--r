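#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid activation with exact anchors phi(0)=0, phi(0.5)=0.5, phi(1)=1.
static inline double phi_sig(double omega, double h) {
  double a = std::exp(0.5 * h);
  double e = std::exp(-h * (omega - 0.5));
  return (-a + e) / ((1.0 - a) * (1.0 + e));
}

// Sparse incoming-edge view of the network, built once per integration.
struct Sys {
  int n;
  std::vector<int> aptr, aidx, iptr, iidx;     // CSR over activators/inhibitors
  std::vector<double> aw, iw;                  // matching weights
  std::vector<double> suma, sumb;
};

static Sys build_sys(const NumericMatrix& wact, const NumericMatrix& winh) {
  Sys s;
  s.n = wact.nrow();
  s.suma.assign(s.n, 0.0); s.sumb.assign(s.n, 0.0);
  s.aptr.push_back(0); s.iptr.push_back(0);
  for (int i = 0; i < s.n; ++i) {
    for (int j = 0; j < s.n; ++j) {
      if (wact(i, j) > 0.0) {
        s.aidx.push_back(j); s.aw.push_back(wact(i, j)); s.suma[i] += wact(i, j);
      }
      if (winh(i, j) > 0.0) {
        s.iidx.push_back(j); s.iw.push_back(winh(i, j)); s.sumb[i] += winh(i, j);
      }
    }
    s.aptr.push_back((int)s.aidx.size());
    s.iptr.push_back((int)s.iidx.size());
  }
  return s;
}

// dx/dt of the clamped system.
// kind: 0 = regulated, 1 = clamped, 2 = source (no regulators).
static void deriv(const Sys& s, const NumericVector& hh, const NumericVector& gam,
                  const IntegerVector& kind, bool source_decay,
                  const std::vector<double>& x, std::vector<double>& dx) {
  for (int i = 0; i < s.n; ++i) {
    if (kind[i] == 1) { dx[i] = 0.0; continue; }
    if (kind[i] == 2) { dx[i] = source_decay ? -gam[i] * x[i] : 0.0; continue; }
    double omega;
    bool hasA = s.suma[i] > 0.0, hasI = s.sumb[i] > 0.0;
    double A = 0.0, I = 0.0;
    if (hasA) {
      double sa = 0.0;
      for (int k = s.aptr[i]; k < s.aptr[i + 1]; ++k) sa += s.aw[k] * x[s.aidx[k]];
      A = (1.0 + s.suma[i]) / s.suma[i] * (sa / (1.0 + sa));
    }
    if (hasI) {
      double sb = 0.0;
      for (int k = s.iptr[i]; k < s.iptr[i + 1]; ++k) sb += s.iw[k] * x[s.iidx[k]];
      I = (1.0 + s.sumb[i]) / s.sumb[i] * (sb / (1.0 + sb));
    }
    if (hasA && hasI) omega = A * (1.0 - I);
    else if (hasA)    omega = A;
    else              omega = 1.0 - I;
    if (omega < 0.0) omega = 0.0; else if (omega > 1.0) omega = 1.0;
    dx[i] = phi_sig(omega, hh[i]) - gam[i] * x[i];
  }
}

// Fixed-step classical Runge-Kutta (order 4) to steady state.
// Terminates when max|dx/dt| <= tol (converged) or t >= t_max.
// Clamped nodes are pinned to clamp_value every step; all states are clipped
// to [0,1] after each step (excursions beyond clip_tol raise an error).
// [[Rcpp::export]]
List rk4_steady_cpp(NumericMatrix wact, NumericMatrix winh,
                    NumericVector h, NumericVector gamma_,
                    IntegerVector kind, NumericVector clamp_value,
                    bool source_decay, NumericVector x0,
                    double step, double tol, double t_max, double clip_tol) {
  Sys sys = build_sys(wact, winh);
  int n = sys.n;
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), xt(n);
  for (int i = 0; i < n; ++i) x[i] = (kind[i] == 1) ? clamp_value[i] : x0[i];

  double t = 0.0;
  bool converged = false;
  double resid = R_PosInf;
  long max_steps = (long)std::ceil(t_max / step) + 1;

  for (long s = 0; s < max_steps; ++s) {
    deriv(sys, h, gamma_, kind, source_decay, x, k1);
    resid = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = std::fabs(k1[i]);
      if (a > resid) resid = a;
    }
    if (resid <= tol) { converged = true; break; }
    if (t >= t_max) break;
    double dt = std::min(step, t_max - t);

    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    deriv(sys, h, gamma_, kind, source_decay, xt, k2);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    deriv(sys, h, gamma_, kind, source_decay, xt, k3);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * k3[i];
    deriv(sys, h, gamma_, kind, source_decay, xt, k4);

    for (int i = 0; i < n; ++i) {
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(x[i]))
        stop("integration error: non-finite state at node index %d (t = %f)", i + 1, t);
      if (x[i] < 0.0) {
        if (x[i] < -clip_tol)
          stop("integration error: state excursion below 0 at node index %d", i + 1);
        x[i] = 0.0;
      } else if (x[i] > 1.0) {
        if (x[i] > 1.0 + clip_tol)
          stop("integration error: state excursion above 1 at node index %d", i + 1);
        x[i] = 1.0;
      }
      if (kind[i] == 1) x[i] = clamp_value[i];
    }
    t += dt;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["converged"] = converged,
                      _["residual"] = resid,
                      _["t_end"] = t);
}

// Single derivative evaluation (used by the R layer and the adaptive solver).
// [[Rcpp::export]]
NumericVector deriv_cpp(NumericMatrix wact, NumericMatrix winh,
                        NumericVector h, NumericVector gamma_,
                        IntegerVector kind, bool source_decay,
                        NumericVector x) {
  Sys sys = build_sys(wact, winh);
  std::vector<double> xx(x.begin(), x.end()), dx(sys.n);
  deriv(sys, h, gamma_, kind, source_decay, xx, dx);
  return NumericVector(dx.begin(), dx.end());
}
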