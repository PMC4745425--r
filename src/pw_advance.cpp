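#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional area-averaged arterial flow:
//   dA/dt + dQ/dx = 0
//   dQ/dt + d(Q^2/A)/dx = -(A/rho) dp/dx - 8 pi nu Q/A
// closed by the elastic tube law p = beta(x) (sqrt(A) - sqrt(Aref)).
// MacCormack predictor (forward) / corrector (backward) on cell averages
// with one ghost cell per end set by characteristic extrapolation:
// Riemann invariants u +/- 4c, c^2 = beta sqrt(A) / (2 rho).
// The continuity update is in exact flux form (ghost-cell MacCormack), so
// the accumulated boundary fluxes v_in/v_out balance the stored volume to
// round-off; this is what the per-cycle volume audit checks.
//
// Inlet types: 0 = non-reflecting (forward invariant held at rest),
//              1 = prescribed mean velocity V(t) (harmonic series).
// The outlet is always non-reflecting (backward invariant held at rest),
// the 1D counterpart of a zero-normal-traction outflow.

static inline double wavec(double beta, double A, double rho) {
  return std::sqrt(beta * std::sqrt(A) / (2.0 * rho));
}

// ghost area from its wave speed, relative to the adjacent interior cell:
// A = (2 rho c^2 / beta)^2 implies Ag = Ai (cg/ci)^4, which is exact (no
// round-trip through sqrt) when cg == ci, so a resting vessel stays at rest
// to the last bit
static inline double area_from_c(double cg, double ci, double Ai) {
  double r = cg / ci;
  return Ai * r * r * r * r;
}

// V(t) = ar[0] + sum_k ar[k] cos(k w t) - ai[k] sin(k w t)
static inline double inlet_velocity(double t, double omega,
                                    const NumericVector& ar,
                                    const NumericVector& ai) {
  double v = ar[0];
  for (int k = 1; k < ar.size(); ++k)
    v += ar[k] * std::cos(k * omega * t) - ai[k] * std::sin(k * omega * t);
  return v;
}

// ghost state at one end; interior cell (Ai, Qi) is the adjacent real cell
static inline void ghost_state(int type, double t, double omega,
                               const NumericVector& ar, const NumericVector& ai,
                               double beta, double Aref, double rho,
                               double Ai, double Qi, bool left,
                               double& Ag, double& Qg) {
  double ui = Qi / Ai;
  double ci = wavec(beta, Ai, rho);
  double cref = wavec(beta, Aref, rho);
  double ug, cg;
  if (left) {
    if (type == 1) {            // prescribed velocity, backward invariant
      ug = inlet_velocity(t, omega, ar, ai);
      cg = ci + (ug - ui) / 4.0;
    } else {                    // non-reflecting: forward invariant at rest
      ug = (4.0 * cref + ui - 4.0 * ci) / 2.0;
      cg = (4.0 * cref - ui + 4.0 * ci) / 8.0;
    }
  } else {                      // non-reflecting: backward invariant at rest
    ug = (ui + 4.0 * ci - 4.0 * cref) / 2.0;
    cg = (ui + 4.0 * ci + 4.0 * cref) / 8.0;
  }
  Ag = area_from_c(cg, ci, Ai);
  Qg = Ag * ug;
}

// [[Rcpp::export(name = ".pw_advance_cpp")]]
List pw_advance_cpp(NumericVector A_in, NumericVector Q_in, NumericVector beta,
                    double Aref, double rho, double mu,
                    double dx, double dt, int nsteps, double t0,
                    int inlet_type, double omega,
                    NumericVector ar, NumericVector ai,
                    double cfl_limit) {
  const int N = A_in.size();
  if (Q_in.size() != N || beta.size() != N)
    stop("A, Q and beta must have equal length");
  const double nu8pi = 8.0 * M_PI * mu / rho;
  const double lam = dt / dx;

  // working arrays with ghost cells at 0 and N+1
  std::vector<double> A(N + 2), Q(N + 2), As(N + 2), Qs(N + 2),
      p(N + 2), ps(N + 2), b(N + 2);
  for (int i = 0; i < N; ++i) { A[i + 1] = A_in[i]; Q[i + 1] = Q_in[i]; b[i + 1] = beta[i]; }
  b[0] = beta[0]; b[N + 1] = beta[N - 1];

  double t = t0, v_in = 0.0, v_out = 0.0, max_cfl = 0.0;
  const double sqAref = std::sqrt(Aref);

  for (int s = 0; s < nsteps; ++s) {
    // CFL / positivity audit on the current state
    double smax = 0.0;
    for (int i = 1; i <= N; ++i) {
      if (!(A[i] > 0.0) || !std::isfinite(A[i]) || !std::isfinite(Q[i]))
        return List::create(_["ok"] = false,
                            _["message"] = "negative or non-finite area/flow",
                            _["t"] = t);
      double sp = std::fabs(Q[i] / A[i]) + wavec(b[i], A[i], rho);
      if (sp > smax) smax = sp;
    }
    double cfl = smax * lam;
    if (cfl > max_cfl) max_cfl = cfl;
    if (cfl > cfl_limit)
      return List::create(_["ok"] = false,
                          _["message"] = "CFL limit exceeded",
                          _["t"] = t, _["cfl"] = cfl);

    ghost_state(inlet_type, t, omega, ar, ai, b[0], Aref, rho,
                A[1], Q[1], true, A[0], Q[0]);
    ghost_state(0, t, omega, ar, ai, b[N + 1], Aref, rho,
                A[N], Q[N], false, A[N + 1], Q[N + 1]);
    for (int i = 0; i <= N + 1; ++i)
      p[i] = b[i] * (std::sqrt(A[i]) - sqAref);

    // predictor: forward differences
    for (int i = 1; i <= N; ++i) {
      double fQp = Q[i + 1] * Q[i + 1] / A[i + 1];
      double fQi = Q[i] * Q[i] / A[i];
      As[i] = A[i] - lam * (Q[i + 1] - Q[i]);
      Qs[i] = Q[i] - lam * (fQp - fQi)
              - lam * (A[i] / rho) * (p[i + 1] - p[i])
              - dt * nu8pi * Q[i] / A[i];
    }
    for (int i = 1; i <= N; ++i)
      if (!(As[i] > 0.0))
        return List::create(_["ok"] = false,
                            _["message"] = "negative area in predictor",
                            _["t"] = t);

    ghost_state(inlet_type, t + dt, omega, ar, ai, b[0], Aref, rho,
                As[1], Qs[1], true, As[0], Qs[0]);
    ghost_state(0, t + dt, omega, ar, ai, b[N + 1], Aref, rho,
                As[N], Qs[N], false, As[N + 1], Qs[N + 1]);
    for (int i = 0; i <= N + 1; ++i)
      ps[i] = b[i] * (std::sqrt(As[i]) - sqAref);

    // boundary fluxes of the equivalent conservative form
    v_in  += dt * 0.5 * (Q[1] + Qs[0]);
    v_out += dt * 0.5 * (Q[N + 1] + Qs[N]);

    // corrector: backward differences on the predicted state
    // (only As/Qs/ps are read at i-1, so overwriting A/Q in place is safe)
    for (int i = 1; i <= N; ++i) {
      double fQs = Qs[i] * Qs[i] / As[i];
      double fQm = Qs[i - 1] * Qs[i - 1] / As[i - 1];
      double Anew = 0.5 * (A[i] + As[i]) - 0.5 * lam * (Qs[i] - Qs[i - 1]);
      double Qnew = 0.5 * (Q[i] + Qs[i]) - 0.5 * lam * (fQs - fQm)
                    - 0.5 * lam * (As[i] / rho) * (ps[i] - ps[i - 1])
                    - 0.5 * dt * nu8pi * Qs[i] / As[i];
      A[i] = Anew; Q[i] = Qnew;
    }
    t = t0 + (s + 1) * dt;
  }

  NumericVector A_out(N), Q_out(N);
  for (int i = 0; i < N; ++i) { A_out[i] = A[i + 1]; Q_out[i] = Q[i + 1]; }
  return List::create(_["ok"] = true, _["A"] = A_out, _["Q"] = Q_out,
                      _["t"] = t, _["v_in"] = v_in, _["v_out"] = v_out,
                      _["max_cfl"] = max_cfl);
}
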