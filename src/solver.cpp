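// 1D pulse propagation in a compliant tube with a nonlinear tube law and a
// three-element Windkessel outlet.
//
// Governing equations (x in [0, L], t > 0):
//   dA/dt + dQ/dx = 0
//   dQ/dt + d(Q^2/A)/dx + (A/rho) dP/dx = -Kf (mu/rho) (Q/A),   P = law(A)
// For an x-independent law the pressure term is the gradient of the
// celerity potential B(A) = int c^2(A) dA, giving the conservative flux
// F = (Q, Q^2/A + B(A)) with friction as the only source term.
//
// Scheme: two-step Richtmyer predictor-corrector (second order) on a
// uniform grid; characteristic-based boundary closure (prescribed inflow at
// the inlet, Windkessel coupling at the outlet). The Windkessel capacitor
// is advanced with the exact integrating-factor step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Law {
  int kind; // 0 constant_pwv, 1 linear_pwv, 2 exponential
  double A_ref, P_ref, p1, p2, rho;

  double P(double A) const {
    switch (kind) {
    case 0:
      return P_ref + rho * p1 * p1 * std::log(A / A_ref);
    case 1: {
      double alpha = p1 - p2 * A_ref;
      return P_ref + rho * (alpha * alpha * std::log(A / A_ref) +
                            2.0 * alpha * p2 * (A - A_ref) +
                            0.5 * p2 * p2 * (A * A - A_ref * A_ref));
    }
    default:
      return P_ref + p1 * (std::exp(p2 * (A / A_ref - 1.0)) - 1.0);
    }
  }

  // squared wave speed c^2(A) = (A/rho) dP/dA
  double c2(double A) const {
    switch (kind) {
    case 0:
      return p1 * p1;
    case 1: {
      double c = p1 + p2 * (A - A_ref);
      return c * c;
    }
    default:
      return (A / rho) * (p1 * p2 / A_ref) * std::exp(p2 * (A / A_ref - 1.0));
    }
  }

  // celerity potential B(A) = int c^2 dA (additive constant irrelevant)
  double B(double A) const {
    switch (kind) {
    case 0:
      return p1 * p1 * A;
    case 1: {
      if (std::fabs(p2) < 1e-300) return p1 * p1 * A;
      double c = p1 + p2 * (A - A_ref);
      return c * c * c / (3.0 * p2);
    }
    default: {
      double u = A / A_ref;
      return (p1 * A_ref / rho) * std::exp(p2 * (u - 1.0)) * (u - 1.0 / p2);
    }
    }
  }
};

// Riemann-invariant integral phi(A) = int c(a)/a da, tabulated on a uniform
// area grid (computed in R); linear interpolation.
struct PhiTable {
  const double *A, *phi;
  int n;
  double A0, dA;

  double eval(double Av) const {
    double x = (Av - A0) / dA;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > n - 2) i = n - 2;
    double w = x - i;
    return phi[i] * (1.0 - w) + phi[i + 1] * w;
  }
};

} // namespace

// [[Rcpp::export]]
List solve_pulse_1d_cpp(int n_nodes, double dx, double dt, int n_steps, int stride,
                        int law_kind, double A_ref, double P_ref,
                        double par1, double par2, double rho,
                        double Kf, double mu,
                        NumericVector Qin,
                        double Rp, double Rd, double Cc, double Pc0,
                        double A_init, double Q_init,
                        NumericVector A_tab, NumericVector phi_tab,
                        int i1, double w1, int i2, double w2) {
  const Law law{law_kind, A_ref, P_ref, par1, par2, rho};
  PhiTable tab{A_tab.begin(), phi_tab.begin(), (int)A_tab.size(),
               A_tab[0], A_tab[1] - A_tab[0]};
  const double Alo = A_tab[0], Ahi = A_tab[A_tab.size() - 1];

  const int n = n_nodes;
  std::vector<double> A(n, A_init), Q(n, Q_init);
  std::vector<double> F2(n), Ah(n - 1), Qh(n - 1), F2h(n - 1), Sh(n - 1);
  double Pc = Pc0;

  const int n_rec = n_steps / stride + 1; // includes the final state
  NumericVector rP1(n_rec), rA1(n_rec), rQ1(n_rec);
  NumericVector rP2(n_rec), rA2(n_rec), rQ2(n_rec);
  NumericVector rQin(n_rec), rQout(n_rec), rVol(n_rec);

  const double fcoef = (rho > 0.0) ? Kf * mu / rho : 0.0;
  std::string err;
  int err_step = -1;

  auto record = [&](int r) {
    double a1 = A[i1] * (1.0 - w1) + A[i1 + 1] * w1;
    double q1 = Q[i1] * (1.0 - w1) + Q[i1 + 1] * w1;
    double p1v = law.P(A[i1]) * (1.0 - w1) + law.P(A[i1 + 1]) * w1;
    double a2 = A[i2] * (1.0 - w2) + A[i2 + 1] * w2;
    double q2 = Q[i2] * (1.0 - w2) + Q[i2 + 1] * w2;
    double p2v = law.P(A[i2]) * (1.0 - w2) + law.P(A[i2 + 1]) * w2;
    rP1[r] = p1v; rA1[r] = a1; rQ1[r] = q1;
    rP2[r] = p2v; rA2[r] = a2; rQ2[r] = q2;
    rQin[r] = Q[0]; rQout[r] = Q[n - 1];
    double vol = 0.0;
    for (int j = 0; j < n; ++j) vol += A[j];
    rVol[r] = dx * (vol - 0.5 * (A[0] + A[n - 1]));
  };

  for (int s = 0; s < n_steps; ++s) {
    if (s % stride == 0) record(s / stride);

    // stability / range monitoring
    double smax = 0.0;
    bool range_ok = true;
    int bad_j = 0;
    for (int j = 0; j < n; ++j) {
      if (A[j] < Alo || A[j] > Ahi || !std::isfinite(A[j]) || !std::isfinite(Q[j])) {
        range_ok = false; bad_j = j; break;
      }
      double u = Q[j] / A[j];
      double c = std::sqrt(law.c2(A[j]));
      double sp = std::fabs(u) + c;
      if (sp > smax) smax = sp;
    }
    if (!range_ok) {
      err = "area left the tube law's working range at node " +
            std::to_string(bad_j) + ", step " + std::to_string(s);
      err_step = s;
      break;
    }
    if (dt * smax / dx > 1.0) {
      err = "CFL violation at step " + std::to_string(s) +
            " (dt*smax/dx = " + std::to_string(dt * smax / dx) + ")";
      err_step = s;
      break;
    }

    for (int j = 0; j < n; ++j) F2[j] = Q[j] * Q[j] / A[j] + law.B(A[j]);

    // predictor: half-step values at j+1/2
    const double r2 = 0.5 * dt / dx;
    for (int j = 0; j < n - 1; ++j) {
      Ah[j] = 0.5 * (A[j] + A[j + 1]) - r2 * (Q[j + 1] - Q[j]);
      double Sj = -fcoef * Q[j] / A[j];
      double Sj1 = -fcoef * Q[j + 1] / A[j + 1];
      Qh[j] = 0.5 * (Q[j] + Q[j + 1]) - r2 * (F2[j + 1] - F2[j]) +
              0.25 * dt * (Sj + Sj1);
      if (Ah[j] < Alo || Ah[j] > Ahi) {
        err = "area left the working range (predictor) at interface " +
              std::to_string(j) + ", step " + std::to_string(s);
        err_step = s;
        break;
      }
      F2h[j] = Qh[j] * Qh[j] / Ah[j] + law.B(Ah[j]);
      Sh[j] = -fcoef * Qh[j] / Ah[j];
    }
    if (err_step >= 0) break;

    // characteristic feet from the old state at the boundaries
    double u0 = Q[0] / A[0], c0v = std::sqrt(law.c2(A[0]));
    double xf_in = (c0v - u0) * dt / dx; // distance (in cells) into the domain
    if (xf_in < 0.0) xf_in = 0.0;
    if (xf_in > 1.0) xf_in = 1.0;
    double Af_in = A[0] * (1.0 - xf_in) + A[1] * xf_in;
    double Qf_in = Q[0] * (1.0 - xf_in) + Q[1] * xf_in;
    double W2 = Qf_in / Af_in - tab.eval(Af_in);

    double uN = Q[n - 1] / A[n - 1], cN = std::sqrt(law.c2(A[n - 1]));
    double xf_out = (uN + cN) * dt / dx;
    if (xf_out < 0.0) xf_out = 0.0;
    if (xf_out > 1.0) xf_out = 1.0;
    double Af_out = A[n - 1] * (1.0 - xf_out) + A[n - 2] * xf_out;
    double Qf_out = Q[n - 1] * (1.0 - xf_out) + Q[n - 2] * xf_out;
    double W1 = Qf_out / Af_out + tab.eval(Af_out);

    // corrector: interior nodes at the new time level
    const double r1 = dt / dx;
    for (int j = 1; j < n - 1; ++j) {
      A[j] -= r1 * (Qh[j] - Qh[j - 1]);
      Q[j] -= r1 * (F2h[j] - F2h[j - 1]);
      Q[j] += 0.5 * dt * (Sh[j] + Sh[j - 1]);
    }

    // inlet: prescribed Q, area from the outgoing characteristic
    double Qbc = Qin[s + 1];
    {
      double lo = Alo, hi = Ahi;
      // g(A) = Qbc/A - phi(A) - W2 is strictly decreasing in A
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        double g = Qbc / mid - tab.eval(mid) - W2;
        if (g > 0.0) lo = mid; else hi = mid;
      }
      A[0] = 0.5 * (lo + hi);
      Q[0] = Qbc;
    }

    // outlet: Windkessel coupling with the incoming characteristic
    {
      const double edec = std::exp(-dt / (Rd * Cc));
      double lo = Alo, hi = Ahi;
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        double Qo = mid * (W1 - tab.eval(mid));
        double Pc_next = Qo * Rd + (Pc - Qo * Rd) * edec;
        double f = law.P(mid) - Rp * Qo - Pc_next;
        if (f < 0.0) lo = mid; else hi = mid;
      }
      double Aout = 0.5 * (lo + hi);
      double Qo = Aout * (W1 - tab.eval(Aout));
      Pc = Qo * Rd + (Pc - Qo * Rd) * edec;
      A[n - 1] = Aout;
      Q[n - 1] = Qo;
    }
  }

  if (err_step < 0) record(n_steps / stride);

  return List::create(
    _["P1"] = rP1, _["A1"] = rA1, _["Q1"] = rQ1,
    _["P2"] = rP2, _["A2"] = rA2, _["Q2"] = rQ2,
    _["Qin"] = rQin, _["Qout"] = rQout, _["Vol"] = rVol,
    _["Pc"] = Pc, _["error"] = err, _["error_step"] = err_step);
}
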