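#include <Rcpp.h>
using namespace Rcpp;

// Parameter slot order shared with the R side (see .smad_param_names):
// Lambda zeta lam tau alpha beta chi upsilon sigma omega psi Phi rho phi
static inline void smad_deriv(const double* y, const double* p, double* dy) {
  const double Lambda = p[0], zeta = p[1], lam = p[2], tau = p[3],
               alpha = p[4], beta = p[5], chi = p[6], upsilon = p[7],
               sigma = p[8], omega = p[9], psi = p[10], Phi = p[11],
               rho = p[12], phi = p[13];
  const double S = y[0], E = y[1], I1 = y[2], I2 = y[3], R = y[4], Q = y[5];
  const double force = phi * chi * I1 * S;  // peer-pressure incidence term
  dy[0] = Lambda + zeta * lam * R - force - (beta + tau) * S;
  dy[1] = force - (sigma + tau) * E;
  dy[2] = Phi * sigma * E - (tau + psi + alpha) * I1;
  dy[3] = alpha * I1 + psi * (1.0 - omega) * I1 - (upsilon + rho + tau) * I2;
  dy[4] = (1.0 - Phi) * sigma * E + upsilon * I2 + psi * omega * I1
          - (tau + lam) * R;
  dy[5] = beta * S + (1.0 - zeta) * lam * R - tau * Q;
}

static inline void rk4_once(const double* y, const double* p, double h,
                            double* out) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  smad_deriv(y, p, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  smad_deriv(tmp, p, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  smad_deriv(tmp, p, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + h * k3[i];
  smad_deriv(tmp, p, k4);
  for (int i = 0; i < 6; ++i)
    out[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector state, NumericVector params) {
  NumericVector out(6);
  smad_deriv(REAL(state), REAL(params), REAL(out));
  return out;
}

// [[Rcpp::export(name = ".rk4_step_cpp")]]
NumericVector rk4_step_cpp(NumericVector state, NumericVector params,
                           double h) {
  NumericVector out(6);
  rk4_once(REAL(state), REAL(params), h, REAL(out));
  return out;
}

// Integrate n_steps of size h from y0, storing the initial state and every
// thin-th step thereafter (plus the final step regardless).  Returns the
// stored states row-wise; attributes carry the minimum component seen over
// ALL steps (for positivity auditing) and the maximum total population.
// [[Rcpp::export(name = ".rk4_integrate_cpp")]]
List rk4_integrate_cpp(NumericVector state0, NumericVector params, double h,
                       int n_steps, int thin) {
  if (thin < 1) stop("`thin` must be >= 1");
  int n_saved = n_steps / thin + ((n_steps % thin) ? 2 : 1);
  NumericMatrix states(n_saved, 6);
  NumericVector times(n_saved);
  double y[6];
  for (int i = 0; i < 6; ++i) y[i] = state0[i];

  double min_comp = R_PosInf, max_n = R_NegInf;
  int row = 0;
  states(row, _) = state0;
  times[row++] = 0.0;

  double ynext[6];
  for (int s = 1; s <= n_steps; ++s) {
    rk4_once(y, REAL(params), h, ynext);
    double n_tot = 0.0;
    for (int i = 0; i < 6; ++i) {
      y[i] = ynext[i];
      if (y[i] < min_comp) min_comp = y[i];
      n_tot += y[i];
    }
    if (n_tot > max_n) max_n = n_tot;
    if (!R_finite(n_tot))
      stop("non-finite state at t = %g; integration aborted", s * h);
    if (s % thin == 0 || s == n_steps) {
      for (int i = 0; i < 6; ++i) states(row, i) = y[i];
      times[row++] = s * h;
    }
  }
  if (row < n_saved) {  // n_steps divisible by thin: final row already stored
    states = states(Range(0, row - 1), _);
    times = times[Range(0, row - 1)];
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["min_component"] = min_comp,
                      _["max_population"] = max_n);
}
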