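#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler / RK4 integrators for the phage-bacteria delay models.
// All three cores share the kinetic rate laws:
//   r(t)   = r_max * (1 - (U + I)/K_C)              (logistic growth)
//   phi(t) = phi_max * P_50 / (P_50 + P)            (saturable adsorption)
// History before t = 0 carries phi*U*P = 0, so convolutions simply skip
// negative indices. States are floored at 0 after each step; the number of
// floored components is reported so callers can audit it.

static inline void check_finite(double U, double I, double P, int n) {
  if (!std::isfinite(U) || !std::isfinite(I) || !std::isfinite(P)) {
    stop("integration produced a non-finite state at step %d", n);
  }
}

// Distributed-delay (DDDE) core. koff are integer delay offsets (>= 1,
// ascending); wI = exp(-delta_I * tau_k) * w_k weights the I-equation lysis
// outflow, wP = beta_0(tau_k) * exp(-delta_I * tau_k) * w_k the P-equation
// source. Both convolve the stored history H(s) = phi(s) U(s) P(s).
// [[Rcpp::export]]
List cpp_sim_ddde(double U0, double P0, double dt, int n_steps,
                  double r_max, double K_C, double phi_max, double P_50,
                  double dU, double dI, double dP,
                  IntegerVector koff, NumericVector wI, NumericVector wP,
                  bool rk4) {
  const int m = koff.size();
  NumericVector U(n_steps + 1), I(n_steps + 1), P(n_steps + 1);
  std::vector<double> H(n_steps + 1, 0.0);
  U[0] = U0; I[0] = 0.0; P[0] = P0;
  int n_floored = 0;
  int jlim = 0;  // offsets already inside the simulated history
  double convI_prev = 0.0, convP_prev = 0.0;  // rk4: convolutions at t_n

  for (int n = 0; n < n_steps; ++n) {
    double phin = phi_max * P_50 / (P_50 + P[n]);
    H[n] = phin * U[n] * P[n];

    double Un, In, Pn;
    if (!rk4) {
      while (jlim < m && koff[jlim] <= n) ++jlim;
      double convI = 0.0, convP = 0.0;
      for (int j = 0; j < jlim; ++j) {
        double h = H[n - koff[j]];
        convI += wI[j] * h;
        convP += wP[j] * h;
      }
      double r = r_max * (1.0 - (U[n] + I[n]) / K_C);
      Un = U[n] + dt * (r * U[n] - H[n] - dU * U[n]);
      In = I[n] + dt * (H[n] - convI - dI * I[n]);
      Pn = P[n] + dt * (convP - phin * (U[n] + I[n]) * P[n] - dP * P[n]);
    } else {
      // classic RK4. The delayed terms depend only on stored history, not on
      // stage states: with all offsets >= 1 the convolutions at stage times
      // t_n and t_n + dt use known history directly, and the linearly
      // interpolated half-step convolution is exactly their average. One new
      // convolution per step (at t_n + dt); the one at t_n is carried over.
      while (jlim < m && koff[jlim] <= n + 1) ++jlim;
      double cIn = 0.0, cPn = 0.0;   // convolutions at t_n + dt
      for (int j = 0; j < jlim; ++j) {
        double h = H[n + 1 - koff[j]];
        cIn += wI[j] * h;
        cPn += wP[j] * h;
      }
      double cI[4] = {convI_prev, 0.5 * (convI_prev + cIn),
                      0.5 * (convI_prev + cIn), cIn};
      double cP[4] = {convP_prev, 0.5 * (convP_prev + cPn),
                      0.5 * (convP_prev + cPn), cPn};
      convI_prev = cIn; convP_prev = cPn;

      double kU[4], kI[4], kP[4];
      const double c[4] = {0.0, 0.5, 0.5, 1.0};
      for (int s = 0; s < 4; ++s) {
        double u = U[n], i_ = I[n], p = P[n];
        if (s > 0) {
          u += dt * c[s] * kU[s - 1];
          i_ += dt * c[s] * kI[s - 1];
          p += dt * c[s] * kP[s - 1];
        }
        if (u < 0) u = 0; if (i_ < 0) i_ = 0; if (p < 0) p = 0;
        double phi = phi_max * P_50 / (P_50 + p);
        double h = phi * u * p;
        double r = r_max * (1.0 - (u + i_) / K_C);
        kU[s] = r * u - h - dU * u;
        kI[s] = h - cI[s] - dI * i_;
        kP[s] = cP[s] - phi * (u + i_) * p - dP * p;
      }
      Un = U[n] + dt / 6.0 * (kU[0] + 2 * kU[1] + 2 * kU[2] + kU[3]);
      In = I[n] + dt / 6.0 * (kI[0] + 2 * kI[1] + 2 * kI[2] + kI[3]);
      Pn = P[n] + dt / 6.0 * (kP[0] + 2 * kP[1] + 2 * kP[2] + kP[3]);
    }

    check_finite(Un, In, Pn, n + 1);
    if (Un < 0) { Un = 0; ++n_floored; }
    if (In < 0) { In = 0; ++n_floored; }
    if (Pn < 0) { Pn = 0; ++n_floored; }
    U[n + 1] = Un; I[n + 1] = In; P[n + 1] = Pn;
  }
  return List::create(_["U"] = U, _["I"] = I, _["P"] = P,
                      _["n_floored"] = n_floored);
}

// Fixed-delay (DDE) core: single latent period tau = k_delay * dt, burst size
// beta, survival factor surv = exp(-delta_I * tau). Kept as an independent
// implementation (direct delayed indexing, no kernel loop) so the point-mass
// kernel collapse of the distributed model can be checked against it.
// [[Rcpp::export]]
List cpp_sim_dde(double U0, double P0, double dt, int n_steps,
                 double r_max, double K_C, double phi_max, double P_50,
                 double dU, double dI, double dP,
                 int k_delay, double beta, double surv, bool rk4) {
  NumericVector U(n_steps + 1), I(n_steps + 1), P(n_steps + 1);
  std::vector<double> H(n_steps + 1, 0.0);
  U[0] = U0; I[0] = 0.0; P[0] = P0;
  int n_floored = 0;

  for (int n = 0; n < n_steps; ++n) {
    double phin = phi_max * P_50 / (P_50 + P[n]);
    H[n] = phin * U[n] * P[n];

    double Un, In, Pn;
    if (!rk4) {
      double hdel = (n >= k_delay) ? H[n - k_delay] : 0.0;
      double r = r_max * (1.0 - (U[n] + I[n]) / K_C);
      Un = U[n] + dt * (r * U[n] - H[n] - dU * U[n]);
      In = I[n] + dt * (H[n] - surv * hdel - dI * I[n]);
      Pn = P[n] + dt * (beta * surv * hdel - phin * (U[n] + I[n]) * P[n] - dP * P[n]);
    } else {
      // delayed history at stage times: known directly at t_n and t_n + dt
      // (offset >= 1), half-step value by linear interpolation = average
      double hprev = 0.0, hnext = 0.0;
      if (k_delay >= 1) {
        if (n >= k_delay) hprev = H[n - k_delay];
        if (n + 1 >= k_delay) hnext = H[n + 1 - k_delay];
      }
      double hd[4] = {hprev, 0.5 * (hprev + hnext), 0.5 * (hprev + hnext),
                      hnext};
      double kU[4], kI[4], kP[4];
      const double c[4] = {0.0, 0.5, 0.5, 1.0};
      for (int s = 0; s < 4; ++s) {
        double u = U[n], i_ = I[n], p = P[n];
        if (s > 0) {
          u += dt * c[s] * kU[s - 1];
          i_ += dt * c[s] * kI[s - 1];
          p += dt * c[s] * kP[s - 1];
        }
        if (u < 0) u = 0; if (i_ < 0) i_ = 0; if (p < 0) p = 0;
        double phi = phi_max * P_50 / (P_50 + p);
        double h = phi * u * p;
        double hdel = (k_delay == 0) ? h : hd[s];
        double r = r_max * (1.0 - (u + i_) / K_C);
        kU[s] = r * u - h - dU * u;
        kI[s] = h - surv * hdel - dI * i_;
        kP[s] = beta * surv * hdel - phi * (u + i_) * p - dP * p;
      }
      Un = U[n] + dt / 6.0 * (kU[0] + 2 * kU[1] + 2 * kU[2] + kU[3]);
      In = I[n] + dt / 6.0 * (kI[0] + 2 * kI[1] + 2 * kI[2] + kI[3]);
      Pn = P[n] + dt / 6.0 * (kP[0] + 2 * kP[1] + 2 * kP[2] + kP[3]);
    }

    check_finite(Un, In, Pn, n + 1);
    if (Un < 0) { Un = 0; ++n_floored; }
    if (In < 0) { In = 0; ++n_floored; }
    if (Pn < 0) { Pn = 0; ++n_floored; }
    U[n + 1] = Un; I[n + 1] = In; P[n + 1] = Pn;
  }
  return List::create(_["U"] = U, _["I"] = I, _["P"] = P,
                      _["n_floored"] = n_floored);
}

// Transit-compartment core: infection inflow enters I_1, cells transit through
// N compartments at rate k_tr, each decaying at delta_I; the outflow of the
// last compartment releases beta_0_mean phage per cell. Reported I(t) is the
// sum over compartments; adsorption removes phage on U + sum(I_j).
// [[Rcpp::export]]
List cpp_sim_tc(double U0, double P0, double dt, int n_steps,
                double r_max, double K_C, double phi_max, double P_50,
                double dU, double dI, double dP,
                int N, double k_tr, double beta0mean) {
  NumericVector U(n_steps + 1), I(n_steps + 1), P(n_steps + 1);
  std::vector<double> x(N, 0.0), xn(N);
  U[0] = U0; I[0] = 0.0; P[0] = P0;
  double Ucur = U0, Pcur = P0;
  int n_floored = 0;

  for (int n = 0; n < n_steps; ++n) {
    double Isum = 0.0;
    for (int j = 0; j < N; ++j) Isum += x[j];
    double phi = phi_max * P_50 / (P_50 + Pcur);
    double inflow = phi * Ucur * Pcur;
    double r = r_max * (1.0 - (Ucur + Isum) / K_C);

    double Un = Ucur + dt * (r * Ucur - inflow - dU * Ucur);
    xn[0] = x[0] + dt * (inflow - (k_tr + dI) * x[0]);
    for (int j = 1; j < N; ++j) {
      xn[j] = x[j] + dt * (k_tr * x[j - 1] - (k_tr + dI) * x[j]);
    }
    double Pn = Pcur + dt * (beta0mean * k_tr * x[N - 1]
                             - phi * (Ucur + Isum) * Pcur - dP * Pcur);

    if (!std::isfinite(Un) || !std::isfinite(Pn)) {
      stop("integration produced a non-finite state at step %d", n + 1);
    }
    if (Un < 0) { Un = 0; ++n_floored; }
    if (Pn < 0) { Pn = 0; ++n_floored; }
    double Isumn = 0.0;
    for (int j = 0; j < N; ++j) {
      if (!std::isfinite(xn[j])) {
        stop("integration produced a non-finite state at step %d", n + 1);
      }
      if (xn[j] < 0) { xn[j] = 0; ++n_floored; }
      Isumn += xn[j];
    }
    Ucur = Un; Pcur = Pn; std::swap(x, xn);
    U[n + 1] = Un; I[n + 1] = Isumn; P[n + 1] = Pn;
  }
  return List::create(_["U"] = U, _["I"] = I, _["P"] = P,
                      _["n_floored"] = n_floored);
}
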