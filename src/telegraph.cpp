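// Core numerics for the telegraph-switch reporter model:
//  - deterministic mean path (RK4, split at the switch time)
//  - chemical-Langevin Euler-Maruyama simulation (reflected at zero)
//  - continuous-discrete Gaussian filter log-likelihood
//  - one Metropolis sweep over all cells (log-scale random walks,
//    reflected window proposal for the switch time)
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tau_at(double t, double tau0, double tau1, double T) {
  return (t < T) ? tau0 : tau1;
}

// one RK4 step of the drift ODE with constant transcription input ct = c*tau
static inline void rk4_step(double &M, double &P, double h, double ct,
                            double dM, double dP, double alpha) {
  double k1M = ct - dM * M;
  double k1P = alpha * M - dP * P;
  double M2 = M + 0.5 * h * k1M, P2 = P + 0.5 * h * k1P;
  double k2M = ct - dM * M2;
  double k2P = alpha * M2 - dP * P2;
  double M3 = M + 0.5 * h * k2M, P3 = P + 0.5 * h * k2P;
  double k3M = ct - dM * M3;
  double k3P = alpha * M3 - dP * P3;
  double M4 = M + h * k3M, P4 = P + h * k3P;
  double k4M = ct - dM * M4;
  double k4P = alpha * M4 - dP * P4;
  M += h / 6.0 * (k1M + 2 * k2M + 2 * k3M + k4M);
  P += h / 6.0 * (k1P + 2 * k2P + 2 * k3P + k4P);
}

// integrate the drift ODE over [t0, t1] with tau constant on each side of T
static void ode_span(double &M, double &P, double t0, double t1,
                     double c, double tau0, double tau1, double T,
                     double dM, double dP, double alpha, double dt) {
  // split at the switch time so RK4 never straddles the discontinuity
  double cuts[3] = {t0, t1, t1};
  int ncut = 2;
  if (T > t0 && T < t1) { cuts[1] = T; cuts[2] = t1; ncut = 3; }
  for (int s = 0; s + 1 < ncut; ++s) {
    double a = cuts[s], b = cuts[s + 1];
    double len = b - a;
    if (len <= 0) continue;
    int n = (int)std::ceil(len / dt);
    double h = len / n;
    double ct = c * tau_at(a, tau0, tau1, T);
    for (int i = 0; i < n; ++i) rk4_step(M, P, h, ct, dM, dP, alpha);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ode_path(NumericVector times, double c, double tau0,
                           double tau1, double T, double M0, double P0,
                           double dM, double dP, double alpha, double dt) {
  int n = times.size();
  NumericMatrix out(n, 2);
  double M = M0, P = P0;
  out(0, 0) = M; out(0, 1) = P;
  for (int i = 1; i < n; ++i) {
    ode_span(M, P, times[i - 1], times[i], c, tau0, tau1, T, dM, dP, alpha, dt);
    out(i, 0) = M; out(i, 1) = P;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_path(NumericVector times, double c, double tau0,
                                double tau1, double T, double M0, double P0,
                                double dM, double dP, double alpha,
                                double dt, bool noise) {
  int n = times.size();
  NumericMatrix out(n, 2);
  double M = M0, P = P0;
  out(0, 0) = M; out(0, 1) = P;
  for (int i = 1; i < n; ++i) {
    double t = times[i - 1], tend = times[i];
    while (t < tend - 1e-12) {
      double h = std::min(dt, tend - t);
      // do not let a substep straddle the switch time
      if (t < T && t + h > T) h = T - t;
      if (h <= 1e-14) { t = T; continue; }
      double ct = c * tau_at(t, tau0, tau1, T);
      if (noise) {
        double qM = ct + dM * M;       // production + degradation propensities
        double qP = alpha * M + dP * P;
        if (qM < 0) qM = 0;
        if (qP < 0) qP = 0;
        // drift via RK4, diffusion via Euler-Maruyama increments
        rk4_step(M, P, h, ct, dM, dP, alpha);
        M += std::sqrt(qM * h) * norm_rand();
        P += std::sqrt(qP * h) * norm_rand();
      } else {
        rk4_step(M, P, h, ct, dM, dP, alpha);
      }
      if (M < 0) M = -M;  // reflect: CLE can undershoot zero
      if (P < 0) P = -P;
      t += h;
      if (!std::isfinite(M) || !std::isfinite(P))
        stop("non-finite state in stochastic integration at t=%f", t);
    }
    out(i, 0) = M; out(i, 1) = P;
  }
  return out;
}

// continuous-discrete Gaussian filter: propagate (mean, covariance) of the
// linear drift with CLE diffusion evaluated along the predicted mean, then
// assimilate each observation F_i ~ N(kappa * P, sigma2).
// [[Rcpp::export]]
double cpp_trace_loglik(NumericVector times, NumericVector F, double c,
                        double tau0, double tau1, double T, double M0,
                        double P0, double dM, double dP, double alpha,
                        double kappa, double sigma2, double dt) {
  int n = times.size();
  if (n == 0) stop("empty trace");
  double m1 = M0, m2 = P0;
  double v11 = 0.0, v12 = 0.0, v22 = 0.0;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double t = times[i - 1], tend = times[i];
      while (t < tend - 1e-12) {
        double h = std::min(dt, tend - t);
        if (t < T && t + h > T) h = T - t;
        if (h <= 1e-14) { t = T; continue; }
        double ct = c * tau_at(t, tau0, tau1, T);
        double q1 = ct + dM * m1;
        double q2 = alpha * m1 + dP * m2;
        if (q1 < 0) q1 = 0;
        if (q2 < 0) q2 = 0;
        // covariance: dV = A V + V A' + Q, Euler step (A constant, Q at mean)
        double nv11 = v11 + h * (-2.0 * dM * v11 + q1);
        double nv12 = v12 + h * (alpha * v11 - (dM + dP) * v12);
        double nv22 = v22 + h * (2.0 * (alpha * v12 - dP * v22) + q2);
        v11 = nv11; v12 = nv12; v22 = nv22;
        rk4_step(m1, m2, h, ct, dM, dP, alpha);
        t += h;
      }
    }
    double S = kappa * kappa * v22 + sigma2;
    double resid = F[i] - kappa * m2;
    if (S <= 0) {
      // degenerate: no observation noise and no accumulated process noise
      if (std::fabs(resid) > 1e-9) return R_NegInf;
      continue;
    }
    ll += -0.5 * (std::log(2.0 * M_PI * S) + resid * resid / S);
    double K1 = kappa * v12 / S;
    double K2 = kappa * v22 / S;
    m1 += K1 * resid;
    m2 += K2 * resid;
    double w11 = v11 - K1 * kappa * v12;
    double w12 = v12 - K1 * kappa * v22;
    double w22 = v22 - K2 * kappa * v22;
    v11 = w11; v12 = w12; v22 = w22;
  }
  if (!std::isfinite(ll)) return R_NegInf;
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_loglik_all(List times, List Fs, NumericVector c_,
                             NumericVector t0_, NumericVector t1_,
                             NumericVector T_, NumericVector M0_,
                             NumericVector P0_, double dM, double dP,
                             double alpha, double kappa, double sigma2,
                             double dt) {
  int ncell = c_.size();
  NumericVector out(ncell);
  for (int i = 0; i < ncell; ++i) {
    NumericVector tt = times[i], ff = Fs[i];
    out[i] = cpp_trace_loglik(tt, ff, c_[i], t0_[i], t1_[i], T_[i], M0_[i],
                              P0_[i], dM, dP, alpha, kappa, sigma2, dt);
  }
  return out;
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.91893853320467274178; // log sqrt(2pi)
}

// One Metropolis sweep over all cells.  Blocks per cell, in order:
//   log c, log tau1, log tau0, T (reflected), log M0, log P0, and a ridge
//   move (c, tau0, tau1) -> (g c, tau0/g, tau1/g) that exploits the exact
//   product-invariance of the likelihood: it needs no filter evaluation and
//   is accepted on the population-prior ratio alone, which is what lets the
//   chain travel along the copy-number/rate ridge.
// Priors: normal on the log scale with hyper (a, b) — per-construct for the
// rates, global for c (a fixed by the anchor), M0, P0; flat on T in
// [Tmin, Tmax].  The ordering tau0 <= tau1 is enforced by proposal rejection.
// update[j] switches block j on/off (for restricted runs).
// [[Rcpp::export]]
List cpp_sweep_cells(List times, List Fs, NumericVector c_, NumericVector t0_,
                     NumericVector t1_, NumericVector T_, NumericVector M0_,
                     NumericVector P0_, NumericVector ll, IntegerVector cons,
                     NumericMatrix rate_hyper, // cols: a0, b0, a1, b1
                     double ac, double bc, double aM0, double bM0,
                     double aP0, double bP0, double Tmin, double Tmax,
                     NumericVector step, LogicalVector update,
                     double dM, double dP, double alpha, double kappa,
                     double sigma2, double dt) {
  int ncell = c_.size();
  NumericVector c = clone(c_), t0 = clone(t0_), t1 = clone(t1_),
                Tv = clone(T_), M0 = clone(M0_), P0 = clone(P0_),
                llv = clone(ll);
  IntegerVector acc(7), prop(7);
  for (int i = 0; i < ncell; ++i) {
    NumericVector tt = times[i], ff = Fs[i];
    int j = cons[i];
    double a0 = rate_hyper(j, 0), b0 = rate_hyper(j, 1);
    double a1 = rate_hyper(j, 2), b1 = rate_hyper(j, 3);

    // block 0: copy number
    if (update[0]) {
      prop[0]++;
      double lc = std::log(c[i]);
      double lcn = lc + step[0] * norm_rand();
      double cn = std::exp(lcn);
      double lln = cpp_trace_loglik(tt, ff, cn, t0[i], t1[i], Tv[i], M0[i],
                                    P0[i], dM, dP, alpha, kappa, sigma2, dt);
      double lr = lln - llv[i] + dnorm_log(lcn, ac, bc) - dnorm_log(lc, ac, bc);
      if (std::isfinite(lln) && std::log(unif_rand()) < lr) {
        c[i] = cn; llv[i] = lln; acc[0]++;
      }
    }
    // block 1: active rate tau1
    if (update[1]) {
      prop[1]++;
      double lt = std::log(t1[i]);
      double ltn = lt + step[1] * norm_rand();
      double tn = std::exp(ltn);
      if (tn >= t0[i]) {
        double lln = cpp_trace_loglik(tt, ff, c[i], t0[i], tn, Tv[i], M0[i],
                                      P0[i], dM, dP, alpha, kappa, sigma2, dt);
        double lr = lln - llv[i] + dnorm_log(ltn, a1, b1) - dnorm_log(lt, a1, b1);
        if (std::isfinite(lln) && std::log(unif_rand()) < lr) {
          t1[i] = tn; llv[i] = lln; acc[1]++;
        }
      }
    }
    // block 2: basal rate tau0
    if (update[2]) {
      prop[2]++;
      double lt = std::log(t0[i]);
      double ltn = lt + step[2] * norm_rand();
      double tn = std::exp(ltn);
      if (tn <= t1[i]) {
        double lln = cpp_trace_loglik(tt, ff, c[i], tn, t1[i], Tv[i], M0[i],
                                      P0[i], dM, dP, alpha, kappa, sigma2, dt);
        double lr = lln - llv[i] + dnorm_log(ltn, a0, b0) - dnorm_log(lt, a0, b0);
        if (std::isfinite(lln) && std::log(unif_rand()) < lr) {
          t0[i] = tn; llv[i] = lln; acc[2]++;
        }
      }
    }
    // block 3: switch time, random walk reflected into [Tmin, Tmax]
    if (update[3]) {
      prop[3]++;
      double Tn = Tv[i] + step[3] * norm_rand();
      for (int r = 0; r < 100 && (Tn < Tmin || Tn > Tmax); ++r) {
        if (Tn < Tmin) Tn = 2 * Tmin - Tn;
        if (Tn > Tmax) Tn = 2 * Tmax - Tn;
      }
      if (Tn >= Tmin && Tn <= Tmax) {
        double lln = cpp_trace_loglik(tt, ff, c[i], t0[i], t1[i], Tn, M0[i],
                                      P0[i], dM, dP, alpha, kappa, sigma2, dt);
        if (std::isfinite(lln) && std::log(unif_rand()) < lln - llv[i]) {
          Tv[i] = Tn; llv[i] = lln; acc[3]++;
        }
      }
    }
    // block 4: initial mRNA
    if (update[4]) {
      prop[4]++;
      double lm = std::log(M0[i]);
      double lmn = lm + step[4] * norm_rand();
      double mn = std::exp(lmn);
      double lln = cpp_trace_loglik(tt, ff, c[i], t0[i], t1[i], Tv[i], mn,
                                    P0[i], dM, dP, alpha, kappa, sigma2, dt);
      double lr = lln - llv[i] + dnorm_log(lmn, aM0, bM0) - dnorm_log(lm, aM0, bM0);
      if (std::isfinite(lln) && std::log(unif_rand()) < lr) {
        M0[i] = mn; llv[i] = lln; acc[4]++;
      }
    }
    // block 5: initial protein
    if (update[5]) {
      prop[5]++;
      double lp = std::log(P0[i]);
      double lpn = lp + step[5] * norm_rand();
      double pn = std::exp(lpn);
      double lln = cpp_trace_loglik(tt, ff, c[i], t0[i], t1[i], Tv[i], M0[i],
                                    pn, dM, dP, alpha, kappa, sigma2, dt);
      double lr = lln - llv[i] + dnorm_log(lpn, aP0, bP0) - dnorm_log(lp, aP0, bP0);
      if (std::isfinite(lln) && std::log(unif_rand()) < lr) {
        P0[i] = pn; llv[i] = lln; acc[5]++;
      }
    }
    // block 6: ridge move along (c, tau) -> (g c, tau/g); likelihood exact-
    // invariant, so only the population priors enter the acceptance ratio
    if (update[6]) {
      prop[6]++;
      double lg = step[6] * norm_rand();
      double lc = std::log(c[i]), l0 = std::log(t0[i]), l1 = std::log(t1[i]);
      double lr = dnorm_log(lc + lg, ac, bc) - dnorm_log(lc, ac, bc) +
                  dnorm_log(l0 - lg, a0, b0) - dnorm_log(l0, a0, b0) +
                  dnorm_log(l1 - lg, a1, b1) - dnorm_log(l1, a1, b1);
      if (std::log(unif_rand()) < lr) {
        double g = std::exp(lg);
        c[i] *= g; t0[i] /= g; t1[i] /= g;
        acc[6]++;
      }
    }
  }
  return List::create(_["c"] = c, _["tau0"] = t0, _["tau1"] = t1, _["T"] = Tv,
                      _["M0"] = M0, _["P0"] = P0, _["ll"] = llv,
                      _["accept"] = acc, _["propose"] = prop);
}
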