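#include <Rcpp.h>
using namespace Rcpp;

// pow with a fast path for small integer exponents (Hill coefficients)
static inline double hpow(double x, double e) {
  if (e == 1.0) return x;
  if (e == 2.0) return x * x;
  if (e == 3.0) return x * x * x;
  if (e == 4.0) { double s = x * x; return s * s; }
  return std::pow(x, e);
}

// Euler--Maruyama integration of the per-cell alarmone--GTP switch model.
//
// Per-cell state: G (GTP, mM), P (alarmone, mM), F (reporter, a.u.),
// l (length, um), b (OU-perturbed basal synthesis rate beta0, mM/min),
// a (OU-perturbed GTP supply rate alpha_G, mM/min), Lam (cumulative death
// hazard under antibiotic, dimensionless), logW (log expected offspring).
//
// The update order per step is fixed and mirrored exactly by the R-level
// sim_step() reference: draw OU innovations for b then a, update b and a,
// evaluate rates at the current (G, P), then update P, G, F, l, Lam, logW.
//
// [[Rcpp::export]]
List sim_core_run(NumericVector G0, NumericVector P0, NumericVector F0,
                  NumericVector l0, NumericVector b0, NumericVector a0,
                  List pars, int n_steps, double dt,
                  LogicalVector induction_on, LogicalVector antibiotic_on,
                  IntegerVector record_ids, int record_every,
                  IntegerVector snapshot_steps) {
  const int n = G0.size();
  NumericVector G = clone(G0), P = clone(P0), Fv = clone(F0), l = clone(l0),
                b = clone(b0), a = clone(a0);
  NumericVector Lam(n), logW(n), mu(n);

  const double h = pars["h"], K_P = pars["K_P"], beta0 = pars["beta0"],
               sigma = pars["sigma"], tau = pars["tau"],
               beta1 = pars["beta1"], beta2 = pars["beta2"],
               delta_P = pars["delta_P"], alpha_G = pars["alpha_G"],
               sigma_alpha = pars["sigma_alpha"], tau_alpha = pars["tau_alpha"],
               K_i = pars["K_i"], gamma = pars["gamma"], K_sub = pars["K_sub"],
               G_th = pars["G_th"], m = pars["m"], mu_max = pars["mu_max"],
               a_F = pars["a_F"], K_F = pars["K_F"], q = pars["q"],
               d_F = pars["d_F"], k_max = pars["k_max"], k_min = pars["k_min"],
               l_birth = pars["l_birth"];

  const double KPh = std::pow(K_P, h), Gthm = std::pow(G_th, m),
               KFq = std::pow(K_F, q);
  // characteristic state scales; a single step moving half a scale means the
  // step size violates the <10% relative-change contract by a wide margin
  const double P_scale = (beta0 + beta1 + beta2) / std::max(delta_P, 1e-9) + 1.0;
  const double G_scale = alpha_G / std::max(mu_max, 1e-9) + 1.0;
  const double ou_b = (sigma > 0.0) ? sigma * std::sqrt(2.0 * dt / tau) : 0.0;
  const double ou_a = (sigma_alpha > 0.0)
      ? sigma_alpha * std::sqrt(2.0 * dt / tau_alpha) : 0.0;

  const int n_rec = record_ids.size();
  const int n_frames =
      (n_rec > 0 && record_every > 0) ? n_steps / record_every + 1 : 0;
  NumericMatrix recG(n_frames, n_rec), recP(n_frames, n_rec),
      recF(n_frames, n_rec), recL(n_frames, n_rec), recMu(n_frames, n_rec);
  LogicalMatrix recDiv(n_frames, n_rec);
  std::vector<int> div_since(n_rec, 0);

  const int n_snap = snapshot_steps.size();
  NumericMatrix snapF(n_snap, 0), snapLam(n_snap, 0), snapMu(n_snap, 0),
      snapP(n_snap, 0), snapG(n_snap, 0);
  if (n_snap > 0) {
    snapF = NumericMatrix(n, n_snap);
    snapLam = NumericMatrix(n, n_snap);
    snapMu = NumericMatrix(n, n_snap);
    snapP = NumericMatrix(n, n_snap);
    snapG = NumericMatrix(n, n_snap);
  }
  int next_snap = 0;

  // initial mu and frame 0
  for (int i = 0; i < n; ++i)
    mu[i] = mu_max * hpow(G[i], m) / (Gthm + hpow(G[i], m));
  int frame = 0;
  if (n_frames > 0) {
    for (int j = 0; j < n_rec; ++j) {
      int i = record_ids[j];
      recG(0, j) = G[i]; recP(0, j) = P[i]; recF(0, j) = Fv[i];
      recL(0, j) = l[i]; recMu(0, j) = mu[i]; recDiv(0, j) = false;
    }
    frame = 1;
  }
  while (next_snap < n_snap && snapshot_steps[next_snap] == 0) {
    for (int i = 0; i < n; ++i) {
      snapF(i, next_snap) = Fv[i]; snapLam(i, next_snap) = 0.0;
      snapMu(i, next_snap) = mu[i]; snapP(i, next_snap) = P[i];
      snapG(i, next_snap) = G[i];
    }
    ++next_snap;
  }

  for (int s = 1; s <= n_steps; ++s) {
    const bool ind = induction_on[s - 1], abx = antibiotic_on[s - 1];
    if (sigma > 0.0) {
      NumericVector xb = rnorm(n);
      for (int i = 0; i < n; ++i) {
        b[i] += (beta0 - b[i]) * dt / tau + ou_b * xb[i];
        if (b[i] < 0.0) b[i] = 0.0;
      }
    }
    if (sigma_alpha > 0.0) {
      NumericVector xa = rnorm(n);
      for (int i = 0; i < n; ++i) {
        a[i] += (alpha_G - a[i]) * dt / tau_alpha + ou_a * xa[i];
        if (a[i] < 0.0) a[i] = 0.0;
      }
    }
    for (int i = 0; i < n; ++i) {
      const double Gi = G[i], Pi = P[i];
      const double Gm = hpow(Gi, m);
      const double mui = mu_max * Gm / (Gthm + Gm);
      const double Ph = hpow(Pi, h);
      double B = b[i] + beta1 * Ph / (KPh + Ph);
      if (ind) B += beta2;
      const double v = B * Gi / (K_sub + Gi);
      double Pn = Pi + (v - delta_P * Pi) * dt;
      double Gn = Gi + (a[i] / (1.0 + Pi / K_i) - gamma * v - mui * Gi) * dt;
      const double Gq = hpow(Gi, q);
      double Fn = Fv[i] + (a_F * KFq / (KFq + Gq) - (mui + d_F) * Fv[i]) * dt;
      if (Pn < 0.0) Pn = 0.0;
      if (Gn < 0.0) Gn = 0.0;
      if (Fn < 0.0) Fn = 0.0;
      if (!R_finite(Pn) || !R_finite(Gn) || Pn > 1e5 || Gn > 1e5 ||
          std::fabs(Pn - Pi) > 0.5 * P_scale || std::fabs(Gn - Gi) > 0.5 * G_scale)
        stop("unstable integration at step %d (state change exceeds half its characteristic scale); reduce dt", s);
      P[i] = Pn; G[i] = Gn; Fv[i] = Fn;
      l[i] += mui * l[i] * dt;
      logW[i] += mui * dt;
      mu[i] = mui;
      if (abx) Lam[i] += (k_min + (k_max - k_min) * mui / mu_max) / 60.0 * dt;
    }
    // divisions (length halves at twice birth length; one daughter kept)
    for (int j = 0; j < n_rec; ++j) {
      int i = record_ids[j];
      if (l[i] >= 2.0 * l_birth) ++div_since[j];
    }
    for (int i = 0; i < n; ++i)
      if (l[i] >= 2.0 * l_birth) l[i] *= 0.5;

    if (n_frames > 0 && s % record_every == 0) {
      for (int j = 0; j < n_rec; ++j) {
        int i = record_ids[j];
        recG(frame, j) = G[i]; recP(frame, j) = P[i]; recF(frame, j) = Fv[i];
        recL(frame, j) = l[i]; recMu(frame, j) = mu[i];
        recDiv(frame, j) = div_since[j] > 0;
        div_since[j] = 0;
      }
      ++frame;
    }
    while (next_snap < n_snap && snapshot_steps[next_snap] == s) {
      for (int i = 0; i < n; ++i) {
        snapF(i, next_snap) = Fv[i]; snapLam(i, next_snap) = Lam[i];
        snapMu(i, next_snap) = mu[i]; snapP(i, next_snap) = P[i];
        snapG(i, next_snap) = G[i];
      }
      ++next_snap;
    }
  }

  return List::create(
      _["G"] = G, _["P"] = P, _["F"] = Fv, _["l"] = l, _["b"] = b, _["a"] = a,
      _["Lambda"] = Lam, _["logW"] = logW, _["mu"] = mu,
      _["rec_G"] = recG, _["rec_P"] = recP, _["rec_F"] = recF,
      _["rec_l"] = recL, _["rec_mu"] = recMu, _["rec_div"] = recDiv,
      _["snap_F"] = snapF, _["snap_Lambda"] = snapLam, _["snap_mu"] = snapMu,
      _["snap_P"] = snapP, _["snap_G"] = snapG);
}
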