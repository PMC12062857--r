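#include <Rcpp.h>
using namespace Rcpp;

// Non-centered hierarchical Metropolis-within-Gibbs sampler, one chain.
//
// Participant parameters live on transformed scales (logit / log); on that
// scale theta_i = mu + sigma * z_i with z_i ~ N(0,1), mu_j ~ N(loc_j, sc_j),
// sigma_j ~ half-Normal(ss_j). Each sweep updates all participants' z rows
// by independent joint random-walk proposals, then each mu_j and log
// sigma_j by scalar random walks; proposal scales adapt during warmup.
// Uses R's RNG (seed via set.seed() before the call).

namespace vb {
  static const double P_EPS = 1e-12;
  static inline double clamp_p(double p) {
    if (p < P_EPS) return P_EPS;
    if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
    return p;
  }
  static double ll_one(int rule, bool has_bias, bool dual, bool uses_mag,
                       const double* par, const int* choice,
                       const int* outcome, const int* phase,
                       const double* magA, const double* magB, int T) {
    const double b = par[0], tau = par[1];
    const double a_s = par[2], a_v = par[3], p_stay = par[4];
    double total = 0.0;
    if (rule == 0) {
      double pA = has_bias ? clamp_p(b) : 0.5;
      for (int t = 0; t < T; t++)
        total += std::log(choice[t] == 1 ? pA : 1.0 - pA);
      return total;
    }
    if (rule == 2) {
      for (int t = 0; t < T; t++) {
        double pA;
        if (t == 0) pA = has_bias ? b : 0.5;
        else {
          double p_rep = outcome[t - 1] == 1 ? p_stay : 1.0 - p_stay;
          pA = (choice[t - 1] == 1) ? p_rep : 1.0 - p_rep;
        }
        pA = clamp_p(pA);
        total += std::log(choice[t] == 1 ? pA : 1.0 - pA);
      }
      return total;
    }
    double vA = has_bias ? b : 0.5, vB = has_bias ? 1.0 - b : 0.5;
    for (int t = 0; t < T; t++) {
      double uA = vA, uB = vB;
      if (uses_mag) { uA = vA * magA[t] / 100.0; uB = vB * magB[t] / 100.0; }
      double pA = clamp_p(1.0 / (1.0 + std::exp(-(uA - uB) / tau)));
      total += std::log(choice[t] == 1 ? pA : 1.0 - pA);
      double alpha = dual ? (phase[t] == 0 ? a_s : a_v) : a_s;
      if (choice[t] == 1) vA += alpha * (outcome[t] - vA);
      else                vB += alpha * (outcome[t] - vB);
    }
    return total;
  }

  // pointwise variant for saved draws
  static void ll_pw(int rule, bool has_bias, bool dual, bool uses_mag,
                    const double* par, const int* choice, const int* outcome,
                    const int* phase, const double* magA, const double* magB,
                    int T, double* out) {
    const double b = par[0], tau = par[1];
    const double a_s = par[2], a_v = par[3], p_stay = par[4];
    if (rule == 0) {
      double pA = has_bias ? clamp_p(b) : 0.5;
      for (int t = 0; t < T; t++)
        out[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
      return;
    }
    if (rule == 2) {
      for (int t = 0; t < T; t++) {
        double pA;
        if (t == 0) pA = has_bias ? b : 0.5;
        else {
          double p_rep = outcome[t - 1] == 1 ? p_stay : 1.0 - p_stay;
          pA = (choice[t - 1] == 1) ? p_rep : 1.0 - p_rep;
        }
        pA = clamp_p(pA);
        out[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
      }
      return;
    }
    double vA = has_bias ? b : 0.5, vB = has_bias ? 1.0 - b : 0.5;
    for (int t = 0; t < T; t++) {
      double uA = vA, uB = vB;
      if (uses_mag) { uA = vA * magA[t] / 100.0; uB = vB * magB[t] / 100.0; }
      double pA = clamp_p(1.0 / (1.0 + std::exp(-(uA - uB) / tau)));
      out[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
      double alpha = dual ? (phase[t] == 0 ? a_s : a_v) : a_s;
      if (choice[t] == 1) vA += alpha * (outcome[t] - vA);
      else                vB += alpha * (outcome[t] - vB);
    }
  }

  static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
}

// Build canonical 5-par for participant i from transformed eta (k values)
static void fill_par(double* par, const double* eta, int k,
                     const IntegerVector& slot1, const IntegerVector& slot2,
                     const IntegerVector& trans) {
  par[0] = 0.5; par[1] = 1.0; par[2] = 0.5; par[3] = 0.5; par[4] = 0.5;
  for (int j = 0; j < k; j++) {
    double nat = trans[j] == 1 ? std::exp(eta[j]) : vb::inv_logit(eta[j]);
    par[slot1[j]] = nat;
    if (slot2[j] >= 0) par[slot2[j]] = nat;
  }
}

// [[Rcpp::export]]
List vb_sample_chain(int rule, bool has_bias, bool dual, bool uses_mag,
                     IntegerVector slot1, IntegerVector slot2,
                     IntegerVector trans,
                     NumericVector loc, NumericVector sc, NumericVector ss,
                     IntegerMatrix choice, IntegerMatrix outcome,
                     IntegerMatrix phase, NumericMatrix magA,
                     NumericMatrix magB,
                     int warmup, int iter,
                     double target_block, double target_scalar,
                     bool save_pointwise) {
  int N = choice.nrow(), T = choice.ncol(), k = loc.size();
  RNGScope scope;

  // flatten data row-wise for cache-friendly per-participant access
  std::vector<int> ch(N * T), oc(N * T), ph(N * T);
  std::vector<double> mA(N * T), mB(N * T);
  for (int i = 0; i < N; i++)
    for (int t = 0; t < T; t++) {
      ch[i * T + t] = choice(i, t); oc[i * T + t] = outcome(i, t);
      ph[i * T + t] = phase(i, t);
      mA[i * T + t] = magA(i, t);  mB[i * T + t] = magB(i, t);
    }

  std::vector<double> mu(k), ls(k), sg(k);
  for (int j = 0; j < k; j++) {
    mu[j] = loc[j] + 0.3 * sc[j] * R::norm_rand();
    ls[j] = std::log(0.5) + 0.2 * R::norm_rand();
    sg[j] = std::exp(ls[j]);
  }
  std::vector<double> z(N * k);
  for (int i = 0; i < N * k; i++) z[i] = 0.1 * R::norm_rand();

  std::vector<double> step_z(N, 0.3), step_mu(k, 0.1), step_ls(k, 0.2);
  std::vector<double> ll(N), eta(k), par(5);

  auto ll_participant = [&](int i, const double* mu_v, const double* sg_v,
                            const double* z_row) {
    for (int j = 0; j < k; j++) eta[j] = mu_v[j] + sg_v[j] * z_row[j];
    fill_par(par.data(), eta.data(), k, slot1, slot2, trans);
    return vb::ll_one(rule, has_bias, dual, uses_mag, par.data(),
                      &ch[i * T], &oc[i * T], &ph[i * T],
                      &mA[i * T], &mB[i * T], T);
  };

  for (int i = 0; i < N; i++) ll[i] = ll_participant(i, mu.data(), sg.data(), &z[i * k]);

  NumericMatrix mu_draws(iter, k), sig_draws(iter, k);
  NumericVector th_draws(Dimension(iter, N, k));
  NumericMatrix pw_draws(save_pointwise ? iter : 1,
                         save_pointwise ? N * T : 1);
  std::vector<double> z_star(k), pwbuf(T);
  double acc_block = 0, prop_block = 0, acc_scalar = 0, prop_scalar = 0;

  int total_sweeps = warmup + iter;
  for (int sw = 1; sw <= total_sweeps; sw++) {
    bool warm = sw <= warmup;
    double gam = warm ? std::pow((double)sw, -0.6) : 0.0;

    // (a) participant z blocks
    for (int i = 0; i < N; i++) {
      double lq = 0.0, lq_star = 0.0;
      for (int j = 0; j < k; j++) {
        z_star[j] = z[i * k + j] + step_z[i] * R::norm_rand();
        lq      += -0.5 * z[i * k + j] * z[i * k + j];
        lq_star += -0.5 * z_star[j] * z_star[j];
      }
      double ll_star = ll_participant(i, mu.data(), sg.data(), z_star.data());
      double logr = ll_star - ll[i] + lq_star - lq;
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) {
        for (int j = 0; j < k; j++) z[i * k + j] = z_star[j];
        ll[i] = ll_star;
      }
      if (warm) {
        step_z[i] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_block));
        step_z[i] = std::min(std::max(step_z[i], 1e-3), 5.0);
      } else { acc_block += acc; prop_block += 1; }
    }

    // (b) group means
    for (int j = 0; j < k; j++) {
      double mu_old = mu[j];
      double mu_new = mu_old + step_mu[j] * R::norm_rand();
      double delta = 0.0;
      std::vector<double> ll_new(N);
      mu[j] = mu_new;
      for (int i = 0; i < N; i++) {
        ll_new[i] = ll_participant(i, mu.data(), sg.data(), &z[i * k]);
        delta += ll_new[i] - ll[i];
      }
      delta += R::dnorm(mu_new, loc[j], sc[j], 1) -
               R::dnorm(mu_old, loc[j], sc[j], 1);
      bool acc = std::log(R::unif_rand()) < delta;
      if (acc) ll = ll_new; else mu[j] = mu_old;
      if (warm) {
        step_mu[j] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_scalar));
        step_mu[j] = std::min(std::max(step_mu[j], 1e-3), 5.0);
      } else { acc_scalar += acc; prop_scalar += 1; }
    }

    // (c) group SDs on log scale; half-Normal prior + Jacobian
    for (int j = 0; j < k; j++) {
      double ls_old = ls[j], sg_old = sg[j];
      double ls_new = ls_old + step_ls[j] * R::norm_rand();
      double sg_new = std::exp(ls_new);
      std::vector<double> ll_new(N);
      double delta = 0.0;
      sg[j] = sg_new;
      for (int i = 0; i < N; i++) {
        ll_new[i] = ll_participant(i, mu.data(), sg.data(), &z[i * k]);
        delta += ll_new[i] - ll[i];
      }
      delta += (-sg_new * sg_new / (2 * ss[j] * ss[j]) + ls_new) -
               (-sg_old * sg_old / (2 * ss[j] * ss[j]) + ls_old);
      bool acc = std::log(R::unif_rand()) < delta;
      if (acc) { ls[j] = ls_new; ll = ll_new; }
      else sg[j] = sg_old;
      if (warm) {
        step_ls[j] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_scalar));
        step_ls[j] = std::min(std::max(step_ls[j], 1e-3), 5.0);
      } else { acc_scalar += acc; prop_scalar += 1; }
    }

    if (!warm) {
      int s = sw - warmup - 1;
      for (int j = 0; j < k; j++) {
        mu_draws(s, j) = mu[j];
        sig_draws(s, j) = sg[j];
      }
      for (int i = 0; i < N; i++) {
        for (int j = 0; j < k; j++) {
          double e = mu[j] + sg[j] * z[i * k + j];
          double nat = trans[j] == 1 ? std::exp(e) : vb::inv_logit(e);
          th_draws[s + iter * (i + N * j)] = nat;
        }
        if (save_pointwise) {
          for (int j = 0; j < k; j++) eta[j] = mu[j] + sg[j] * z[i * k + j];
          fill_par(par.data(), eta.data(), k, slot1, slot2, trans);
          vb::ll_pw(rule, has_bias, dual, uses_mag, par.data(),
                    &ch[i * T], &oc[i * T], &ph[i * T], &mA[i * T],
                    &mB[i * T], T, pwbuf.data());
          // column order matches as.vector(N x T matrix): i + N * t
          for (int t = 0; t < T; t++)
            pw_draws(s, i + N * t) = pwbuf[t];
        }
      }
    }
  }

  return List::create(
    _["mu"] = mu_draws, _["sigma"] = sig_draws, _["theta"] = th_draws,
    _["pointwise"] = save_pointwise ? (SEXP)pw_draws : R_NilValue,
    _["accept_block"] = prop_block > 0 ? acc_block / prop_block : NA_REAL,
    _["accept_scalar"] = prop_scalar > 0 ? acc_scalar / prop_scalar : NA_REAL);
}
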