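#include <Rcpp.h>
using namespace Rcpp;

// Trialwise choice likelihoods for the bandit model family.
//
// All functions share a canonical 5-slot parameter layout (natural scale):
//   par[0] = b        starting bias / constant choice bias, in (0,1)
//   par[1] = tau      softmax temperature, > 0
//   par[2] = alpha_s  learning rate, stable phase, in (0,1)
//   par[3] = alpha_v  learning rate, volatile phase, in (0,1)
//   par[4] = p_stay   win-stay probability (WSLS rule), in (0,1)
// Slots a given model does not use are ignored.
//
// rule: 0 = random (null), 1 = Rescorla-Wagner, 2 = win-stay-lose-shift
// choice is coded 1 = option A, 2 = option B; outcome is 0/1; phase is
// 0 = stable, 1 = volatile; magnitudes are the displayed coin counts.

static const double P_EPS = 1e-12;

static inline double clamp_p(double p) {
  if (p < P_EPS) return P_EPS;
  if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
  return p;
}

// log P(choice_t) for one participant, written into ll[0..T-1]
static void ll_seq(int rule, bool has_bias, bool dual, bool uses_mag,
                   const double* par,
                   const int* choice, const int* outcome, const int* phase,
                   const double* magA, const double* magB,
                   int T, double* ll) {
  const double b = par[0], tau = par[1];
  const double a_s = par[2], a_v = par[3], p_stay = par[4];

  if (rule == 0) { // random / null
    double pA = has_bias ? clamp_p(b) : 0.5;
    for (int t = 0; t < T; t++)
      ll[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
    return;
  }

  if (rule == 2) { // win-stay-lose-shift
    for (int t = 0; t < T; t++) {
      double pA;
      if (t == 0) {
        pA = has_bias ? b : 0.5;
      } else {
        double p_rep = outcome[t - 1] == 1 ? p_stay : 1.0 - p_stay;
        pA = (choice[t - 1] == 1) ? p_rep : 1.0 - p_rep;
      }
      pA = clamp_p(pA);
      ll[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
    }
    return;
  }

  // Rescorla-Wagner
  double vA = has_bias ? b : 0.5;
  double vB = has_bias ? 1.0 - b : 0.5;
  for (int t = 0; t < T; t++) {
    double uA = vA, uB = vB;
    if (uses_mag) {
      uA = vA * magA[t] / 100.0;
      uB = vB * magB[t] / 100.0;
    }
    double pA = clamp_p(1.0 / (1.0 + std::exp(-(uA - uB) / tau)));
    ll[t] = std::log(choice[t] == 1 ? pA : 1.0 - pA);
    double alpha = dual ? (phase[t] == 0 ? a_s : a_v) : a_s;
    if (choice[t] == 1) vA += alpha * (outcome[t] - vA);
    else                vB += alpha * (outcome[t] - vB);
  }
}

// [[Rcpp::export]]
NumericVector vb_ll_pointwise(int rule, bool has_bias, bool dual, bool uses_mag,
                              NumericVector par,
                              IntegerVector choice, IntegerVector outcome,
                              IntegerVector phase,
                              NumericVector magA, NumericVector magB) {
  int T = choice.size();
  NumericVector ll(T);
  if (T == 0) return ll;
  ll_seq(rule, has_bias, dual, uses_mag, REAL(par),
         INTEGER(choice), INTEGER(outcome), INTEGER(phase),
         REAL(magA), REAL(magB), T, REAL(ll));
  return ll;
}

// Per-participant total log-likelihood for a cohort: theta is N x 5,
// data matrices are N x T (one row per participant).
// [[Rcpp::export]]
NumericVector vb_ll_total_mat(int rule, bool has_bias, bool dual, bool uses_mag,
                              NumericMatrix theta,
                              IntegerMatrix choice, IntegerMatrix outcome,
                              IntegerMatrix phase,
                              NumericMatrix magA, NumericMatrix magB) {
  int N = choice.nrow(), T = choice.ncol();
  NumericVector out(N);
  std::vector<double> ll(T), par(5);
  std::vector<int> ch(T), oc(T), ph(T);
  std::vector<double> mA(T), mB(T);
  for (int i = 0; i < N; i++) {
    for (int j = 0; j < 5; j++) par[j] = theta(i, j);
    for (int t = 0; t < T; t++) {
      ch[t] = choice(i, t); oc[t] = outcome(i, t); ph[t] = phase(i, t);
      mA[t] = magA(i, t);   mB[t] = magB(i, t);
    }
    ll_seq(rule, has_bias, dual, uses_mag, par.data(),
           ch.data(), oc.data(), ph.data(), mA.data(), mB.data(), T, ll.data());
    double s = 0.0;
    for (int t = 0; t < T; t++) s += ll[t];
    out[i] = s;
  }
  return out;
}

// Pointwise log-likelihood matrix (N x T) for one cohort-level draw.
// [[Rcpp::export]]
NumericMatrix vb_ll_pointwise_mat(int rule, bool has_bias, bool dual, bool uses_mag,
                                  NumericMatrix theta,
                                  IntegerMatrix choice, IntegerMatrix outcome,
                                  IntegerMatrix phase,
                                  NumericMatrix magA, NumericMatrix magB) {
  int N = choice.nrow(), T = choice.ncol();
  NumericMatrix out(N, T);
  std::vector<double> ll(T), par(5);
  std::vector<int> ch(T), oc(T), ph(T);
  std::vector<double> mA(T), mB(T);
  for (int i = 0; i < N; i++) {
    for (int j = 0; j < 5; j++) par[j] = theta(i, j);
    for (int t = 0; t < T; t++) {
      ch[t] = choice(i, t); oc[t] = outcome(i, t); ph[t] = phase(i, t);
      mA[t] = magA(i, t);   mB[t] = magB(i, t);
    }
    ll_seq(rule, has_bias, dual, uses_mag, par.data(),
           ch.data(), oc.data(), ph.data(), mA.data(), mB.data(), T, ll.data());
    for (int t = 0; t < T; t++) out(i, t) = ll[t];
  }
  return out;
}

// Pointwise log-likelihood for S parameter draws of a single participant:
// par_draws is S x 5, result is S x T. Used for Laplace-approximation WAIC.
// [[Rcpp::export]]
NumericMatrix vb_ll_pointwise_draws(int rule, bool has_bias, bool dual, bool uses_mag,
                                    NumericMatrix par_draws,
                                    IntegerVector choice, IntegerVector outcome,
                                    IntegerVector phase,
                                    NumericVector magA, NumericVector magB) {
  int S = par_draws.nrow(), T = choice.size();
  NumericMatrix out(S, T);
  std::vector<double> ll(T), par(5);
  for (int s = 0; s < S; s++) {
    for (int j = 0; j < 5; j++) par[j] = par_draws(s, j);
    ll_seq(rule, has_bias, dual, uses_mag, par.data(),
           INTEGER(choice), INTEGER(outcome), INTEGER(phase),
           REAL(magA), REAL(magB), T, ll.data());
    for (int t = 0; t < T; t++) out(s, t) = ll[t];
  }
  return out;
}
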