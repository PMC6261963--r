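#include <Rcpp.h>
using namespace Rcpp;

// Core trial-level computations for the dual-learning-rate Q-learning model.
//
// Conventions shared by all routines:
//  * symbols are indexed 0..5; pair p (0-based) owns symbols 2p (better)
//    and 2p+1 (worse); Q starts at 0 for every symbol at segment start;
//  * a "segment" is one task session of one subject-day: Q is reset at its
//    start and evolves only within it;
//  * rewards are coded 0/1; learning rates act on the prediction error
//    r - Q of the chosen symbol only, alpha_G for positive, alpha_L for
//    negative errors (an exactly zero error updates nothing);
//  * the softmax uses exp(Q/beta), so only the scaled value difference
//    (Q_chosen - Q_other)/beta enters the choice log-likelihood.

static inline double log_sigmoid(double u) {
  // log(1/(1+exp(-u))), stable for large |u|
  if (u > 0.0) return -log1p(std::exp(-u));
  return u - log1p(std::exp(u));
}

static inline double sigmoid_neg(double u) {
  // 1/(1+exp(u)) = d/du log_sigmoid(u)
  if (u > 0.0) { double e = std::exp(-u); return e / (1.0 + e); }
  return 1.0 / (1.0 + std::exp(u));
}

// Pointwise log-likelihood and its gradient w.r.t. the natural-scale
// parameters (alpha_G, alpha_L, beta) of each parameter set.
//
// pair, chose_better, reward: concatenated trials over all segments.
// seg_start (0-based), seg_len: segment boundaries.
// seg_par (0-based): which parameter set governs each segment.
// Returns total and pointwise log-likelihood plus an n_par x 3 gradient
// matrix (columns: d/d alpha_G, d/d alpha_L, d/d beta).
// [[Rcpp::export]]
List rl_loglik_grad_cpp(IntegerVector pair, IntegerVector chose_better,
                        IntegerVector reward,
                        IntegerVector seg_start, IntegerVector seg_len,
                        IntegerVector seg_par,
                        NumericVector alpha_G, NumericVector alpha_L,
                        NumericVector beta) {
  const int n_seg = seg_start.size();
  const int n_par = alpha_G.size();
  const int n_trial = pair.size();
  NumericVector pointwise(n_trial);
  NumericMatrix grad(n_par, 3);
  double total = 0.0;

  double Q[6], dQG[6], dQL[6];

  for (int s = 0; s < n_seg; ++s) {
    const int p = seg_par[s];
    const double aG = alpha_G[p], aL = alpha_L[p], be = beta[p];
    double gG = 0.0, gL = 0.0, gB = 0.0;
    for (int k = 0; k < 6; ++k) { Q[k] = 0.0; dQG[k] = 0.0; dQL[k] = 0.0; }

    const int t0 = seg_start[s], t1 = seg_start[s] + seg_len[s];
    for (int t = t0; t < t1; ++t) {
      const int pr = pair[t];
      const int better = 2 * pr, worse = 2 * pr + 1;
      const int ch = chose_better[t] ? better : worse;
      const int ot = chose_better[t] ? worse : better;

      const double u = (Q[ch] - Q[ot]) / be;
      const double ll = log_sigmoid(u);
      pointwise[t] = ll;
      total += ll;

      const double g = sigmoid_neg(u); // dll/du
      gG += g * (dQG[ch] - dQG[ot]) / be;
      gL += g * (dQL[ch] - dQL[ot]) / be;
      gB += -g * u / be;

      const double pe = (double)reward[t] - Q[ch];
      if (pe > 0.0) {
        dQG[ch] = (1.0 - aG) * dQG[ch] + pe;
        dQL[ch] = (1.0 - aG) * dQL[ch];
        Q[ch] += aG * pe;
      } else if (pe < 0.0) {
        dQG[ch] = (1.0 - aL) * dQG[ch];
        dQL[ch] = (1.0 - aL) * dQL[ch] + pe;
        Q[ch] += aL * pe;
      }
    }
    grad(p, 0) += gG;
    grad(p, 1) += gL;
    grad(p, 2) += gB;
  }

  return List::create(_["loglik"] = total,
                      _["pointwise"] = pointwise,
                      _["grad"] = grad);
}

// Simulate one segment: softmax choices over the current Q values and
// Bernoulli feedback from the pair contingencies. Uses R's RNG so that
// set.seed() in R makes runs reproducible.
// p_better/p_worse indexed by pair (length 3).
// [[Rcpp::export]]
List rl_simulate_cpp(IntegerVector pair, NumericVector p_better,
                     NumericVector p_worse,
                     double alpha_G, double alpha_L, double beta) {
  const int n = pair.size();
  IntegerVector chose_better(n), reward(n);
  double Q[6];
  for (int k = 0; k < 6; ++k) Q[k] = 0.0;

  for (int t = 0; t < n; ++t) {
    const int pr = pair[t];
    const int better = 2 * pr, worse = 2 * pr + 1;
    const double u = (Q[better] - Q[worse]) / beta;
    const double p_b = 1.0 / (1.0 + std::exp(-u));
    const int cb = (unif_rand() < p_b) ? 1 : 0;
    const int ch = cb ? better : worse;
    const double p_rew = cb ? p_better[pr] : p_worse[pr];
    const int r = (unif_rand() < p_rew) ? 1 : 0;
    chose_better[t] = cb;
    reward[t] = r;

    const double pe = (double)r - Q[ch];
    if (pe > 0.0) Q[ch] += alpha_G * pe;
    else if (pe < 0.0) Q[ch] += alpha_L * pe;
  }
  return List::create(_["chose_better"] = chose_better,
                      _["reward"] = reward);
}

// Mean accuracy (proportion of better-symbol choices) over n_reps
// replicate agents run on the same trial schedule. Used by the
// expected-performance map, where per-replicate records are not needed.
// [[Rcpp::export]]
double rl_sim_accuracy_cpp(IntegerVector pair, NumericVector p_better,
                           NumericVector p_worse,
                           double alpha_G, double alpha_L, double beta,
                           int n_reps) {
  const int n = pair.size();
  long correct = 0;
  double Q[6];

  for (int rep = 0; rep < n_reps; ++rep) {
    for (int k = 0; k < 6; ++k) Q[k] = 0.0;
    for (int t = 0; t < n; ++t) {
      const int pr = pair[t];
      const int better = 2 * pr, worse = 2 * pr + 1;
      const double u = (Q[better] - Q[worse]) / beta;
      const double p_b = 1.0 / (1.0 + std::exp(-u));
      const int cb = (unif_rand() < p_b) ? 1 : 0;
      const int ch = cb ? better : worse;
      const double p_rew = cb ? p_better[pr] : p_worse[pr];
      const int r = (unif_rand() < p_rew) ? 1 : 0;
      correct += cb;
      const double pe = (double)r - Q[ch];
      if (pe > 0.0) Q[ch] += alpha_G * pe;
      else if (pe < 0.0) Q[ch] += alpha_L * pe;
    }
  }
  return (double)correct / ((double)n * n_reps);
}
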