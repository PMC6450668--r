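// Two-state Gaussian-emission HMM inner loops.
// Scaled forward/backward (Rabiner per-step normalization, so long series
// never underflow) and log-space Viterbi with ties broken toward the
// lower-index (open) state.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gaussPdf(double x, double mean, double var) {
  double d = x - mean;
  return std::exp(-0.5 * d * d / var) / std::sqrt(2.0 * M_PI * var);
}

// Scaled forward pass. Returns log-likelihood, scaled alpha (T x 2) and the
// per-step scale factors c_t (so that unscaled alpha_t = alphaHat_t *
// prod_{s<=t} c_s^{-1} ... stored as sums of logs in logLik).
// [[Rcpp::export(name = ".hmmForwardCpp")]]
List hmmForwardCpp(NumericVector obs, NumericVector means, NumericVector vars,
                   NumericMatrix trans, NumericVector init) {
  int T = obs.size();
  NumericMatrix alpha(T, 2);
  NumericVector scale(T);
  double ll = 0.0;
  double a0 = init[0] * gaussPdf(obs[0], means[0], vars[0]);
  double a1 = init[1] * gaussPdf(obs[0], means[1], vars[1]);
  double c = a0 + a1;
  if (c <= 0) { c = 1e-300; }
  alpha(0, 0) = a0 / c; alpha(0, 1) = a1 / c;
  scale[0] = c; ll += std::log(c);
  for (int t = 1; t < T; ++t) {
    double p0 = alpha(t - 1, 0) * trans(0, 0) + alpha(t - 1, 1) * trans(1, 0);
    double p1 = alpha(t - 1, 0) * trans(0, 1) + alpha(t - 1, 1) * trans(1, 1);
    a0 = p0 * gaussPdf(obs[t], means[0], vars[0]);
    a1 = p1 * gaussPdf(obs[t], means[1], vars[1]);
    c = a0 + a1;
    if (c <= 0) { c = 1e-300; }
    alpha(t, 0) = a0 / c; alpha(t, 1) = a1 / c;
    scale[t] = c; ll += std::log(c);
  }
  return List::create(_["logLik"] = ll, _["alpha"] = alpha,
                      _["scale"] = scale);
}

// Scaled backward pass using the forward scale factors.
// [[Rcpp::export(name = ".hmmBackwardCpp")]]
NumericMatrix hmmBackwardCpp(NumericVector obs, NumericVector means,
                             NumericVector vars, NumericMatrix trans,
                             NumericVector scale) {
  int T = obs.size();
  NumericMatrix beta(T, 2);
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double b0n = gaussPdf(obs[t + 1], means[0], vars[0]) * beta(t + 1, 0);
    double b1n = gaussPdf(obs[t + 1], means[1], vars[1]) * beta(t + 1, 1);
    double c = scale[t + 1];
    beta(t, 0) = (trans(0, 0) * b0n + trans(0, 1) * b1n) / c;
    beta(t, 1) = (trans(1, 0) * b0n + trans(1, 1) * b1n) / c;
  }
  return beta;
}

// Accumulate E-step sufficient statistics for one series:
// gamma sums, xi sums, gamma-weighted obs sums, gamma at t = 1.
// [[Rcpp::export(name = ".hmmEStepCpp")]]
List hmmEStepCpp(NumericVector obs, NumericVector means, NumericVector vars,
                 NumericMatrix trans, NumericVector init) {
  int T = obs.size();
  List fw = hmmForwardCpp(obs, means, vars, trans, init);
  NumericMatrix alpha = fw["alpha"];
  NumericVector scale = fw["scale"];
  NumericMatrix beta = hmmBackwardCpp(obs, means, vars, trans, scale);
  NumericVector gammaSum(2), gammaObs(2), gammaObs2(2), gamma1(2), gammaT(2);
  NumericMatrix xiSum(2, 2);
  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double z = g0 + g1;
    if (z <= 0) { g0 = 0.5; g1 = 0.5; z = 1.0; }
    g0 /= z; g1 /= z;
    gammaSum[0] += g0; gammaSum[1] += g1;
    gammaObs[0] += g0 * obs[t]; gammaObs[1] += g1 * obs[t];
    gammaObs2[0] += g0 * obs[t] * obs[t]; gammaObs2[1] += g1 * obs[t] * obs[t];
    if (t == 0) { gamma1[0] = g0; gamma1[1] = g1; }
    if (t == T - 1) { gammaT[0] = g0; gammaT[1] = g1; }
  }
  for (int t = 0; t < T - 1; ++t) {
    double e0 = gaussPdf(obs[t + 1], means[0], vars[0]);
    double e1 = gaussPdf(obs[t + 1], means[1], vars[1]);
    double den = scale[t + 1];
    double x00 = alpha(t, 0) * trans(0, 0) * e0 * beta(t + 1, 0) / den;
    double x01 = alpha(t, 0) * trans(0, 1) * e1 * beta(t + 1, 1) / den;
    double x10 = alpha(t, 1) * trans(1, 0) * e0 * beta(t + 1, 0) / den;
    double x11 = alpha(t, 1) * trans(1, 1) * e1 * beta(t + 1, 1) / den;
    double z = x00 + x01 + x10 + x11;
    if (z > 0) {
      xiSum(0, 0) += x00 / z; xiSum(0, 1) += x01 / z;
      xiSum(1, 0) += x10 / z; xiSum(1, 1) += x11 / z;
    }
  }
  return List::create(_["logLik"] = fw["logLik"], _["gammaSum"] = gammaSum,
                      _["gammaObs"] = gammaObs, _["gammaObs2"] = gammaObs2,
                      _["gamma1"] = gamma1, _["gammaT"] = gammaT,
                      _["xiSum"] = xiSum);
}

// Log-space Viterbi. Ties broken toward state 0 (open): a path through the
// lower-index state wins when scores are equal.
// [[Rcpp::export(name = ".hmmViterbiCpp")]]
List hmmViterbiCpp(NumericVector obs, NumericVector means, NumericVector vars,
                   NumericMatrix trans, NumericVector init) {
  int T = obs.size();
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  const double NEG = -1e300;
  double lTrans[2][2], lInit[2];
  for (int i = 0; i < 2; ++i) {
    lInit[i] = init[i] > 0 ? std::log(init[i]) : NEG;
    for (int j = 0; j < 2; ++j)
      lTrans[i][j] = trans(i, j) > 0 ? std::log(trans(i, j)) : NEG;
  }
  for (int j = 0; j < 2; ++j) {
    double d = obs[0] - means[j];
    double le = -0.5 * d * d / vars[j] - 0.5 * std::log(2.0 * M_PI * vars[j]);
    delta(0, j) = lInit[j] + le;
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double s0 = delta(t - 1, 0) + lTrans[0][j];
      double s1 = delta(t - 1, 1) + lTrans[1][j];
      int arg = (s1 > s0) ? 1 : 0;       // tie -> state 0
      double best = (arg == 1) ? s1 : s0;
      double d = obs[t] - means[j];
      double le = -0.5 * d * d / vars[j] - 0.5 * std::log(2.0 * M_PI * vars[j]);
      delta(t, j) = best + le;
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int last = (delta(T - 1, 1) > delta(T - 1, 0)) ? 1 : 0;  // tie -> open
  double lp = delta(T - 1, last);
  path[T - 1] = last;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return List::create(_["states"] = path, _["logProb"] = lp);
}
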