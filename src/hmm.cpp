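// Duration-structured 3-state HMM for nucleosome calling from tiling-array
// signal. Macro-states: L (linker), W (well-positioned nucleosome, fixed
// duration of dW probes encoded as a chain of sub-states), D (delocalized
// nucleosome, minimum duration dD then geometric continuation p_cont).
// Missing probes contribute emission likelihood 1 (marginalized out).
//
// State indexing over the expanded chain: 0 = L; 1..dW = W sub-states;
// dW+1..dW+dD = D sub-states. Transition parameters: pLL, pLW, pLD
// (leaving/looping at L) and p_cont (self-loop of the last D sub-state).
// W_dW and D_last (on exit) return to L.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int macro_of(int s, int dW) {
  if (s == 0) return 0;
  if (s <= dW) return 1;
  return 2;
}

// Gaussian emission density; missing -> 1.0. Floored at a tiny positive
// value so a far outlier cannot zero out the whole forward recursion.
static inline double emis(double x, bool miss, double mu, double sd) {
  if (miss) return 1.0;
  double z = (x - mu) / sd;
  double e = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return std::max(e, 1e-290);
}

// Fill emission matrix T x n (expanded states) given per-macro params
static void fill_emissions(const NumericVector& x, const LogicalVector& miss,
                           int dW, int dD,
                           const double* mu, const double* sd,
                           NumericMatrix& E) {
  int T = x.size(), n = 1 + dW + dD;
  for (int t = 0; t < T; ++t) {
    double eL = emis(x[t], miss[t], mu[0], sd[0]);
    double eW = emis(x[t], miss[t], mu[1], sd[1]);
    double eD = emis(x[t], miss[t], mu[2], sd[2]);
    E(t, 0) = eL;
    for (int s = 1; s <= dW; ++s) E(t, s) = eW;
    for (int s = dW + 1; s < n; ++s) E(t, s) = eD;
  }
}

// Scaled forward pass. trans is T x 4 (pLL,pLW,pLD,pcont); row t gives the
// parameters of the t -> t+1 step (row T-1 unused). Returns log-likelihood.
static double forward_pass(const NumericMatrix& E, const NumericMatrix& trans,
                           int dW, int dD, NumericMatrix& alpha,
                           NumericVector& cvec) {
  int T = E.nrow(), n = E.ncol();
  int f = dW + 1, last = dW + dD;
  // initial distribution: 1/3 per macro-state, uniform within chains
  double piL = 1.0 / 3.0, piW = (1.0 / 3.0) / dW, piD = (1.0 / 3.0) / dD;
  double c = 0.0;
  alpha(0, 0) = piL * E(0, 0);
  for (int s = 1; s <= dW; ++s) alpha(0, s) = piW * E(0, s);
  for (int s = f; s <= last; ++s) alpha(0, s) = piD * E(0, s);
  for (int s = 0; s < n; ++s) c += alpha(0, s);
  if (c <= 0) c = 1e-300;
  for (int s = 0; s < n; ++s) alpha(0, s) /= c;
  cvec[0] = c;
  double ll = std::log(c);

  for (int t = 1; t < T; ++t) {
    double pLL = trans(t - 1, 0), pLW = trans(t - 1, 1), pLD = trans(t - 1, 2),
           pc = trans(t - 1, 3);
    const double aL = alpha(t - 1, 0), aWlast = alpha(t - 1, dW),
                 aDlast = alpha(t - 1, last);
    alpha(t, 0) = (aL * pLL + aWlast + aDlast * (1.0 - pc)) * E(t, 0);
    alpha(t, 1) = aL * pLW * E(t, 1);
    for (int s = 2; s <= dW; ++s) alpha(t, s) = alpha(t - 1, s - 1) * E(t, s);
    // D chain
    double inD1 = aL * pLD;
    if (f == last) inD1 += aDlast * pc;
    alpha(t, f) = inD1 * E(t, f);
    for (int s = f + 1; s <= last; ++s) {
      double in = alpha(t - 1, s - 1);
      if (s == last) in += aDlast * pc;
      alpha(t, s) = in * E(t, s);
    }
    c = 0.0;
    for (int s = 0; s < n; ++s) c += alpha(t, s);
    if (c <= 0) c = 1e-300;
    for (int s = 0; s < n; ++s) alpha(t, s) /= c;
    cvec[t] = c;
    ll += std::log(c);
  }
  return ll;
}

// Backward pass computing macro-state posteriors and (optionally) the
// expected transition counts needed for EM. beta is kept as two rolling rows.
static void backward_pass(const NumericMatrix& E, const NumericMatrix& trans,
                          int dW, int dD, const NumericMatrix& alpha,
                          const NumericVector& cvec, NumericMatrix& gamma,
                          bool want_xi, double* xi /* xi00,xi01,xi0f,xill,xil0 */) {
  int T = E.nrow(), n = E.ncol();
  int f = dW + 1, last = dW + dD;
  std::vector<double> bnext(n, 1.0), bcur(n, 0.0);
  // gamma at T-1
  for (int s = 0; s < n; ++s) {
    double g = alpha(T - 1, s);
    gamma(T - 1, macro_of(s, dW)) += g;
  }
  for (int t = T - 2; t >= 0; --t) {
    double pLL = trans(t, 0), pLW = trans(t, 1), pLD = trans(t, 2), pc = trans(t, 3);
    double cn = cvec[t + 1];
    // beta_t(s) = sum_s' a(s,s') E(t+1,s') beta_{t+1}(s') / c_{t+1}
    double eb0 = E(t + 1, 0) * bnext[0] / cn;
    double eb1 = E(t + 1, 1) * bnext[1] / cn;
    double ebf = E(t + 1, f) * bnext[f] / cn;
    double eblast = E(t + 1, last) * bnext[last] / cn;
    bcur[0] = pLL * eb0 + pLW * eb1 + pLD * ebf;
    for (int s = 1; s < dW; ++s) bcur[s] = E(t + 1, s + 1) * bnext[s + 1] / cn;
    bcur[dW] = eb0;
    for (int s = f; s < last; ++s) bcur[s] = E(t + 1, s + 1) * bnext[s + 1] / cn;
    bcur[last] = pc * eblast + (1.0 - pc) * eb0;

    for (int s = 0; s < n; ++s) {
      double g = alpha(t, s) * bcur[s];
      gamma(t, macro_of(s, dW)) += g;
    }
    if (want_xi) {
      double aL = alpha(t, 0), aDlast = alpha(t, last);
      xi[0] += aL * pLL * eb0;            // L -> L
      xi[1] += aL * pLW * eb1;            // L -> W1
      xi[2] += aL * pLD * ebf;            // L -> D1
      xi[3] += aDlast * pc * eblast;      // Dlast -> Dlast
      xi[4] += aDlast * (1.0 - pc) * eb0; // Dlast -> L
    }
    std::swap(bnext, bcur);
  }
  // renormalize gamma rows (guard numeric drift)
  for (int t = 0; t < T; ++t) {
    double s3 = gamma(t, 0) + gamma(t, 1) + gamma(t, 2);
    if (s3 > 0) { gamma(t, 0) /= s3; gamma(t, 1) /= s3; gamma(t, 2) /= s3; }
  }
}

// [[Rcpp::export]]
List hmm_em_window_cpp(NumericVector x, LogicalVector miss, int dW, int dD,
                       NumericVector mu0, NumericVector sd0,
                       NumericVector trans0, int max_iter, double tol,
                       double sd_floor) {
  int T = x.size(), n = 1 + dW + dD;
  double mu[3] = {mu0[0], mu0[1], mu0[2]};
  double sd[3] = {sd0[0], sd0[1], sd0[2]};
  double pLL = trans0[0], pLW = trans0[1], pLD = trans0[2], pc = trans0[3];

  NumericMatrix E(T, n), alpha(T, n);
  NumericVector cvec(T);
  NumericMatrix trans(T, 4);
  NumericMatrix gamma(T, 3);
  double ll_old = R_NegInf, ll = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int t = 0; t < T; ++t) {
      trans(t, 0) = pLL; trans(t, 1) = pLW; trans(t, 2) = pLD; trans(t, 3) = pc;
    }
    fill_emissions(x, miss, dW, dD, mu, sd, E);
    ll = forward_pass(E, trans, dW, dD, alpha, cvec);
    std::fill(gamma.begin(), gamma.end(), 0.0);
    double xi[5] = {0, 0, 0, 0, 0};
    backward_pass(E, trans, dW, dD, alpha, cvec, gamma, true, xi);

    // M-step: transitions
    double fromL = xi[0] + xi[1] + xi[2];
    if (fromL > 0) {
      pLL = xi[0] / fromL; pLW = xi[1] / fromL; pLD = xi[2] / fromL;
      // keep strictly inside (0,1)
      const double eps = 1e-6;
      pLL = std::min(std::max(pLL, eps), 1.0 - 2 * eps);
      pLW = std::min(std::max(pLW, eps), 1.0 - 2 * eps);
      pLD = std::max(1.0 - pLL - pLW, eps);
      double z = pLL + pLW + pLD;
      pLL /= z; pLW /= z; pLD /= z;
    }
    double fromD = xi[3] + xi[4];
    if (fromD > 0) pc = std::min(std::max(xi[3] / fromD, 1e-6), 1.0 - 1e-6);

    // M-step: emissions over observed probes
    double sw[3] = {0, 0, 0}, sx[3] = {0, 0, 0}, sxx[3] = {0, 0, 0};
    for (int t = 0; t < T; ++t) {
      if (miss[t]) continue;
      for (int m = 0; m < 3; ++m) {
        double g = gamma(t, m);
        sw[m] += g; sx[m] += g * x[t]; sxx[m] += g * x[t] * x[t];
      }
    }
    for (int m = 0; m < 3; ++m) {
      if (sw[m] > 1e-8) {
        double mnew = sx[m] / sw[m];
        double v = sxx[m] / sw[m] - mnew * mnew;
        mu[m] = mnew;
        sd[m] = std::sqrt(std::max(v, sd_floor * sd_floor));
      }
    }
    // enforce mean_W >= mean_D >= mean_L by relabeling emission params
    // order macro means: L smallest, D middle, W largest
    int ord[3] = {0, 2, 1}; // target: mu[0] <= mu[2] <= mu[1]
    double mus[3] = {mu[0], mu[1], mu[2]}, sds[3] = {sd[0], sd[1], sd[2]};
    int idx[3] = {0, 1, 2};
    std::sort(idx, idx + 3, [&](int a, int b) { return mus[a] < mus[b]; });
    mu[ord[0]] = mus[idx[0]]; sd[ord[0]] = sds[idx[0]];
    mu[ord[1]] = mus[idx[1]]; sd[ord[1]] = sds[idx[1]];
    mu[ord[2]] = mus[idx[2]]; sd[ord[2]] = sds[idx[2]];

    if (iter > 1 && std::fabs(ll - ll_old) < tol) { converged = true; break; }
    ll_old = ll;
  }

  // final E-step with the converged parameters so posteriors match them
  for (int t = 0; t < T; ++t) {
    trans(t, 0) = pLL; trans(t, 1) = pLW; trans(t, 2) = pLD; trans(t, 3) = pc;
  }
  fill_emissions(x, miss, dW, dD, mu, sd, E);
  ll = forward_pass(E, trans, dW, dD, alpha, cvec);
  std::fill(gamma.begin(), gamma.end(), 0.0);
  double xi[5] = {0, 0, 0, 0, 0};
  backward_pass(E, trans, dW, dD, alpha, cvec, gamma, false, xi);

  return List::create(
    _["mu"] = NumericVector::create(mu[0], mu[1], mu[2]),
    _["sd"] = NumericVector::create(sd[0], sd[1], sd[2]),
    _["trans"] = NumericVector::create(pLL, pLW, pLD, pc),
    _["gamma"] = gamma,
    _["loglik"] = ll,
    _["niter"] = iter,
    _["converged"] = converged);
}

// Position-specific forward-backward: mu/sd are T x 3, trans T x 4.
// [[Rcpp::export]]
List hmm_posterior_cpp(NumericVector x, LogicalVector miss, int dW, int dD,
                       NumericMatrix mu, NumericMatrix sd, NumericMatrix trans) {
  int T = x.size(), n = 1 + dW + dD;
  NumericMatrix E(T, n), alpha(T, n), gamma(T, 3);
  NumericVector cvec(T);
  for (int t = 0; t < T; ++t) {
    double eL = emis(x[t], miss[t], mu(t, 0), sd(t, 0));
    double eW = emis(x[t], miss[t], mu(t, 1), sd(t, 1));
    double eD = emis(x[t], miss[t], mu(t, 2), sd(t, 2));
    E(t, 0) = eL;
    for (int s = 1; s <= dW; ++s) E(t, s) = eW;
    for (int s = dW + 1; s < n; ++s) E(t, s) = eD;
  }
  double ll = forward_pass(E, trans, dW, dD, alpha, cvec);
  double xi[5];
  backward_pass(E, trans, dW, dD, alpha, cvec, gamma, false, xi);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// Position-specific Viterbi over the expanded chain; returns the macro-state
// path (0 = L, 1 = W, 2 = D). Ties are broken toward L (and, within chains,
// toward the earlier-listed state) by strict-improvement comparisons.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, LogicalVector miss, int dW, int dD,
                              NumericMatrix mu, NumericMatrix sd, NumericMatrix trans) {
  int T = x.size(), n = 1 + dW + dD;
  int f = dW + 1, last = dW + dD;
  const double NEG = -1e300;
  std::vector<double> dprev(n), dcur(n);
  IntegerMatrix bp(T, n);

  auto logemis = [&](int t, int m) {
    if (miss[t]) return 0.0;
    double s = sd(t, m), z = (x[t] - mu(t, m)) / s;
    return -0.5 * z * z - std::log(s) - 0.9189385332046727;
  };

  double piL = std::log(1.0 / 3.0), piW = std::log((1.0 / 3.0) / dW),
         piD = std::log((1.0 / 3.0) / dD);
  dprev[0] = piL + logemis(0, 0);
  for (int s = 1; s <= dW; ++s) dprev[s] = piW + logemis(0, 1);
  for (int s = f; s <= last; ++s) dprev[s] = piD + logemis(0, 2);

  for (int t = 1; t < T; ++t) {
    double lLL = std::log(trans(t - 1, 0)), lLW = std::log(trans(t - 1, 1)),
           lLD = std::log(trans(t - 1, 2));
    double lcc = std::log(trans(t - 1, 3)), lcx = std::log(1.0 - trans(t - 1, 3));
    double eL = logemis(t, 0), eW = logemis(t, 1), eD = logemis(t, 2);

    // into L: candidates in order L, W_dW, D_last -> ties prefer L
    double best = dprev[0] + lLL; int arg = 0;
    if (dprev[dW] > best) { best = dprev[dW]; arg = dW; }
    if (dprev[last] + lcx > best) { best = dprev[last] + lcx; arg = last; }
    dcur[0] = best + eL; bp(t, 0) = arg;
    // into W chain
    dcur[1] = dprev[0] + lLW + eW; bp(t, 1) = 0;
    for (int s = 2; s <= dW; ++s) { dcur[s] = dprev[s - 1] + eW; bp(t, s) = s - 1; }
    // into D chain
    double bf = dprev[0] + lLD; int af = 0;
    if (f == last && dprev[last] + lcc > bf) { bf = dprev[last] + lcc; af = last; }
    dcur[f] = bf + eD; bp(t, f) = af;
    for (int s = f + 1; s <= last; ++s) {
      double b = dprev[s - 1]; int a = s - 1;
      if (s == last && dprev[last] + lcc > b) { b = dprev[last] + lcc; a = last; }
      dcur[s] = b + eD; bp(t, s) = a;
    }
    std::swap(dprev, dcur);
  }

  // termination: prefer L on ties (states scanned in order 0..n-1, strict >)
  int s = 0; double best = dprev[0];
  for (int k = 1; k < n; ++k) if (dprev[k] > best) { best = dprev[k]; s = k; }
  IntegerVector path(T);
  for (int t = T - 1; t >= 0; --t) {
    path[t] = macro_of(s, dW);
    if (t > 0) s = bp(t, s);
  }
  return path;
}
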