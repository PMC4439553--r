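// Linear-chain conditional random field over the three BIO states.
// Parameter layout (single flat vector):
//   state weights  w[f + nfeat*y]   f = 0..nfeat-1, y = 0..2
//   transitions    tr[i + 3*j]      score of moving from state i to state j
//   initial        init[y]
// Training minimizes the negative log-likelihood plus an L2 penalty
// c2*||theta||^2; gradients come from forward-backward expectations.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int L = 3;

static inline double logsumexp3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector theta, List seqs, int nfeat, double c2) {
  const double *w = REAL(theta);
  const double *tr = w + (size_t)nfeat * L;
  const double *init = tr + L * L;
  NumericVector grad(theta.size());
  double *gw = REAL(grad);
  double *gtr = gw + (size_t)nfeat * L;
  double *ginit = gtr + L * L;
  double nll = 0.0;

  for (int s = 0; s < seqs.size(); ++s) {
    List seq = seqs[s];
    List feats = seq["feats"];
    IntegerVector labels = seq["labels"];
    int T = feats.size();
    if (T == 0) continue;

    std::vector<double> em((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t) {
      IntegerVector f = feats[t];
      for (int y = 0; y < L; ++y) {
        double v = 0.0;
        for (int k = 0; k < f.size(); ++k) v += w[(f[k] - 1) + (size_t)nfeat * y];
        em[(size_t)t * L + y] = v;
      }
    }

    std::vector<double> alpha((size_t)T * L), beta((size_t)T * L);
    for (int y = 0; y < L; ++y) alpha[y] = init[y] + em[y];
    for (int t = 1; t < T; ++t)
      for (int y = 0; y < L; ++y)
        alpha[(size_t)t * L + y] = em[(size_t)t * L + y] + logsumexp3(
          alpha[(size_t)(t - 1) * L + 0] + tr[0 + L * y],
          alpha[(size_t)(t - 1) * L + 1] + tr[1 + L * y],
          alpha[(size_t)(t - 1) * L + 2] + tr[2 + L * y]);
    for (int y = 0; y < L; ++y) beta[(size_t)(T - 1) * L + y] = 0.0;
    for (int t = T - 2; t >= 0; --t)
      for (int i = 0; i < L; ++i)
        beta[(size_t)t * L + i] = logsumexp3(
          tr[i + L * 0] + em[(size_t)(t + 1) * L + 0] + beta[(size_t)(t + 1) * L + 0],
          tr[i + L * 1] + em[(size_t)(t + 1) * L + 1] + beta[(size_t)(t + 1) * L + 1],
          tr[i + L * 2] + em[(size_t)(t + 1) * L + 2] + beta[(size_t)(t + 1) * L + 2]);

    double logZ = logsumexp3(alpha[(size_t)(T - 1) * L + 0],
                             alpha[(size_t)(T - 1) * L + 1],
                             alpha[(size_t)(T - 1) * L + 2]);

    double gold = init[labels[0] - 1] + em[labels[0] - 1];
    for (int t = 1; t < T; ++t)
      gold += tr[(labels[t - 1] - 1) + L * (labels[t] - 1)] +
              em[(size_t)t * L + (labels[t] - 1)];
    nll += logZ - gold;

    // state-feature expectations minus empirical counts
    for (int t = 0; t < T; ++t) {
      IntegerVector f = feats[t];
      for (int y = 0; y < L; ++y) {
        double p = std::exp(alpha[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ);
        double d = p - (labels[t] - 1 == y ? 1.0 : 0.0);
        if (d != 0.0)
          for (int k = 0; k < f.size(); ++k)
            gw[(f[k] - 1) + (size_t)nfeat * y] += d;
      }
    }
    // initial-state expectations
    for (int y = 0; y < L; ++y)
      ginit[y] += std::exp(alpha[y] + beta[y] - logZ) -
                  (labels[0] - 1 == y ? 1.0 : 0.0);
    // transition expectations
    for (int t = 1; t < T; ++t) {
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j)
          gtr[i + L * j] += std::exp(alpha[(size_t)(t - 1) * L + i] + tr[i + L * j] +
                                     em[(size_t)t * L + j] +
                                     beta[(size_t)t * L + j] - logZ);
      gtr[(labels[t - 1] - 1) + L * (labels[t] - 1)] -= 1.0;
    }
  }

  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    nll += c2 * w[i] * w[i];
    grad[i] += 2.0 * c2 * w[i];
  }
  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(List feats, NumericVector theta, int nfeat) {
  const double *w = REAL(theta);
  const double *tr = w + (size_t)nfeat * L;
  const double *init = tr + L * L;
  int T = feats.size();
  IntegerVector path(T);
  if (T == 0) return path;

  std::vector<double> em((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    for (int y = 0; y < L; ++y) {
      double v = 0.0;
      for (int k = 0; k < f.size(); ++k) v += w[(f[k] - 1) + (size_t)nfeat * y];
      em[(size_t)t * L + y] = v;
    }
  }
  std::vector<double> delta((size_t)T * L);
  std::vector<int> back((size_t)T * L, 0);
  for (int y = 0; y < L; ++y) delta[y] = init[y] + em[y];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < L; ++y) {
      int best = 0;
      double bv = delta[(size_t)(t - 1) * L] + tr[0 + L * y];
      for (int i = 1; i < L; ++i) {
        double v = delta[(size_t)(t - 1) * L + i] + tr[i + L * y];
        if (v > bv) { bv = v; best = i; }
      }
      delta[(size_t)t * L + y] = bv + em[(size_t)t * L + y];
      back[(size_t)t * L + y] = best;
    }
  }
  int y = 0;
  for (int i = 1; i < L; ++i)
    if (delta[(size_t)(T - 1) * L + i] > delta[(size_t)(T - 1) * L + y]) y = i;
  for (int t = T - 1; t >= 0; --t) {
    path[t] = y + 1;
    y = back[(size_t)t * L + y];
  }
  return path;
}
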