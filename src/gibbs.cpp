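// Gibbs sampler for the admixture model with genotype uncertainty.
//
// Model: each of the two allele copies of individual i at locus l draws an
// ancestry z ~ Categorical(q_i) and an allele ~ Bernoulli(p_{z,l}); the
// observed data enter only through the genotype likelihoods GL_{il}(g).
// Priors: q_i ~ Dirichlet(1,...,1), p_{kl} ~ Beta(1,1). The sweep samples
// genotypes g | GL, q, p; copy ancestries | g; then conjugate updates of p
// (Beta) and q (Dirichlet). Uses R's RNG so set.seed() governs everything.

#include <Rcpp.h>
using namespace Rcpp;

static inline int sampleCategorical3(double w0, double w1, double w2) {
  double tot = w0 + w1 + w2;
  double u = unif_rand() * tot;
  if (u < w0) return 0;
  if (u < w0 + w1) return 1;
  return 2;
}

static inline int sampleCategoricalK(const std::vector<double> &w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot;
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u < c) return k;
  }
  return K - 1;
}

// [[Rcpp::export(name = ".gibbsAdmixtureCpp")]]
List gibbsAdmixtureCpp(NumericMatrix gl0, NumericMatrix gl1,
                       NumericMatrix gl2, NumericMatrix qInit,
                       NumericMatrix pInit, int nSteps, int burnIn,
                       int thin) {
  const int L = gl0.nrow(), N = gl0.ncol();
  const int K = qInit.ncol();
  if (qInit.nrow() != N) stop("qInit must be N x K");
  if (pInit.nrow() != K || pInit.ncol() != L) stop("pInit must be K x L");

  NumericMatrix q(clone(qInit));          // N x K
  NumericMatrix p(clone(pInit));          // K x L
  NumericMatrix qSum(N, K), pSum(K, L);
  NumericMatrix gpost0(L, N), gpost1(L, N), gpost2(L, N);
  std::vector<double> devKeep;
  std::vector<double> wk(K);
  // per-sweep sufficient statistics
  NumericMatrix altCnt(K, L), refCnt(K, L);
  NumericMatrix nIK(N, K);
  int nKeep = 0;

  for (int step = 0; step < nSteps; ++step) {
    std::fill(altCnt.begin(), altCnt.end(), 0.0);
    std::fill(refCnt.begin(), refCnt.end(), 0.0);
    std::fill(nIK.begin(), nIK.end(), 0.0);
    const bool keep = (step >= burnIn) && ((step - burnIn) % thin == 0);
    double dev = 0.0;

    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        double m = 0.0;
        for (int k = 0; k < K; ++k) m += q(i, k) * p(k, l);
        const double l0 = gl0(l, i), l1 = gl1(l, i), l2 = gl2(l, i);
        if (!R_finite(l0) || !R_finite(l1) || !R_finite(l2))
          stop("non-finite genotype likelihood at site %d", l + 1);
        const double w0 = l0 * (1.0 - m) * (1.0 - m);
        const double w1 = l1 * 2.0 * m * (1.0 - m);
        const double w2 = l2 * m * m;
        const double tot = w0 + w1 + w2;
        if (keep) {
          dev += -2.0 * std::log(std::max(tot, 1e-300));
          gpost0(l, i) += w0 / tot;
          gpost1(l, i) += w1 / tot;
          gpost2(l, i) += w2 / tot;
        }
        const int g = sampleCategorical3(w0, w1, w2);
        // ancestries of the two copies given the genotype
        const int nAlt = g, nRef = 2 - g;
        for (int c = 0; c < nAlt; ++c) {
          for (int k = 0; k < K; ++k) wk[k] = q(i, k) * p(k, l);
          const int z = sampleCategoricalK(wk, K);
          altCnt(z, l) += 1.0;
          nIK(i, z) += 1.0;
        }
        for (int c = 0; c < nRef; ++c) {
          for (int k = 0; k < K; ++k) wk[k] = q(i, k) * (1.0 - p(k, l));
          const int z = sampleCategoricalK(wk, K);
          refCnt(z, l) += 1.0;
          nIK(i, z) += 1.0;
        }
      }
    }
    // conjugate updates
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        p(k, l) = R::rbeta(1.0 + altCnt(k, l), 1.0 + refCnt(k, l));
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        wk[k] = R::rgamma(1.0 + nIK(i, k), 1.0);
        s += wk[k];
      }
      for (int k = 0; k < K; ++k) q(i, k) = wk[k] / s;
    }
    if (keep) {
      ++nKeep;
      devKeep.push_back(dev);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qSum(i, k) += q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) pSum(k, l) += p(k, l);
    }
  }
  if (nKeep == 0) stop("no retained samples: check nSteps/burnIn/thin");
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) qSum(i, k) /= nKeep;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) pSum(k, l) /= nKeep;
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < N; ++i) {
      gpost0(l, i) /= nKeep;
      gpost1(l, i) /= nKeep;
      gpost2(l, i) /= nKeep;
    }
  return List::create(_["q"] = qSum, _["p"] = pSum,
                      _["gpost0"] = gpost0, _["gpost1"] = gpost1,
                      _["gpost2"] = gpost2,
                      _["deviance"] = NumericVector(devKeep.begin(),
                                                    devKeep.end()),
                      _["nKeep"] = nKeep);
}
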