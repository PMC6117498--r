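#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampling for LDA / labeled-LDA.
//
// Topic assignments are integrated over theta and phi; each token's topic is
// resampled from
//   p(z_i = k | z_-i, w) ∝ (n_dk + alpha) * (n_kw + beta) / (n_k + V * beta)
// restricted to the document's allowed topic set (labeled-LDA). Plain LDA is
// the special case where every document allows all K topics, so the two share
// one code path and, under the same seed, an identical random-number trace.
//
// RNG: R's uniform stream (unif_rand), consumed in a fixed order — documents
// in corpus order, tokens in sequence order, one draw per token per sweep
// (plus one per token at initialization) — so set.seed() in R makes runs
// bit-reproducible.

static inline double cond_weight(int ndk, int nkw, int nk,
                                 double alpha, double beta, double vbeta) {
  return (ndk + alpha) * (nkw + beta) / (nk + vbeta);
}

static void verify_counts(const std::vector<std::vector<int> >& w,
                          const std::vector<std::vector<int> >& z,
                          const IntegerMatrix& n_dk,
                          const IntegerMatrix& n_kw,
                          const IntegerVector& n_k,
                          int K, int V) {
  int M = w.size();
  IntegerMatrix dk(M, K), kw(K, V);
  IntegerVector kk(K);
  for (int d = 0; d < M; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      dk(d, z[d][i])++;
      kw(z[d][i], w[d][i])++;
      kk[z[d][i]]++;
    }
  }
  for (int d = 0; d < M; ++d) {
    long rs = 0;
    for (int k = 0; k < K; ++k) {
      if (dk(d, k) != n_dk(d, k)) stop("count invariant violated: n_dk");
      rs += n_dk(d, k);
    }
    if (rs != (long)w[d].size()) stop("count invariant violated: sum_k n_dk != N_d");
  }
  for (int k = 0; k < K; ++k) {
    long rs = 0;
    for (int v = 0; v < V; ++v) {
      if (kw(k, v) != n_kw(k, v)) stop("count invariant violated: n_kw");
      rs += n_kw(k, v);
    }
    if (kk[k] != n_k[k] || rs != (long)n_k[k])
      stop("count invariant violated: n_k");
  }
}

// docs: list of 0-based word-index vectors; allowed: list of 0-based topic
// index vectors (ascending). Returns final counts, assignments and
// theta/phi estimates (averaged over post-burn-in samples at sample_lag
// spacing when average is true and samples exist, else from final counts).
// [[Rcpp::export]]
List gibbs_lda_cpp(const List& docs, const List& allowed, int K, int V,
                   double alpha, double beta, int iterations, int burn_in,
                   int sample_lag, bool average, bool check_invariants) {
  int M = docs.size();
  if (M == 0) stop("empty corpus");
  if (sample_lag < 1) sample_lag = 1;
  double vbeta = V * beta;

  std::vector<std::vector<int> > w(M), a(M), z(M);
  for (int d = 0; d < M; ++d) {
    IntegerVector wd = docs[d];
    IntegerVector ad = allowed[d];
    if (ad.size() == 0) stop("document with empty allowed topic set");
    w[d].assign(wd.begin(), wd.end());
    a[d].assign(ad.begin(), ad.end());
    z[d].resize(wd.size());
  }

  IntegerMatrix n_dk(M, K), n_kw(K, V);
  IntegerVector n_k(K);

  // init: uniform over the allowed set, one draw per token
  for (int d = 0; d < M; ++d) {
    int A = a[d].size();
    for (size_t i = 0; i < w[d].size(); ++i) {
      int j = (int)(unif_rand() * A);
      if (j >= A) j = A - 1;
      int k = a[d][j];
      z[d][i] = k;
      n_dk(d, k)++;
      n_kw(k, w[d][i])++;
      n_k[k]++;
    }
  }

  NumericMatrix theta_sum(M, K), phi_sum(K, V);
  int n_samples = 0;
  std::vector<double> p(K);

  for (int iter = 1; iter <= iterations; ++iter) {
    for (int d = 0; d < M; ++d) {
      const std::vector<int>& ad = a[d];
      int A = ad.size();
      for (size_t i = 0; i < w[d].size(); ++i) {
        int word = w[d][i];
        int old = z[d][i];
        n_dk(d, old)--;
        n_kw(old, word)--;
        n_k[old]--;
        double total = 0.0;
        for (int j = 0; j < A; ++j) {
          int k = ad[j];
          p[j] = cond_weight(n_dk(d, k), n_kw(k, word), n_k[k],
                             alpha, beta, vbeta);
          total += p[j];
        }
        double u = unif_rand() * total, cum = 0.0;
        int jn = A - 1;
        for (int j = 0; j < A; ++j) {
          cum += p[j];
          if (u <= cum) { jn = j; break; }
        }
        int knew = ad[jn];
        z[d][i] = knew;
        n_dk(d, knew)++;
        n_kw(knew, word)++;
        n_k[knew]++;
      }
    }
    if (check_invariants) verify_counts(w, z, n_dk, n_kw, n_k, K, V);
    if (average && iter > burn_in && (iter - burn_in) % sample_lag == 0) {
      for (int d = 0; d < M; ++d) {
        double denom = w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (n_dk(d, k) + alpha) / denom;
      }
      for (int k = 0; k < K; ++k) {
        double denom = n_k[k] + vbeta;
        for (int v = 0; v < V; ++v)
          phi_sum(k, v) += (n_kw(k, v) + beta) / denom;
      }
      n_samples++;
    }
  }

  NumericMatrix theta(M, K), phi(K, V);
  if (n_samples > 0) {
    for (int d = 0; d < M; ++d)
      for (int k = 0; k < K; ++k) theta(d, k) = theta_sum(d, k) / n_samples;
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) phi(k, v) = phi_sum(k, v) / n_samples;
  } else {
    for (int d = 0; d < M; ++d) {
      double denom = w[d].size() + K * alpha;
      for (int k = 0; k < K; ++k) theta(d, k) = (n_dk(d, k) + alpha) / denom;
    }
    for (int k = 0; k < K; ++k) {
      double denom = n_k[k] + vbeta;
      for (int v = 0; v < V; ++v) phi(k, v) = (n_kw(k, v) + beta) / denom;
    }
  }

  List zz(M);
  for (int d = 0; d < M; ++d) zz[d] = IntegerVector(z[d].begin(), z[d].end());
  return List::create(_["z"] = zz, _["n_dk"] = n_dk, _["n_kw"] = n_kw,
                      _["n_k"] = n_k, _["theta"] = theta, _["phi"] = phi,
                      _["n_samples"] = n_samples);
}

// Fold-in inference: phi held fixed, per-document topic counts resampled with
//   p(z_i = k) ∝ (n_dk + alpha) * phi[k, w].
// Empty documents get the prior-only (uniform) row.
// [[Rcpp::export]]
NumericMatrix gibbs_foldin_cpp(const List& docs, const NumericMatrix& phi,
                               double alpha, int iterations, int burn_in,
                               int sample_lag) {
  int M = docs.size();
  int K = phi.nrow();
  if (sample_lag < 1) sample_lag = 1;
  NumericMatrix theta(M, K);
  std::vector<double> p(K);

  for (int d = 0; d < M; ++d) {
    IntegerVector wd = docs[d];
    int Nd = wd.size();
    if (Nd == 0) {
      for (int k = 0; k < K; ++k) theta(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> zd(Nd);
    std::vector<int> ndk(K, 0);
    for (int i = 0; i < Nd; ++i) {
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      zd[i] = k;
      ndk[k]++;
    }
    std::vector<double> tsum(K, 0.0);
    int n_samples = 0;
    for (int iter = 1; iter <= iterations; ++iter) {
      for (int i = 0; i < Nd; ++i) {
        int word = wd[i];
        ndk[zd[i]]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk[k] + alpha) * phi(k, word);
          total += p[k];
        }
        double u = unif_rand() * total, cum = 0.0;
        int kn = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += p[k];
          if (u <= cum) { kn = k; break; }
        }
        zd[i] = kn;
        ndk[kn]++;
      }
      if (iter > burn_in && (iter - burn_in) % sample_lag == 0) {
        double denom = Nd + K * alpha;
        for (int k = 0; k < K; ++k) tsum[k] += (ndk[k] + alpha) / denom;
        n_samples++;
      }
    }
    double denom = Nd + K * alpha;
    for (int k = 0; k < K; ++k)
      theta(d, k) = n_samples > 0 ? tsum[k] / n_samples
                                  : (ndk[k] + alpha) / denom;
  }
  return theta;
}

// One-step conditional p(z = k | everything else) for a single token whose
// counts have already been decremented, over the allowed (0-based) topic set.
// This is the exact distribution the sampler draws from.
// [[Rcpp::export]]
NumericVector lda_conditional_cpp(const IntegerVector& n_dk_d,
                                  const IntegerMatrix& n_kw,
                                  const IntegerVector& n_k, int word,
                                  const IntegerVector& allowed,
                                  double alpha, double beta) {
  int V = n_kw.ncol();
  double vbeta = V * beta;
  int A = allowed.size();
  NumericVector out(A);
  double total = 0.0;
  for (int j = 0; j < A; ++j) {
    int k = allowed[j];
    out[j] = cond_weight(n_dk_d[k], n_kw(k, word), n_k[k], alpha, beta, vbeta);
    total += out[j];
  }
  for (int j = 0; j < A; ++j) out[j] /= total;
  return out;
}
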