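#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation with
// symmetric priors. Documents arrive as 0-based word-id vectors.
// Uses R's RNG so results are reproducible under set.seed().
// Returns the topic-word count matrix after the final sweep.
// [[Rcpp::export]]
List lda_gibbs(List docs, int V, int K, double alpha, double beta,
               int n_iter) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D), z(D);
  IntegerMatrix ndk(D, K);   // doc-topic counts
  IntegerMatrix nkw(K, V);   // topic-word counts
  IntegerVector nk(K);       // topic totals

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int N = doc.size();
    w[d].resize(N);
    z[d].resize(N);
    for (int i = 0; i < N; ++i) {
      w[d][i] = doc[i];
      int t = (int)(unif_rand() * K);
      if (t == K) t = K - 1;
      z[d][i] = t;
      ndk(d, t)++;
      nkw(t, w[d][i])++;
      nk[t]++;
    }
  }

  std::vector<double> p(K);
  double Vbeta = V * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      int N = w[d].size();
      for (int i = 0; i < N; ++i) {
        int wi = w[d][i], t = z[d][i];
        ndk(d, t)--; nkw(t, wi)--; nk[t]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk(d, k) + alpha) * (nkw(k, wi) + beta) / (nk[k] + Vbeta);
          total += p[k];
        }
        double u = unif_rand() * total, cum = 0.0;
        int tnew = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += p[k];
          if (u <= cum) { tnew = k; break; }
        }
        z[d][i] = tnew;
        ndk(d, tnew)++; nkw(tnew, wi)++; nk[tnew]++;
      }
    }
  }

  return List::create(_["nkw"] = nkw, _["ndk"] = ndk, _["nk"] = nk);
}
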