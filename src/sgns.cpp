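// Skip-gram word2vec with negative sampling, single-threaded and seeded so
// embedding training is reproducible. Corpus sentences are single tokenized
// molecules; ids are 1-based from R.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat sgns_train(Rcpp::List corpus, int vocab, int dim, int window,
                     int epochs, int negatives, double lr,
                     unsigned int seed) {
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(-0.5, 0.5);
  mat W(vocab, dim), C(vocab, dim, fill::zeros);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = unif(rng) / dim;

  // unigram^(3/4) table for negative sampling
  std::vector<double> freq(vocab, 0.0);
  std::vector<std::vector<int>> sents(corpus.size());
  for (int i = 0; i < corpus.size(); ++i) {
    Rcpp::IntegerVector v = corpus[i];
    sents[i].resize(v.size());
    for (int j = 0; j < v.size(); ++j) {
      sents[i][j] = v[j] - 1;
      freq[v[j] - 1] += 1.0;
    }
  }
  std::vector<double> cum(vocab);
  double tot = 0;
  for (int i = 0; i < vocab; ++i) { tot += std::pow(freq[i], 0.75); cum[i] = tot; }
  if (tot <= 0) Rcpp::stop("empty corpus");
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  auto draw_negative = [&]() {
    double r = u01(rng) * tot;
    return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
  };

  std::uniform_int_distribution<int> win_draw(1, window);
  rowvec grad_in(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (auto& s : sents) {
      int n = s.size();
      for (int t = 0; t < n; ++t) {
        int b = win_draw(rng);  // dynamic window, word2vec convention
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int ci = t + off;
          if (ci < 0 || ci >= n) continue;
          int w = s[t], ctx = s[ci];
          grad_in.zeros();
          for (int neg = 0; neg <= negatives; ++neg) {
            int target; double label;
            if (neg == 0) { target = ctx; label = 1.0; }
            else {
              target = draw_negative();
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = dot(W.row(w), C.row(target));
            double sig = 1.0 / (1.0 + std::exp(-f));
            double gduce = lr * (label - sig);
            grad_in += gduce * C.row(target);
            C.row(target) += gduce * W.row(w);
          }
          W.row(w) += grad_in;
        }
      }
    }
  }
  return W;
}
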