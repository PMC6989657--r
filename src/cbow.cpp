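// Continuous bag-of-words embeddings with negative sampling. Single-threaded
// SGD; the context window is randomly shrunk per position and negatives are
// drawn from the unigram distribution raised to 3/4, following the reference
// formulation. Randomness comes from R's RNG for reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline double sigmoid(double z) {
  if (z > 10.0) return 1.0;
  if (z < -10.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-z));
}

// [[Rcpp::export]]
NumericMatrix cpp_train_cbow(List docs, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int negative, int iterations, double alpha0) {
  // negative-sampling table: cumulative unigram^{3/4}
  vec cum(vocab_size);
  double acc = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    acc += std::pow(counts[i], 0.75);
    cum(i) = acc;
  }
  cum /= acc;

  mat syn0(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int j = 0; j < dim; ++j)
      syn0(i, j) = (unif_rand() - 0.5) / dim;
  mat syn1(vocab_size, dim, fill::zeros);

  std::vector<std::vector<int>> dd(docs.size());
  long long total_words = 0;
  for (int i = 0; i < docs.size(); ++i) {
    IntegerVector v = docs[i];
    dd[i].assign(v.begin(), v.end());
    total_words += v.size();
  }
  const double total_steps = (double)total_words * iterations + 1.0;
  long long processed = 0;

  rowvec h(dim), neu1e(dim);
  for (int it = 0; it < iterations; ++it) {
    for (const auto& doc : dd) {
      const int L = doc.size();
      for (int t = 0; t < L; ++t, ++processed) {
        double alpha = alpha0 * (1.0 - processed / total_steps);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int shrink = (int)(unif_rand() * window);
        const int win = window - shrink;
        int lo = std::max(0, t - win), hi = std::min(L - 1, t + win);
        int n_ctx = 0;
        h.zeros();
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          h += syn0.row(doc[c]);
          ++n_ctx;
        }
        if (n_ctx == 0) continue;
        h /= (double)n_ctx;
        neu1e.zeros();
        for (int k = 0; k <= negative; ++k) {
          int target;
          double label;
          if (k == 0) {
            target = doc[t];
            label = 1.0;
          } else {
            // binary search in the cumulative table
            double u = unif_rand();
            int loi = 0, hii = vocab_size - 1;
            while (loi < hii) {
              int mid = (loi + hii) / 2;
              if (cum(mid) < u) loi = mid + 1; else hii = mid;
            }
            target = loi;
            if (target == doc[t]) continue;
            label = 0.0;
          }
          const double f = sigmoid(dot(h, syn1.row(target)));
          const double g = (label - f) * alpha;
          neu1e += g * syn1.row(target);
          syn1.row(target) += g * h;
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          syn0.row(doc[c]) += neu1e;
        }
      }
    }
  }
  return wrap(syn0);
}
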