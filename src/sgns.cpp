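#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus.
//
// Single-threaded SGD in canonical word2vec order (walk by walk, position by
// position, dynamic window shrink b ~ U{0..window-1}), so the result is fully
// deterministic given the seed. Noise distribution is unigram^0.75 over the
// corpus. Input vectors start at U(-0.5, 0.5)/dim, context vectors at zero;
// epochs = 0 returns that seeded initialization unchanged.
//
// walks: list of integer vectors with 1-based vocabulary ids.
// Returns input and context matrices (vocab_size x dim).
// subsample: frequent-token subsampling threshold t (0 disables); token with
// corpus frequency f is kept with prob (sqrt(f/(t*N)) + 1) * t*N / f.
// [[Rcpp::export]]
List sgns_train(List walks, int vocab_size, int dim, int window, int negatives,
                int epochs, double lr, bool decay, double subsample, int seed) {
  if (vocab_size < 1) stop("vocab_size must be >= 1");
  if (dim < 1) stop("dim must be >= 1");
  if (window < 1) stop("window must be >= 1");
  if (negatives < 0) stop("negatives must be >= 0");
  if (epochs < 0) stop("epochs must be >= 0");

  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const size_t V = static_cast<size_t>(vocab_size);
  const size_t D = static_cast<size_t>(dim);
  std::vector<double> syn0(V * D), syn1(V * D, 0.0);
  for (size_t i = 0; i < V * D; ++i) syn0[i] = (unif(rng) - 0.5) / dim;

  // corpus as flat sentences
  const int n_walks = walks.size();
  std::vector<std::vector<int> > corpus(n_walks);
  std::vector<double> counts(V, 0.0);
  double total_tokens = 0.0;
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector iv = walks[w];
    corpus[w].assign(iv.begin(), iv.end());
    for (int tok : corpus[w]) {
      if (tok < 1 || tok > vocab_size) stop("walk token id out of range");
      counts[tok - 1] += 1.0;
      total_tokens += 1.0;
    }
  }

  // cumulative unigram^0.75 noise table
  std::vector<double> cum(V, 0.0);
  double z = 0.0;
  for (size_t i = 0; i < V; ++i) {
    z += std::pow(counts[i], 0.75);
    cum[i] = z;
  }
  bool have_noise = z > 0.0;

  std::vector<double> keep_prob(V, 1.0);
  if (subsample > 0.0 && total_tokens > 0.0) {
    const double tn = subsample * total_tokens;
    for (size_t i = 0; i < V; ++i) {
      if (counts[i] > tn) {
        keep_prob[i] = (std::sqrt(counts[i] / tn) + 1.0) * tn / counts[i];
        if (keep_prob[i] > 1.0) keep_prob[i] = 1.0;
      }
    }
  }

  std::vector<double> neu1e(D);
  double processed = 0.0;
  const double total_work = total_tokens * std::max(epochs, 1) + 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      // per-sentence subsampled view, as in canonical word2vec
      std::vector<int> sen;
      sen.reserve(corpus[w].size());
      for (int tok : corpus[w]) {
        if (keep_prob[tok - 1] >= 1.0 || unif(rng) < keep_prob[tok - 1]) {
          sen.push_back(tok);
        }
      }
      const int slen = static_cast<int>(sen.size());
      for (int pos = 0; pos < slen; ++pos) {
        double alpha = lr;
        if (decay) {
          alpha = lr * std::max(1.0 - processed / total_work, 1e-4);
        }
        processed += 1.0;
        const int center = sen[pos] - 1;
        const int b = static_cast<int>(rng() % static_cast<uint64_t>(window));
        for (int a = b; a < 2 * window + 1 - b; ++a) {
          if (a == window) continue;
          const int pos2 = pos - window + a;
          if (pos2 < 0 || pos2 >= slen) continue;
          const int context = sen[pos2] - 1;
          double *u = &syn0[static_cast<size_t>(center) * D];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int s = 0; s < negatives + 1; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = context;
              label = 1.0;
            } else {
              if (!have_noise) break;
              const double r = unif(rng) * z;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *v = &syn1[static_cast<size_t>(target) * D];
            double dot = 0.0;
            for (size_t d = 0; d < D; ++d) dot += u[d] * v[d];
            const double f = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - f) * alpha;
            for (size_t d = 0; d < D; ++d) neu1e[d] += g * v[d];
            for (size_t d = 0; d < D; ++d) v[d] += g * u[d];
          }
          for (size_t d = 0; d < D; ++d) u[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix input(vocab_size, dim), output(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i) {
    for (int d = 0; d < dim; ++d) {
      input(i, d) = syn0[static_cast<size_t>(i) * D + d];
      output(i, d) = syn1[static_cast<size_t>(i) * D + d];
    }
  }
  return List::create(_["input"] = input, _["output"] = output);
}
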