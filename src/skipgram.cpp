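#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic portable RNG (same linear congruential step as the classic
// word2vec implementation); avoids compiler-dependent std::distribution
// behaviour so trained matrices are bit-identical across platforms.
static inline std::uint64_t lcg_next(std::uint64_t &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return state;
}

static inline double lcg_unif(std::uint64_t &state) {
  return (double)(lcg_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0 - 1e-12;
  if (x < -8.0) return 1e-12;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling, single thread, fixed (non-shrinking)
// symmetric window. Returns input-side vectors, per-epoch mean loss and the
// number of (center, context) pairs per epoch.
// [[Rcpp::export]]
List sgns_train_cpp(List sentences, NumericMatrix init, NumericVector counts,
                    int window, int epochs, int negatives,
                    double lr_start, double lr_end, double seed) {
  const int V = init.nrow();
  const int d = init.ncol();

  std::vector< std::vector<int> > sents;
  sents.reserve(sentences.size());
  long long total_tokens = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    std::vector<int> v(s.begin(), s.end());
    total_tokens += (long long)v.size();
    sents.push_back(std::move(v));
  }

  std::vector<float> syn0((size_t)V * d), syn1((size_t)V * d, 0.0f);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < d; ++j)
      syn0[(size_t)i * d + j] = (float)init(i, j);

  // unigram^0.75 noise distribution as a cumulative table
  std::vector<double> cum(V);
  double z = 0.0;
  for (int i = 0; i < V; ++i) { z += std::pow((double)counts[i], 0.75); cum[i] = z; }

  std::uint64_t rng = (std::uint64_t)seed * 2654435761ULL + 1ULL;
  const long long total_steps = std::max((long long)1, total_tokens * (long long)epochs);
  long long processed = 0;

  NumericVector epoch_loss(epochs);
  NumericVector epoch_pairs(epochs);
  std::vector<float> grad_in(d);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long long n_pairs = 0;
    for (size_t si = 0; si < sents.size(); ++si) {
      const std::vector<int> &s = sents[si];
      const int T = (int)s.size();
      for (int t = 0; t < T; ++t) {
        double lr = lr_start + (lr_end - lr_start) * ((double)processed / (double)total_steps);
        ++processed;
        const int center = s[t];
        float *vin = &syn0[(size_t)center * d];
        const int lo = std::max(0, t - window);
        const int hi = std::min(T - 1, t + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == t) continue;
          const int context = s[j];
          ++n_pairs;
          std::fill(grad_in.begin(), grad_in.end(), 0.0f);
          for (int k = 0; k <= negatives; ++k) {
            int target; double label;
            if (k == 0) { target = context; label = 1.0; }
            else {
              double r = lcg_unif(rng) * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == context) continue;
              label = 0.0;
            }
            float *vout = &syn1[(size_t)target * d];
            // 4 independent accumulators so the reduction vectorizes
            float f0 = 0.f, f1 = 0.f, f2 = 0.f, f3 = 0.f;
            int c = 0;
            for (; c + 3 < d; c += 4) {
              f0 += vin[c] * vout[c];
              f1 += vin[c + 1] * vout[c + 1];
              f2 += vin[c + 2] * vout[c + 2];
              f3 += vin[c + 3] * vout[c + 3];
            }
            for (; c < d; ++c) f0 += vin[c] * vout[c];
            const double f = (double)((f0 + f1) + (f2 + f3));
            const double p = sigmoid(f);
            loss -= label > 0.5 ? std::log(p) : std::log(1.0 - p);
            const float g = (float)((label - p) * lr);
            float *gi = grad_in.data();
            for (int c2 = 0; c2 < d; ++c2) {
              gi[c2] += g * vout[c2];
              vout[c2] += g * vin[c2];
            }
          }
          for (int c = 0; c < d; ++c) vin[c] += grad_in[c];
        }
      }
    }
    epoch_loss[ep] = n_pairs > 0 ? loss / (double)n_pairs : NA_REAL;
    epoch_pairs[ep] = (double)n_pairs;
  }

  NumericMatrix out(V, d);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < d; ++j)
      out(i, j) = (double)syn0[(size_t)i * d + j];

  return List::create(
    _["vectors"] = out,
    _["epoch_loss"] = epoch_loss,
    _["epoch_pairs"] = epoch_pairs
  );
}
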