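// Skip-gram training with hierarchical softmax over random-walk corpora.
// Self-contained and single-threaded so embeddings are bit-reproducible for
// a given seed; the RNG is an explicit xorshift64* stream, independent of R's
// global generator.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Huffman coding of the vocabulary by frequency (word2vec construction).
struct Huffman {
  std::vector<std::vector<int> > code;   // per word: 0/1 bits
  std::vector<std::vector<int> > point;  // per word: inner-node indices
};

Huffman build_huffman(const std::vector<long>& counts) {
  int vocab = counts.size();
  std::vector<long> count(2 * vocab + 1);
  std::vector<int> binary(2 * vocab + 1, 0), parent(2 * vocab + 1, 0);
  for (int i = 0; i < vocab; ++i) count[i] = counts[i];
  for (int i = vocab; i < 2 * vocab; ++i) count[i] = 1000000000000L;
  int pos1 = vocab - 1, pos2 = vocab;
  int min1i, min2i;
  for (int i = 0; i < vocab - 1; ++i) {
    if (pos1 >= 0) {
      if (count[pos1] < count[pos2]) min1i = pos1--; else min1i = pos2++;
    } else min1i = pos2++;
    if (pos1 >= 0) {
      if (count[pos1] < count[pos2]) min2i = pos1--; else min2i = pos2++;
    } else min2i = pos2++;
    count[vocab + i] = count[min1i] + count[min2i];
    parent[min1i] = vocab + i;
    parent[min2i] = vocab + i;
    binary[min2i] = 1;
  }
  Huffman h;
  h.code.resize(vocab);
  h.point.resize(vocab);
  for (int w = 0; w < vocab; ++w) {
    std::vector<int> code, point;
    if (vocab == 1) {  // degenerate single-word vocabulary: no inner nodes
      h.code[w] = code;
      h.point[w] = point;
      continue;
    }
    int node = w;
    while (node != 2 * vocab - 2) {
      code.push_back(binary[node]);
      point.push_back(parent[node] - vocab);
      node = parent[node];
    }
    // root-to-leaf order
    std::vector<int> rc(code.rbegin(), code.rend());
    std::vector<int> rp(point.rbegin(), point.rend());
    h.code[w] = rc;
    h.point[w] = rp;
  }
  return h;
}

}  // namespace

// [[Rcpp::export]]
List sg_train_cpp(List walks, int vocab, int dim, int window, int epochs,
                  double alpha0, double min_alpha, double seed,
                  NumericVector counts) {
  std::vector<long> cnt(vocab);
  for (int i = 0; i < vocab; ++i) cnt[i] = (long)counts[i];
  Huffman h = build_huffman(cnt);

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)std::max(vocab - 1, 1) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / dim;

  long total_words = 0;
  int n_walks = walks.size();
  std::vector<std::vector<int> > corpus(n_walks);
  for (int s = 0; s < n_walks; ++s) {
    IntegerVector w = walks[s];
    corpus[s] = std::vector<int>(w.begin(), w.end());
    total_words += w.size();
  }
  total_words *= epochs;

  std::vector<double> neu1e(dim);
  long word_count = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_walks; ++s) {
      const std::vector<int>& sen = corpus[s];
      int len = sen.size();
      for (int i = 0; i < len; ++i) {
        ++word_count;
        double alpha = alpha0 * (1.0 - (double)word_count / (total_words + 1));
        if (alpha < min_alpha) alpha = min_alpha;
        int word = sen[i];  // center word supplies the Huffman path
        for (int j = i - window; j <= i + window; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          int last = sen[j];  // context word supplies the input vector
          double* v0 = &syn0[(size_t)last * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          const std::vector<int>& code = h.code[word];
          const std::vector<int>& point = h.point[word];
          for (size_t b = 0; b < code.size(); ++b) {
            double* v1 = &syn1[(size_t)point[b] * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v0[d] * v1[d];
            f = sigmoid(f);
            double g = (1.0 - code[b] - f) * alpha;
            for (int d = 0; d < dim; ++d) neu1e[d] += g * v1[d];
            for (int d = 0; d < dim; ++d) v1[d] += g * v0[d];
          }
          for (int d = 0; d < dim; ++d) v0[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix m0(vocab, dim), m1(std::max(vocab - 1, 1), dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d) m0(i, d) = syn0[(size_t)i * dim + d];
  for (int i = 0; i < std::max(vocab - 1, 1); ++i)
    for (int d = 0; d < dim; ++d) m1(i, d) = syn1[(size_t)i * dim + d];

  List code(vocab), point(vocab);
  for (int w = 0; w < vocab; ++w) {
    code[w] = IntegerVector(h.code[w].begin(), h.code[w].end());
    point[w] = IntegerVector(h.point[w].begin(), h.point[w].end());
  }
  return List::create(_["syn0"] = m0, _["syn1"] = m1,
                      _["code"] = code, _["point"] = point);
}

// Average hierarchical-softmax log-likelihood of the window pairs in `walks`
// under a trained model: mean over (center i, context j) pairs of
// log P(v_i | Phi(v_j)).
// [[Rcpp::export]]
double sg_loglik_cpp(List walks, int window, NumericMatrix syn0,
                     NumericMatrix syn1, List code, List point) {
  int dim = syn0.ncol();
  double total = 0.0;
  long pairs = 0;
  int n_walks = walks.size();
  for (int s = 0; s < n_walks; ++s) {
    IntegerVector sen = walks[s];
    int len = sen.size();
    for (int i = 0; i < len; ++i) {
      int word = sen[i];
      IntegerVector cd = code[word];
      IntegerVector pt = point[word];
      for (int j = i - window; j <= i + window; ++j) {
        if (j == i || j < 0 || j >= len) continue;
        int last = sen[j];
        double lp = 0.0;
        for (int b = 0; b < cd.size(); ++b) {
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += syn0(last, d) * syn1(pt[b], d);
          double p = sigmoid(cd[b] == 0 ? f : -f);
          lp += std::log(std::max(p, 1e-300));
        }
        total += lp;
        ++pairs;
      }
    }
  }
  return pairs > 0 ? total / pairs : NA_REAL;
}
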