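#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Small deterministic RNG (splitmix64 seeded xorshift128+) so walk sampling
// and embedding training do not touch R's RNG stream and stay reproducible
// under a single integer seed.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(unif() * n); }
};

static inline bool has_edge(const std::vector<int>& indptr,
                            const std::vector<int>& indices,
                            int u, int v) {
  return std::binary_search(indices.begin() + indptr[u],
                            indices.begin() + indptr[u + 1], v);
}

// Second-order (node2vec) biased random walks on a CSR graph with sorted
// neighbour lists. Bias on moving from t -> v -> x: 1/p if x == t, 1 if x
// is adjacent to t, 1/q otherwise. Walks hitting a dead end stop early.
// [[Rcpp::export]]
List cpp_node2vec_walks(IntegerVector indptr_, IntegerVector indices_,
                        int n_walks, int walk_length,
                        double p, double q, int seed) {
  std::vector<int> indptr(indptr_.begin(), indptr_.end());
  std::vector<int> indices(indices_.begin(), indices_.end());
  int n = (int)indptr.size() - 1;
  XRng rng((uint64_t)seed);
  List out(0);
  std::vector<IntegerVector> walks;
  walks.reserve((size_t)n * n_walks);
  std::vector<int> walk;
  std::vector<double> w;
  for (int iter = 0; iter < n_walks; ++iter) {
    for (int start = 0; start < n; ++start) {
      int deg0 = indptr[start + 1] - indptr[start];
      if (deg0 == 0) continue;  // isolated start: skipped (caller warns)
      walk.clear();
      walk.push_back(start);
      while ((int)walk.size() < walk_length) {
        int cur = walk.back();
        int lo = indptr[cur], hi = indptr[cur + 1];
        int deg = hi - lo;
        if (deg == 0) break;  // dead end
        int nxt;
        if (walk.size() == 1 || (p == 1.0 && q == 1.0)) {
          nxt = indices[lo + rng.below(deg)];
        } else {
          int prev = walk[walk.size() - 2];
          w.resize(deg);
          double tot = 0.0;
          for (int e = 0; e < deg; ++e) {
            int x = indices[lo + e];
            double b;
            if (x == prev) b = 1.0 / p;
            else if (has_edge(indptr, indices, prev, x)) b = 1.0;
            else b = 1.0 / q;
            w[e] = b;
            tot += b;
          }
          double u = rng.unif() * tot;
          int e = 0;
          double acc = w[0];
          while (acc < u && e + 1 < deg) acc += w[++e];
          nxt = indices[lo + e];
        }
        walk.push_back(nxt);
      }
      walks.push_back(IntegerVector(walk.begin(), walk.end()));
    }
  }
  return wrap(walks);
}

// Skip-gram with negative sampling over integer-token sentences
// (word2vec-style: dynamic window, unigram^0.75 negative table, linearly
// decaying learning rate, single thread).
// tokens are 0-based node indices; returns the input-embedding matrix.
// [[Rcpp::export]]
NumericMatrix cpp_skipgram(List walks, int n_nodes, int dim, int window,
                           int epochs, int negative, double alpha0,
                           int seed) {
  // flatten corpus
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  long long n_tokens = 0;
  std::vector<double> freq(n_nodes, 0.0);
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    corpus.emplace_back(w.begin(), w.end());
    n_tokens += w.size();
    for (int t : corpus.back()) freq[t] += 1.0;
  }
  // negative-sampling table, unigram^0.75
  const int TABLE = 1 << 20;
  std::vector<int> table(TABLE);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) z += std::pow(freq[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int t = 0; t < TABLE; ++t) {
      table[t] = i;
      if ((double)(t + 1) / TABLE > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(freq[i], 0.75) / z;
      }
    }
  }
  XRng rng((uint64_t)seed);
  // init: input vectors uniform(-0.5,0.5)/dim, output vectors zero
  std::vector<float> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0f);
  for (auto& v : syn0) v = (float)((rng.unif() - 0.5) / dim);
  std::vector<float> neu1e(dim);

  long long total = (long long)epochs * n_tokens;
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& sent : corpus) {
      int len = (int)sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double)done / (total + 1));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        ++done;
        int b = rng.below(window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int w_in = sent[cpos];          // context word -> input
          int w_out = sent[pos];          // centre word  -> target
          float* v_in = &syn0[(size_t)w_in * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) { target = w_out; label = 1.0; }
            else {
              target = table[rng.below(TABLE)];
              if (target == w_out) continue;
              label = 0.0;
            }
            float* v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            double g;
            if (f > 6.0) g = (label - 1.0) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += (float)(g * v_out[k]);
            for (int k = 0; k < dim; ++k) v_out[k] += (float)(g * v_in[k]);
          }
          for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
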