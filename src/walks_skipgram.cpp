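#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Deterministic RNG shared by the walk generator and the Skipgram trainer.
// std::mt19937_64 raw output is fully specified by the C++ standard, unlike
// the standard distributions, so uniforms are derived by hand to keep results
// identical across platforms and compilers.
static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa
}

static inline int unif_int(std::mt19937_64 &rng, int n) {
  int k = static_cast<int>(unif01(rng) * n);
  return k >= n ? n - 1 : k;
}

// Uniform random walks on an undirected graph given as 0-based adjacency
// lists. Each of the walks_per_node passes visits every node in index order,
// so the corpus layout is deterministic under a fixed seed. A walk records
// walk_length nodes (the start node plus walk_length - 1 uniform steps);
// isolated nodes yield a single-node walk.
// [[Rcpp::export(name = ".cpp_generate_walks")]]
List cpp_generate_walks(List adjacency, int walks_per_node, int walk_length,
                        double seed) {
  int n = adjacency.size();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjacency[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  List walks(static_cast<R_xlen_t>(n) * walks_per_node);
  R_xlen_t w = 0;
  for (int pass = 0; pass < walks_per_node; ++pass) {
    for (int start = 0; start < n; ++start) {
      if (adj[start].empty()) {
        walks[w++] = IntegerVector::create(start + 1);
        continue;
      }
      IntegerVector walk(walk_length);
      int cur = start;
      walk[0] = cur + 1;
      for (int s = 1; s < walk_length; ++s) {
        const std::vector<int> &nb = adj[cur];
        cur = nb[unif_int(rng, static_cast<int>(nb.size()))];
        walk[s] = cur + 1;
      }
      walks[w++] = walk;
    }
  }
  return walks;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skipgram with negative sampling (SGNS) over a walk corpus. Input vectors
// are initialised uniform in (-0.5/d, 0.5/d), output vectors at zero, as in
// the original word2vec implementation. Negatives are drawn from the
// unigram^0.75 distribution via inverse-CDF binary search. The learning rate
// decays linearly to 1e-4 * lr over all (epoch, token) positions.
// Single-threaded and deterministic under a fixed seed.
// [[Rcpp::export(name = ".cpp_train_skipgram")]]
NumericMatrix cpp_train_skipgram(List corpus, int n_nodes, int dim, int window,
                                 int negatives, int epochs, double lr,
                                 double seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<std::vector<int>> walks(corpus.size());
  R_xlen_t total_tokens = 0;
  std::vector<double> freq(n_nodes, 0.0);
  for (R_xlen_t i = 0; i < corpus.size(); ++i) {
    IntegerVector wv = corpus[i];
    walks[i].resize(wv.size());
    for (R_xlen_t j = 0; j < wv.size(); ++j) {
      int node = wv[j] - 1;
      walks[i][j] = node;
      freq[node] += 1.0;
    }
    total_tokens += wv.size();
  }

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(n_nodes);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += std::pow(freq[i], 0.75);
    cum[i] = acc;
  }
  if (acc <= 0.0) stop("empty corpus: no tokens to train on");

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  std::vector<double> grad(dim);
  const double total_positions =
      static_cast<double>(total_tokens) * epochs;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < walks.size(); ++wi) {
      const std::vector<int> &walk = walks[wi];
      int len = static_cast<int>(walk.size());
      for (int pos = 0; pos < len; ++pos) {
        double alpha = lr * (1.0 - processed / total_positions);
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        processed += 1.0;
        int center = walk[pos];
        double *v = &syn0[static_cast<size_t>(center) * dim];
        int lo = pos - window, hi = pos + window;
        if (lo < 0) lo = 0;
        if (hi > len - 1) hi = len - 1;
        for (int cp = lo; cp <= hi; ++cp) {
          if (cp == pos) continue;
          int context = walk[cp];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              double r = unif01(rng) * acc;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *u = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * u[k];
            double g = (label - sigmoid(dot)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u[k];
              u[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}
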