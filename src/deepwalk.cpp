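// Weighted random walks and skip-gram negative-sampling training.
// Self-contained RNG (xorshift64*) so results are deterministic given the
// seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline uint64_t next_rand(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double unif01(uint64_t &s) {
  return (next_rand(s) >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
IntegerMatrix cpp_random_walks(List neighbors, List cumprobs,
                               int walks_per_node, int walk_length,
                               double seed) {
  const int n = neighbors.size();
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  next_rand(rng);

  std::vector<std::vector<int> > nb(n);
  std::vector<std::vector<double> > cp(n);
  for (int i = 0; i < n; ++i) {
    nb[i] = as<std::vector<int> >(neighbors[i]);   // 1-based node ids
    cp[i] = as<std::vector<double> >(cumprobs[i]); // cumulative transition probs
  }

  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  int row = 0;
  for (int e = 0; e < walks_per_node; ++e) {
    // fresh shuffled start order per pass over the nodes
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(next_rand(rng) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < n; ++s, ++row) {
      int cur = order[s]; // 0-based
      walks(row, 0) = cur + 1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int> &nbr = nb[cur];
        if (nbr.empty()) {
          walks(row, step) = cur + 1; // isolated node: walk repeats itself
          continue;
        }
        double u = unif01(rng);
        const std::vector<double> &c = cp[cur];
        int lo = 0, hi = (int)c.size() - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (c[mid] < u) lo = mid + 1; else hi = mid;
        }
        cur = nbr[lo] - 1;
        walks(row, step) = cur + 1;
      }
    }
  }
  return walks;
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns(IntegerMatrix walks, int n_nodes, int dim, int window,
                       int negative, int epochs, double lr, double seed) {
  const int n_walks = walks.nrow();
  const int wl = walks.ncol();
  uint64_t rng = (uint64_t)seed * 11400714819323198485ULL + 2545764946718895387ULL;
  next_rand(rng);

  // unigram^(3/4) negative-sampling distribution (cumulative, binary search)
  std::vector<double> freq(n_nodes, 0.0);
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j) freq[walks(i, j) - 1] += 1.0;
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) { tot += std::pow(freq[v], 0.75); cum[v] = tot; }
  for (int v = 0; v < n_nodes; ++v) cum[v] /= tot;

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  const double total_tokens = (double)epochs * n_walks * wl;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int iw = 0; iw < n_walks; ++iw) {
      for (int pos = 0; pos < wl; ++pos) {
        processed += 1.0;
        double alpha = lr * (1.0 - processed / (total_tokens + 1.0));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        int center = walks(iw, pos) - 1;
        int b = (int)(next_rand(rng) % (uint64_t)window); // dynamic window
        for (int a = b; a < 2 * window + 1 - b; ++a) {
          if (a == window) continue;
          int cpos = pos - window + a;
          if (cpos < 0 || cpos >= wl) continue;
          int ctx = walks(iw, cpos) - 1;
          double *v = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              double u = unif01(rng);
              int lo = 0, hi = n_nodes - 1;
              while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
              target = lo; label = 0.0;
              if (target == center) continue;
            }
            double *w = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v[k] * w[k];
            double g;
            if (f > 6.0) g = (label - 1.0) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int k = 0; k < dim; ++k) grad[k] += g * w[k];
            for (int k = 0; k < dim; ++k) w[k] += g * v[k];
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
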