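// Generalized Louvain heuristic and exhaustive optimizer over a dense
// supra-modularity matrix B (node-layer slots flattened layer-major).
// Both optimizers work on the raw quality sum_{ij} B_ij * delta(g_i, g_j)
// (diagonal included); the 1/(2*mu) prefactor is applied on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fisher-Yates shuffle driven by R's RNG so that set.seed() on the R side
// makes the heuristic fully reproducible.
static void shuffle_rng(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// One Louvain level on dense symmetric B: greedy single-node moves until
// no move improves the raw quality by more than tol. Among equal-gain
// moves the current community is kept. Returns compacted labels.
static std::vector<int> louvain_level(const std::vector<double> &B, int n,
                                      double tol, bool &moved_any) {
  std::vector<int> label(n);
  for (int i = 0; i < n; ++i) label[i] = i;
  std::vector<double> acc(n + 1);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  moved_any = false;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 200) {
    improved = false;
    ++pass;
    shuffle_rng(order);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      std::fill(acc.begin(), acc.end(), 0.0);
      const double *row = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j != i) acc[label[j]] += row[j];
      }
      int cur = label[i];
      // candidate set: every nonempty community plus a fresh singleton
      int best = cur;
      double best_val = acc[cur];
      for (int c = 0; c < n; ++c) {
        if (acc[c] > best_val + tol) { best_val = acc[c]; best = c; }
      }
      // fresh singleton community has value 0
      if (0.0 > best_val + tol) {
        // find an unused label
        std::vector<char> used(n + 1, 0);
        for (int j = 0; j < n; ++j) used[label[j]] = 1;
        for (int c = 0; c <= n; ++c) {
          if (!used[c]) { best = c; break; }
        }
        best_val = 0.0;
      }
      if (best != cur && best_val > acc[cur] + tol) {
        label[i] = best;
        improved = true;
        moved_any = true;
      }
    }
  }
  // compact labels to 0..k-1
  std::vector<int> map(n + 1, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[label[i]] < 0) map[label[i]] = k++;
    label[i] = map[label[i]];
  }
  return label;
}

// [[Rcpp::export(name = ".louvain_dense")]]
IntegerVector louvain_dense(NumericMatrix Bmat, double tol = 1e-10) {
  int n = Bmat.nrow();
  std::vector<double> B(Bmat.begin(), Bmat.end());
  std::vector<int> assign(n);
  for (int i = 0; i < n; ++i) assign[i] = i;
  int level_n = n;

  for (int level = 0; level < 100; ++level) {
    bool moved = false;
    std::vector<int> lab = louvain_level(B, level_n, tol, moved);
    int k = 1 + *std::max_element(lab.begin(), lab.end());
    // fold level labels into the original-node assignment
    for (int i = 0; i < n; ++i) assign[i] = lab[assign[i]];
    if (!moved || k == level_n) break;
    // aggregate B into k x k
    std::vector<double> Bn((size_t)k * k, 0.0);
    for (int i = 0; i < level_n; ++i) {
      for (int j = 0; j < level_n; ++j) {
        Bn[(size_t)lab[i] * k + lab[j]] += B[(size_t)i * level_n + j];
      }
    }
    B.swap(Bn);
    level_n = k;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = assign[i] + 1;  // 1-based
  return out;
}

// Exhaustive maximization over all set partitions of the N slots,
// enumerated as restricted growth strings with incremental evaluation of
// the raw quality (diagonal included).
struct BruteState {
  const double *B;
  int n;
  double best_q;
  std::vector<int> a, best;
};

static void brute_rec(BruteState &st, int pos, int maxlab, double q) {
  if (pos == st.n) {
    if (q > st.best_q + 1e-15) {
      st.best_q = q;
      st.best = st.a;
    }
    return;
  }
  const double *col = &st.B[(size_t)pos * st.n];
  double self = col[pos];
  int top = std::min(maxlab + 1, pos);
  for (int lab = 0; lab <= top; ++lab) {
    double delta = self;
    for (int j = 0; j < pos; ++j) {
      if (st.a[j] == lab) delta += 2.0 * col[j];
    }
    st.a[pos] = lab;
    brute_rec(st, pos + 1, std::max(maxlab, lab), q + delta);
  }
}

// [[Rcpp::export(name = ".brute_force_partition")]]
List brute_force_partition(NumericMatrix Bmat) {
  int n = Bmat.nrow();
  if (n > 12) stop("exhaustive search limited to 12 node-layer slots");
  BruteState st;
  std::vector<double> B(Bmat.begin(), Bmat.end());
  st.B = B.data();
  st.n = n;
  st.best_q = -std::numeric_limits<double>::infinity();
  st.a.assign(n, 0);
  st.best.assign(n, 0);
  brute_rec(st, 0, -1, 0.0);
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = st.best[i] + 1;
  return List::create(_["q_raw"] = st.best_q, _["labels"] = lab);
}
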