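#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Classification forest grown purely to accumulate Gini importance:
// bootstrap resamples, CART splits on Gini impurity over `mtry` randomly
// chosen features, unlimited depth, no pruning. Importance(f) is the total
// weighted impurity decrease of all splits on f, summed over the ensemble
// and divided by ntree ("mean decrease in Gini").
//
// All randomness comes from a seeded mt19937 with hand-rolled bounded draws
// and Fisher-Yates shuffling: the mt19937 engine itself is fully specified
// by the C++ standard, while std::uniform_int_distribution is not, and seed
// determinism must hold across platforms.

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // bounded draw in [0, n); modulo bias is negligible for n << 2^32
  int below(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
};

struct Task {
  std::vector<int> idx;  // bootstrap sample indices at this node
};

// weighted Gini impurity: n * (1 - sum p_k^2) = n - sum c_k^2 / n
double weighted_gini(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double ss = 0.0;
  for (double c : cnt) ss += c * c;
  return n - ss / n;
}

}  // namespace

// [[Rcpp::export(name = ".gini_forest_cpp")]]
List gini_forest_cpp(NumericMatrix x, IntegerVector y, int nclass, int ntree,
                     int mtry, int min_node, int seed) {
  const int n = x.nrow(), p = x.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (ntree < 1) stop("ntree must be >= 1");
  if (min_node < 1) stop("min_node must be >= 1");

  std::vector<double> importance(p, 0.0);
  double total_decrease = 0.0;
  Rng rng(static_cast<uint32_t>(seed));

  std::vector<int> feat(p);
  std::vector<int> order;
  std::vector<double> cls_left(nclass), cls_node(nclass);

  for (int tree = 0; tree < ntree; ++tree) {
    Task root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = rng.below(n);

    std::vector<Task> stack;
    stack.push_back(std::move(root));

    while (!stack.empty()) {
      Task node = std::move(stack.back());
      stack.pop_back();
      const int nn = static_cast<int>(node.idx.size());
      if (nn < 2 * min_node || nn < 2) continue;

      std::fill(cls_node.begin(), cls_node.end(), 0.0);
      for (int i : node.idx) cls_node[y[i]] += 1.0;
      const double imp_node = weighted_gini(cls_node, nn);
      if (imp_node <= 0.0) continue;  // pure node

      // sample mtry distinct features (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) feat[j] = j;
      for (int j = 0; j < mtry; ++j)
        std::swap(feat[j], feat[j + rng.below(p - j)]);

      double best_dec = 0.0, best_thr = 0.0;
      int best_f = -1;

      for (int fj = 0; fj < mtry; ++fj) {
        const int f = feat[fj];
        order = node.idx;
        std::sort(order.begin(), order.end(), [&](int a, int b) {
          double va = x(a, f), vb = x(b, f);
          if (va != vb) return va < vb;
          return a < b;  // deterministic tie order
        });
        std::fill(cls_left.begin(), cls_left.end(), 0.0);
        for (int i = 0; i + 1 < nn; ++i) {
          cls_left[y[order[i]]] += 1.0;
          const double v = x(order[i], f), vnext = x(order[i + 1], f);
          if (v == vnext) continue;
          const int nl = i + 1, nr = nn - nl;
          if (nl < min_node || nr < min_node) continue;
          double ssl = 0.0;
          for (int k = 0; k < nclass; ++k) ssl += cls_left[k] * cls_left[k];
          double ssr = 0.0;
          for (int k = 0; k < nclass; ++k) {
            const double cr = cls_node[k] - cls_left[k];
            ssr += cr * cr;
          }
          const double dec = imp_node - (nl - ssl / nl) - (nr - ssr / nr);
          if (dec > best_dec) {
            best_dec = dec;
            best_f = f;
            best_thr = (v + vnext) / 2.0;
          }
        }
      }

      if (best_f < 0) continue;  // no impurity-reducing split found
      importance[best_f] += best_dec;
      total_decrease += best_dec;

      Task left, right;
      left.idx.reserve(nn);
      right.idx.reserve(nn);
      for (int i : node.idx) {
        if (x(i, best_f) <= best_thr) left.idx.push_back(i);
        else right.idx.push_back(i);
      }
      stack.push_back(std::move(left));
      stack.push_back(std::move(right));
    }
  }

  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["importance"] = imp,
                      _["total_decrease"] = total_decrease);
}
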