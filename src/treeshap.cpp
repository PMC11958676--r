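// Path-dependent Shapley attribution for decision-tree ensembles.
//
// Implements the polynomial-time path algorithm over a generic node-table
// representation (one matrix per tree). The value function being
// attributed is the tree-conditional expectation: features absent from a
// coalition are marginalized with the node cover fractions recorded at
// training time. An exhaustive-enumeration oracle for the same value
// function lives on the R side and pins this implementation down on small
// trees.
//
// Node table columns (one row per node):
//   0 feature   1-based split feature index, 0 for leaves
//   1 threshold split point; x[feature] <= threshold goes left
//   2 yes       1-based left (<=) child index, 0 for leaves
//   3 no        1-based right child index, 0 for leaves
//   4 value     leaf value (ignored on internal nodes)
//   5 cover     number (or weight) of training rows through the node

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElem {
  int d;          // feature index (0-based), -1 for the root placeholder
  double z;       // fraction of "zero" (marginalized) paths that flow through
  double o;       // fraction of "one" (observed) paths (0 or 1)
  double w;       // permutation weight
};

static void path_extend(std::vector<PathElem> &m, double pz, double po,
                        int pi) {
  const int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

// undo the extension that introduced element k, removing it from the path
static void path_unwind(std::vector<PathElem> &m, int k) {
  const int d = static_cast<int>(m.size()) - 1; // unique_depth
  const double one = m[k].o;
  const double zero = m[k].z;
  double next_one = m[d].w;
  for (int i = d - 1; i >= 0; --i) {
    if (one != 0) {
      const double tmp = m[i].w;
      m[i].w = next_one * (d + 1) / static_cast<double>((i + 1) * one);
      next_one = tmp - m[i].w * zero * (d - i) / static_cast<double>(d + 1);
    } else {
      m[i].w = m[i].w * (d + 1) / static_cast<double>(zero * (d - i));
    }
  }
  for (int i = k; i < d; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
  m.pop_back();
}

// total permutation weight if element k were unwound (path left untouched)
static double path_unwound_sum(const std::vector<PathElem> &m, int k) {
  std::vector<PathElem> cp(m);
  path_unwind(cp, k);
  double s = 0;
  for (const PathElem &e : cp) s += e.w;
  return s;
}

struct Tree {
  const double *feature, *threshold, *yes, *no, *value, *cover;
  int n;
  explicit Tree(const NumericMatrix &t)
      : feature(&t(0, 0)), threshold(&t(0, 1)), yes(&t(0, 2)), no(&t(0, 3)),
        value(&t(0, 4)), cover(&t(0, 5)), n(t.nrow()) {}
  bool leaf(int j) const { return feature[j] == 0; }
  int feat(int j) const { return static_cast<int>(feature[j]) - 1; }
  int left(int j) const { return static_cast<int>(yes[j]) - 1; }
  int right(int j) const { return static_cast<int>(no[j]) - 1; }
};

static void shap_recurse(const Tree &tr, const double *x, double *phi,
                         int node, std::vector<PathElem> path, double pz,
                         double po, int pi) {
  path_extend(path, pz, po, pi);
  const int d = static_cast<int>(path.size()) - 1;
  if (tr.leaf(node)) {
    for (int i = 1; i <= d; ++i) {
      const double w = path_unwound_sum(path, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * tr.value[node];
    }
    return;
  }
  const int f = tr.feat(node);
  const int lft = tr.left(node), rgt = tr.right(node);
  const int hot = (x[f] <= tr.threshold[node]) ? lft : rgt;
  const int cold = (hot == lft) ? rgt : lft;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i <= d; ++i) {
    if (path[i].d == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = path[k].z;
    io = path[k].o;
    path_unwind(path, k);
  }
  const double rj = tr.cover[node];
  shap_recurse(tr, x, phi, hot, path, iz * tr.cover[hot] / rj, io, f);
  shap_recurse(tr, x, phi, cold, path, iz * tr.cover[cold] / rj, 0.0, f);
}

// [[Rcpp::export(name = ".tree_shap_cpp")]]
NumericMatrix tree_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), nt = trees.size();
  NumericMatrix phi(n, p);
  std::vector<double> row(p);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tm = trees[t];
    Tree tr(tm);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      std::vector<double> ph(p, 0.0);
      shap_recurse(tr, row.data(), ph.data(), 0, {}, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += ph[j] / nt;
    }
  }
  return phi;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tm = trees[t];
    Tree tr(tm);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (!tr.leaf(node)) {
        node = (X(i, tr.feat(node)) <= tr.threshold[node]) ? tr.left(node)
                                                           : tr.right(node);
      }
      out[i] += tr.value[node] / nt;
    }
  }
  return out;
}
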