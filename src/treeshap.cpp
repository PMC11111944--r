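#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Shapley attribution for tree ensembles (the polynomial-time
// path-weight recursion), computed in double precision so that the
// per-row additivity identity  sum(phi) + E[f] == f(x)  holds to
// machine accuracy against tree_predict_cpp on the same parsed trees.

namespace {

struct PathElem {
  int d;       // feature index of the split that created this element
  double z;    // fraction of "zero" (feature-hidden) paths that flow through
  double o;    // fraction of "one" (feature-observed) paths that flow through
  double w;    // permutation weight
};

typedef std::vector<PathElem> Path;

void path_extend(Path &m, double pz, double po, int pi) {
  const int l = (int)m.size();
  PathElem e; e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (l + 1.0);
    m[i].w = pz * m[i].w * (l - i) / (l + 1.0);
  }
}

void path_unwind(Path &m, int i) {
  const int l = (int)m.size() - 1;
  const double pz = m[i].z, po = m[i].o;
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (po != 0.0) {
      const double t = m[j].w;
      m[j].w = n * (l + 1.0) / ((j + 1.0) * po);
      n = t - m[j].w * pz * (l - j) / (l + 1.0);
    } else {
      m[j].w = m[j].w * (l + 1.0) / (pz * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

double unwound_sum(const Path &m, int i) {
  Path cp(m);
  path_unwind(cp, i);
  double s = 0.0;
  for (size_t j = 0; j < cp.size(); ++j) s += cp[j].w;
  return s;
}

struct Tree {
  IntegerVector yes, no, feature;
  NumericVector thr, cover, value;
};

void shap_recurse(const Tree &tr, const NumericVector &x, NumericVector &phi,
                  Path m, int node, double pz, double po, int pi) {
  path_extend(m, pz, po, pi);
  if (tr.feature[node] < 0) {  // leaf
    const double v = tr.value[node];
    for (int i = 1; i < (int)m.size(); ++i)
      phi[m[i].d] += unwound_sum(m, i) * (m[i].o - m[i].z) * v;
    return;
  }
  const int f = tr.feature[node];
  const double xv = x[f];
  int hot, cold;
  if (NumericVector::is_na(xv) || std::isnan(xv)) { hot = tr.yes[node]; }
  else hot = (xv < tr.thr[node]) ? tr.yes[node] : tr.no[node];
  cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) if (m[i].d == f) { k = i; break; }
  if (k >= 0) { iz = m[k].z; io = m[k].o; path_unwind(m, k); }
  const double rj = tr.cover[node];
  shap_recurse(tr, x, phi, m, hot, iz * tr.cover[hot] / rj, io, f);
  shap_recurse(tr, x, phi, m, cold, iz * tr.cover[cold] / rj, 0.0, f);
}

Tree as_tree(List t) {
  Tree tr;
  tr.yes = t["yes"]; tr.no = t["no"]; tr.feature = t["feature"];
  tr.thr = t["threshold"]; tr.cover = t["cover"]; tr.value = t["value"];
  return tr;
}

double tree_mean(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const double rj = tr.cover[node];
  return tree_mean(tr, tr.yes[node]) * tr.cover[tr.yes[node]] / rj +
         tree_mean(tr, tr.no[node]) * tr.cover[tr.no[node]] / rj;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix tree_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), nt = trees.size();
  NumericMatrix out(n, p + 1);  // last column: cover-weighted expectation
  std::vector<Tree> parsed(nt);
  for (int t = 0; t < nt; ++t) parsed[t] = as_tree(trees[t]);
  double base = 0.0;
  for (int t = 0; t < nt; ++t) base += tree_mean(parsed[t], 0);
  for (int i = 0; i < n; ++i) {
    NumericVector x = X(i, _);
    NumericVector phi(p);
    for (int t = 0; t < nt; ++t) {
      Path m;
      shap_recurse(parsed[t], x, phi, m, 0, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
    out(i, p) = base;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    Tree tr = as_tree(trees[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0) {
        const double xv = X(i, tr.feature[node]);
        if (NumericVector::is_na(xv) || std::isnan(xv)) node = tr.yes[node];
        else node = (xv < tr.thr[node]) ? tr.yes[node] : tr.no[node];
      }
      out[i] += tr.value[node];
    }
  }
  return out;
}
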