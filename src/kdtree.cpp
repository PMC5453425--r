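// Max-norm (Chebyshev) k-d tree for KSG/KL estimators and the Ragwitz
// local predictor. All estimators in this package count neighbours under
// the maximum norm, so the tree prunes on per-coordinate distance.
// Points are stored row-major and reordered in leaf order so leaf scans
// are contiguous in memory.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int left, right;   // child node ids, -1 if leaf
  int begin, end;    // range into the reordered point array
  std::vector<double> lo, hi;  // bounding box
};

class KDTree {
public:
  KDTree(const NumericMatrix& X, int leaf_size = 16)
    : n_(X.nrow()), d_(X.ncol()), leaf_size_(leaf_size) {
    std::vector<int> idx(n_);
    for (int i = 0; i < n_; ++i) idx[i] = i;
    // temporary row-major copy in original order
    std::vector<double> tmp((size_t)n_ * d_);
    for (int j = 0; j < d_; ++j)
      for (int i = 0; i < n_; ++i) tmp[(size_t)i * d_ + j] = X(i, j);
    nodes_.reserve(2 * n_ / leaf_size_ + 8);
    build(tmp, idx, 0, n_);
    // reorder into leaf order
    pts_.resize((size_t)n_ * d_);
    orig_.resize(n_);
    for (int t = 0; t < n_; ++t) {
      orig_[t] = idx[t];
      std::copy(tmp.begin() + (size_t)idx[t] * d_,
                tmp.begin() + (size_t)(idx[t] + 1) * d_,
                pts_.begin() + (size_t)t * d_);
    }
  }

  const double* pt(int t) const { return &pts_[(size_t)t * d_]; }
  int orig(int t) const { return orig_[t]; }

  double dist_to(const double* q, int t) const {
    const double* p = pt(t);
    double m = 0.0;
    for (int j = 0; j < d_; ++j) {
      double v = std::fabs(q[j] - p[j]);
      if (v > m) m = v;
    }
    return m;
  }

  // k nearest neighbours of query point q; `self` is the original index
  // to exclude (-1 for none). Ties on distance broken toward the smaller
  // original index so results are independent of traversal order.
  void knn(const double* q, int self, int k, std::vector<int>& out_idx,
           std::vector<double>& out_dist) const {
    heap_.clear();
    knn_rec(0, q, self, k);
    std::sort(heap_.begin(), heap_.end());
    int m = (int)heap_.size();
    out_idx.resize(m); out_dist.resize(m);
    for (int j = 0; j < m; ++j) {
      out_dist[j] = heap_[j].first;
      out_idx[j] = heap_[j].second;
    }
  }

  // number of points with maxnorm distance < r (strict) or <= r from q,
  // excluding original index `self`
  int count_within(const double* q, int self, double r, bool strict) const {
    int c = count_rec(0, q, r, strict);
    if (self >= 0) --c;  // self always within its own radius
    return c;
  }

private:
  int n_, d_, leaf_size_;
  std::vector<double> pts_;
  std::vector<int> orig_;
  std::vector<Node> nodes_;
  // scratch max-heap of (dist, orig index); kept as sortable vector
  mutable std::vector<std::pair<double, int> > heap_;

  int build(std::vector<double>& tmp, std::vector<int>& idx,
            int begin, int end) {
    int id = (int)nodes_.size();
    nodes_.push_back(Node());
    {
      Node& nd = nodes_[id];
      nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
      nd.lo.assign(d_, R_PosInf); nd.hi.assign(d_, R_NegInf);
      for (int t = begin; t < end; ++t) {
        const double* p = &tmp[(size_t)idx[t] * d_];
        for (int j = 0; j < d_; ++j) {
          if (p[j] < nd.lo[j]) nd.lo[j] = p[j];
          if (p[j] > nd.hi[j]) nd.hi[j] = p[j];
        }
      }
    }
    if (end - begin > leaf_size_) {
      int sd = 0; double w = -1.0;
      for (int j = 0; j < d_; ++j) {
        double wj = nodes_[id].hi[j] - nodes_[id].lo[j];
        if (wj > w) { w = wj; sd = j; }
      }
      if (w > 0.0) {
        int mid = (begin + end) / 2;
        std::nth_element(idx.begin() + begin, idx.begin() + mid,
                         idx.begin() + end,
                         [&tmp, sd, this](int a, int b) {
                           return tmp[(size_t)a * d_ + sd] <
                                  tmp[(size_t)b * d_ + sd];
                         });
        int l = build(tmp, idx, begin, mid);
        int r = build(tmp, idx, mid, end);
        nodes_[id].left = l; nodes_[id].right = r;
      }
    }
    return id;
  }

  double box_dist(const Node& nd, const double* q) const {
    double m = 0.0;
    for (int j = 0; j < d_; ++j) {
      double e = 0.0;
      if (q[j] < nd.lo[j]) e = nd.lo[j] - q[j];
      else if (q[j] > nd.hi[j]) e = q[j] - nd.hi[j];
      if (e > m) m = e;
    }
    return m;
  }

  double box_far(const Node& nd, const double* q) const {
    double m = 0.0;
    for (int j = 0; j < d_; ++j) {
      double e = std::max(std::fabs(q[j] - nd.lo[j]),
                          std::fabs(q[j] - nd.hi[j]));
      if (e > m) m = e;
    }
    return m;
  }

  void heap_push(int k, double dist, int oi) const {
    if ((int)heap_.size() < k) {
      heap_.push_back(std::make_pair(dist, oi));
      std::push_heap(heap_.begin(), heap_.end());
    } else if (dist < heap_.front().first ||
               (dist == heap_.front().first && oi < heap_.front().second)) {
      std::pop_heap(heap_.begin(), heap_.end());
      heap_.back() = std::make_pair(dist, oi);
      std::push_heap(heap_.begin(), heap_.end());
    }
  }

  void knn_rec(int node, const double* q, int self, int k) const {
    const Node& nd = nodes_[node];
    if ((int)heap_.size() == k && box_dist(nd, q) > heap_.front().first)
      return;
    if (nd.left < 0) {
      for (int t = nd.begin; t < nd.end; ++t) {
        if (orig_[t] == self) continue;
        heap_push(k, dist_to(q, t), orig_[t]);
      }
      return;
    }
    double dl = box_dist(nodes_[nd.left], q);
    double dr = box_dist(nodes_[nd.right], q);
    if (dl <= dr) { knn_rec(nd.left, q, self, k); knn_rec(nd.right, q, self, k); }
    else { knn_rec(nd.right, q, self, k); knn_rec(nd.left, q, self, k); }
  }

  int count_rec(int node, const double* q, double r, bool strict) const {
    const Node& nd = nodes_[node];
    double bd = box_dist(nd, q);
    if (strict ? (bd >= r) : (bd > r)) return 0;
    double far = box_far(nd, q);
    if (strict ? (far < r) : (far <= r)) return nd.end - nd.begin;
    if (nd.left < 0) {
      int c = 0;
      for (int t = nd.begin; t < nd.end; ++t) {
        double dist = dist_to(q, t);
        if (strict ? (dist < r) : (dist <= r)) ++c;
      }
      return c;
    }
    return count_rec(nd.left, q, r, strict) +
           count_rec(nd.right, q, r, strict);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of points");
  KDTree tree(X);
  NumericVector kdist(n);
  IntegerMatrix idx(n, k);
  std::vector<int> oi; std::vector<double> od;
  std::vector<double> q(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) q[j] = X(i, j);
    tree.knn(q.data(), i, k, oi, od);
    kdist[i] = od[k - 1];
    for (int j = 0; j < k; ++j) idx(i, j) = oi[j] + 1;  // 1-based for R
  }
  return List::create(_["dist"] = kdist, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_count_within")]]
IntegerVector cpp_count_within(NumericMatrix X, NumericVector radii,
                               bool strict) {
  int n = X.nrow(), d = X.ncol();
  if (radii.size() != n) stop("radii must have one entry per point");
  IntegerVector cnt(n);
  if (d == 1) {
    // sorted-array shortcut
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = X(i, 0);
    std::vector<double> s(v);
    std::sort(s.begin(), s.end());
    for (int i = 0; i < n; ++i) {
      double r = radii[i];
      long c;
      if (strict)
        c = std::upper_bound(s.begin(), s.end(),
                             std::nextafter(v[i] + r, -HUGE_VAL)) -
            std::lower_bound(s.begin(), s.end(),
                             std::nextafter(v[i] - r, HUGE_VAL));
      else
        c = std::upper_bound(s.begin(), s.end(), v[i] + r) -
            std::lower_bound(s.begin(), s.end(), v[i] - r);
      cnt[i] = (int)c - 1;
    }
    return cnt;
  }
  KDTree tree(X);
  std::vector<double> q(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) q[j] = X(i, j);
    cnt[i] = tree.count_within(q.data(), i, radii[i], strict);
  }
  return cnt;
}

// Per-point marginal radii for the KSG algorithm-2 estimator: for each
// point, the largest per-block max-norm distance to any of its k nearest
// joint-space neighbours. `blocks` gives the (1-based, inclusive) column
// ranges of the marginal subspaces.
// [[Rcpp::export(name = ".cpp_marginal_radii")]]
NumericMatrix cpp_marginal_radii(NumericMatrix X, IntegerMatrix knn_idx,
                                 IntegerMatrix blocks) {
  int n = X.nrow(), k = knn_idx.ncol(), nb = blocks.nrow();
  NumericMatrix out(n, nb);
  for (int i = 0; i < n; ++i) {
    for (int b = 0; b < nb; ++b) {
      double m = 0.0;
      for (int j = 0; j < k; ++j) {
        int p = knn_idx(i, j) - 1;
        double dd = 0.0;
        for (int c = blocks(b, 0) - 1; c <= blocks(b, 1) - 1; ++c) {
          double v = std::fabs(X(i, c) - X(p, c));
          if (v > dd) dd = v;
        }
        if (dd > m) m = dd;
      }
      out(i, b) = m;
    }
  }
  return out;
}
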