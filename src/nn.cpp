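#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Minimal static 3-d k-d tree for nearest-neighbour queries on point clouds.
// Points are copied into a flat array; nodes are split on the axis of the
// current depth (x, y, z cyclically) at the median. Queries prune subtrees
// whose splitting plane is farther than the current best distance.

namespace {

struct KDNode {
  int idx;    // row index of the point stored at this node
  int left;   // child node positions in the node vector, -1 if absent
  int right;
};

class KDTree {
public:
  KDTree(const Rcpp::NumericMatrix &pts) : n_(pts.nrow()), xyz_(3 * pts.nrow()) {
    for (int i = 0; i < n_; ++i) {
      xyz_[3 * i] = pts(i, 0);
      xyz_[3 * i + 1] = pts(i, 1);
      xyz_[3 * i + 2] = pts(i, 2);
    }
    std::vector<int> order(n_);
    for (int i = 0; i < n_; ++i) order[i] = i;
    nodes_.reserve(n_);
    root_ = build(order.data(), n_, 0);
  }

  // squared distance from query q to stored point i
  double sqdist(const double *q, int i) const {
    const double dx = q[0] - xyz_[3 * i];
    const double dy = q[1] - xyz_[3 * i + 1];
    const double dz = q[2] - xyz_[3 * i + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  void nn1(const double *q, int &best_idx, double &best_sq) const {
    best_idx = -1;
    best_sq = std::numeric_limits<double>::infinity();
    search(root_, 0, q, best_idx, best_sq);
  }

private:
  int n_;
  std::vector<double> xyz_;
  std::vector<KDNode> nodes_;
  int root_;

  int build(int *idx, int m, int depth) {
    if (m <= 0) return -1;
    const int axis = depth % 3;
    int *mid = idx + m / 2;
    std::nth_element(idx, mid, idx + m, [&](int a, int b) {
      return xyz_[3 * a + axis] < xyz_[3 * b + axis];
    });
    KDNode node;
    node.idx = *mid;
    const int pos = (int)nodes_.size();
    nodes_.push_back(node);
    const int left = build(idx, (int)(mid - idx), depth + 1);
    const int right = build(mid + 1, (int)(m - (mid - idx) - 1), depth + 1);
    nodes_[pos].left = left;
    nodes_[pos].right = right;
    return pos;
  }

  void search(int pos, int depth, const double *q, int &best_idx, double &best_sq) const {
    if (pos < 0) return;
    const KDNode &node = nodes_[pos];
    const double d = sqdist(q, node.idx);
    if (d < best_sq) {
      best_sq = d;
      best_idx = node.idx;
    }
    const int axis = depth % 3;
    const double delta = q[axis] - xyz_[3 * node.idx + axis];
    const int near = delta <= 0 ? node.left : node.right;
    const int far = delta <= 0 ? node.right : node.left;
    search(near, depth + 1, q, best_idx, best_sq);
    if (delta * delta < best_sq) search(far, depth + 1, q, best_idx, best_sq);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_nn1")]]
Rcpp::List cpp_nn1(Rcpp::NumericMatrix query, Rcpp::NumericMatrix target) {
  if (query.ncol() != 3 || target.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  if (target.nrow() < 1) Rcpp::stop("target cloud is empty");
  KDTree tree(target);
  const int nq = query.nrow();
  Rcpp::IntegerVector idx(nq);
  Rcpp::NumericVector dist(nq);
  double q[3];
  for (int i = 0; i < nq; ++i) {
    q[0] = query(i, 0);
    q[1] = query(i, 1);
    q[2] = query(i, 2);
    int bi;
    double bs;
    tree.nn1(q, bi, bs);
    idx[i] = bi + 1; // 1-based for R
    dist[i] = std::sqrt(bs);
  }
  return Rcpp::List::create(Rcpp::Named("idx") = idx, Rcpp::Named("dist") = dist);
}
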