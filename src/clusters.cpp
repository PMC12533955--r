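#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a logical matrix (column-major) with
// 4- or 8-connectivity, via iterative flood fill. Returns integer labels
// (0 = background), cluster ids are 1..k in discovery order.
// [[Rcpp::export]]
IntegerMatrix label_clusters_cpp(LogicalMatrix supra, int connectivity) {
  int nr = supra.nrow(), nc = supra.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> stack;
  stack.reserve(nr * nc);
  int next = 0;
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int ndir = connectivity == 8 ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!supra(r, c) || labels(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      labels(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int r2 = cr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!supra(r2, c2) || labels(r2, c2)) continue;
          labels(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  labels.attr("n_clusters") = next;
  return labels;
}

// Maximum cluster statistic (size = pixel count, or mass = sum of |stat|)
// over connected suprathreshold components. Used in the permutation loop.
// [[Rcpp::export]]
double max_cluster_stat_cpp(LogicalVector supra, NumericVector stat,
                            int nr, int nc, int connectivity,
                            bool use_mass) {
  std::vector<int> labels(nr * nc, 0);
  std::vector<int> stack;
  double best = 0.0;
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int ndir = connectivity == 8 ? 8 : 4;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx0 = r + c * nr;
      if (!supra[idx0] || labels[idx0]) continue;
      ++next;
      double acc = 0.0;
      stack.push_back(idx0);
      labels[idx0] = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        acc += use_mass ? std::fabs(stat[idx]) : 1.0;
        int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int r2 = cr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = r2 + c2 * nr;
          if (!supra[i2] || labels[i2]) continue;
          labels[i2] = next;
          stack.push_back(i2);
        }
      }
      if (acc > best) best = acc;
    }
  }
  return best;
}
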