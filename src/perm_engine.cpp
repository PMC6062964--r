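// Connected-component labelling on the L x C parametric grid and the
// permutation null of the maximum supra-threshold cluster size.
//
// The grid is a tube: columns may wrap (column 0 adjacent to column C-1),
// rows never wrap. Vertex v maps to (l, c) with v = l + c*L (column-major,
// matching R's as.vector() on an L x C matrix).
//
// The permutation engine avoids refitting the full GLM per permutation:
// by the Frisch-Waugh-Lovell identity the tested-column t statistic needs
// only (a) the permuted projection of the reduced-model residuals onto the
// residualized regressor and (b) the permuted projection onto an
// orthonormal basis of the design, both of which are batched into one
// matrix product per chunk of permutations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GridTopo {
  int L, C;
  bool wrap, eight;
};

template <typename InMask>
int flood_from(int l0, int c0, const GridTopo& g, InMask in,
               std::vector<signed char>& visited, std::vector<int>& stack,
               IntegerMatrix* lab, int label) {
  int size = 0;
  stack.clear();
  stack.push_back(l0 + c0 * g.L);
  visited[l0 + c0 * g.L] = 1;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    ++size;
    if (lab) (*lab)(idx % g.L, idx / g.L) = label;
    int l = idx % g.L, c = idx / g.L;
    const int dl4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
    const int dl8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
              dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
    int nn = g.eight ? 8 : 4;
    const int* dl = g.eight ? dl8 : dl4;
    const int* dc = g.eight ? dc8 : dc4;
    for (int k = 0; k < nn; ++k) {
      int ll = l + dl[k];
      if (ll < 0 || ll >= g.L) continue;
      int cc = c + dc[k];
      if (g.wrap) {
        if (cc < 0) cc += g.C;
        else if (cc >= g.C) cc -= g.C;
      } else if (cc < 0 || cc >= g.C) {
        continue;
      }
      int nidx = ll + cc * g.L;
      if (!visited[nidx] && in(ll, cc)) {
        visited[nidx] = 1;
        stack.push_back(nidx);
      }
    }
  }
  return size;
}

// maximum component size over both sign-segregated masks of a t-map
int max_cluster_of_t(const double* t, double thr, const GridTopo& g,
                     const int* roi, std::vector<signed char>& visited,
                     std::vector<int>& stack) {
  int n = g.L * g.C;
  int best = 0;
  for (int sign = 0; sign < 2; ++sign) {
    std::fill(visited.begin(), visited.end(), 0);
    auto in = [&](int l, int c) {
      int v = l + c * g.L;
      if (roi && !roi[v]) return false;
      double x = t[v];
      return sign == 0 ? (x > thr) : (x < -thr);
    };
    for (int v = 0; v < n; ++v) {
      if (visited[v]) continue;
      int l = v % g.L, c = v / g.L;
      if (!in(l, c)) continue;
      int s = flood_from(l, c, g, in, visited, stack, nullptr, 0);
      if (s > best) best = s;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool wrap, bool eight) {
  GridTopo g{mask.nrow(), mask.ncol(), wrap, eight};
  IntegerMatrix lab(g.L, g.C);
  std::vector<signed char> visited(g.L * g.C, 0);
  std::vector<int> stack;
  auto in = [&](int l, int c) { return mask(l, c) == TRUE; };
  int next = 0;
  for (int c = 0; c < g.C; ++c)
    for (int l = 0; l < g.L; ++l) {
      if (visited[l + c * g.L] || !in(l, c)) continue;
      ++next;
      flood_from(l, c, g, in, visited, stack, &lab, next);
    }
  return lab;
}

// Null distribution of the maximum cluster size.
//
// Y: n x V matrix of radial distances (V = L*C, column-major grid order).
// X: full design; jcol: 1-based column of the group effect.
// perms: B x n matrix of 1-based row permutations (generated in R so the
//        caller owns the RNG stream).
// scheme: "freedman_lane" permutes reduced-model residuals; "labels"
//        permutes the group column of X.
// [[Rcpp::export]]
IntegerVector perm_maxcluster_cpp(const arma::mat& Y, const arma::mat& X,
                                  int jcol, const IntegerMatrix& perms,
                                  std::string scheme, double t_thr, int L,
                                  int C, Nullable<LogicalMatrix> roi_,
                                  bool wrap, bool eight) {
  int n = X.n_rows, p = X.n_cols, V = Y.n_cols, B = perms.nrow();
  if ((int)Y.n_rows != n) stop("Y and X row counts differ");
  if (V != L * C) stop("Y columns must equal L*C");
  int j = jcol - 1;
  double df = n - p;
  if (df < 1) stop("non-positive residual degrees of freedom");
  if (scheme != "freedman_lane" && scheme != "labels")
    stop("unknown permutation scheme '%s'", scheme.c_str());
  bool fl = scheme == "freedman_lane";

  GridTopo g{L, C, wrap, eight};
  std::vector<int> roi_store;
  const int* roi = nullptr;
  if (roi_.isNotNull()) {
    LogicalMatrix rm(roi_);
    roi_store.resize(V);
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < L; ++l) roi_store[l + c * L] = rm(l, c) == TRUE;
    roi = roi_store.data();
  }

  // reduced model: design without the tested column
  arma::mat Z = X;
  Z.shed_col(j);
  arma::mat Qz, Rz;
  if (!arma::qr_econ(Qz, Rz, Z)) stop("QR of the reduced design failed");
  arma::mat E = Y - Qz * (Qz.t() * Y);            // reduced-model residuals
  arma::rowvec e2 = arma::sum(arma::square(E), 0);

  arma::vec xj = X.col(j);
  arma::vec xt = xj - Qz * (Qz.t() * xj);         // residualized regressor
  double xt2 = arma::dot(xt, xt);
  if (xt2 <= 0) stop("tested column is collinear with the covariates");

  arma::mat Qx, Rx;
  if (!arma::qr_econ(Qx, Rx, X)) stop("QR of the design failed");

  std::vector<signed char> visited(V, 0);
  std::vector<int> stack;
  IntegerVector out(B);
  std::vector<double> tv(V);

  // rows of the batched product per permutation:
  // freedman_lane: 1 numerator row + p rows of Qx' P_b  -> RSS
  // labels:        1 numerator row (permuted group gathered) + p-1 rows
  //                of Qz' gathered for ||gtil||^2 bookkeeping done densely
  const int chunk = 128;
  int rows_per = fl ? (p + 1) : 1;
  arma::mat W(rows_per * chunk, n);
  arma::vec gtil2(chunk);

  for (int b0 = 0; b0 < B; b0 += chunk) {
    int nb = std::min(chunk, B - b0);
    W.zeros();
    for (int b = 0; b < nb; ++b) {
      const int r0 = b * rows_per;
      if (fl) {
        // scatter: row of xt and of each Qx column into permuted positions
        for (int i = 0; i < n; ++i) {
          int m = perms(b0 + b, i) - 1;
          W(r0, m) = xt(i);
          for (int k = 0; k < p; ++k) W(r0 + 1 + k, m) = Qx(i, k);
        }
      } else {
        // gather: permuted group column, then residualize against Z
        arma::rowvec gb(n);
        for (int i = 0; i < n; ++i) gb(i) = xj(perms(b0 + b, i) - 1);
        arma::rowvec proj = (gb * Qz);
        gtil2(b) = arma::dot(gb, gb) - arma::dot(proj, proj);
        W.row(r0) = gb - proj * Qz.t();
      }
    }
    arma::mat T = W.rows(0, nb * rows_per - 1) * E;
    for (int b = 0; b < nb; ++b) {
      const int r0 = b * rows_per;
      double denom2 = fl ? xt2 : gtil2(b);
      for (int v = 0; v < V; ++v) {
        double num = T(r0, v);
        double rss;
        if (fl) {
          double q2 = 0;
          for (int k = 0; k < p; ++k) q2 += T(r0 + 1 + k, v) * T(r0 + 1 + k, v);
          rss = e2(v) - q2;
        } else {
          rss = e2(v) - num * num / denom2;
        }
        if (rss < 0) rss = 0;
        double s2 = rss / df;
        if (s2 <= 0 || denom2 <= 0)
          tv[v] = num == 0 ? 0.0 : (num > 0 ? 1e8 : -1e8);
        else
          tv[v] = num / std::sqrt(s2 * denom2);
      }
      out[b0 + b] = max_cluster_of_t(tv.data(), t_thr, g, roi, visited, stack);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
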