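// Equal-arc-length resampling of closed contours (fixed-point refinement)
// and the minimal-twist cyclic alignment. These sit in the per-slice inner
// loop of surface extraction, hence the compiled implementation; the R
// reference semantics are documented in R/surface.R.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// one equal-arc sampling pass over the closed polyline p (CCW, open form)
void resample_pass(const std::vector<double>& px, const std::vector<double>& py,
                   int C, std::vector<double>& qx, std::vector<double>& qy) {
  int m = px.size();
  std::vector<double> cum(m + 1);
  cum[0] = 0.0;
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double dx = px[j] - px[i], dy = py[j] - py[i];
    cum[i + 1] = cum[i] + std::sqrt(dx * dx + dy * dy);
  }
  double per = cum[m];

  // area centroid
  double a2 = 0.0, cx = 0.0, cy = 0.0;
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double cr = px[i] * py[j] - px[j] * py[i];
    a2 += cr;
    cx += (px[i] + px[j]) * cr;
    cy += (py[i] + py[j]) * cr;
  }
  cx /= 3.0 * a2;
  cy /= 3.0 * a2;

  // anchor: first crossing of the +x ray from the centroid
  double s0 = 0.0, best_x = R_PosInf;
  bool found = false;
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double yi = py[i] - cy, yj = py[j] - cy;
    if ((yi <= 0 && yj > 0) || (yi > 0 && yj <= 0)) {
      double t = -yi / (yj - yi);
      double xint = px[i] + t * (px[j] - px[i]);
      if (xint > cx && xint < best_x) {
        best_x = xint;
        s0 = cum[i] + t * (cum[i + 1] - cum[i]);
        found = true;
      }
    }
  }
  if (!found) s0 = 0.0;

  // snap to an existing vertex (keeps the anchor stable across passes)
  double tol = per / (100.0 * C);
  double best_d = R_PosInf;
  int best_v = 0;
  for (int i = 0; i <= m; ++i) {
    double d = std::fabs(cum[i] - s0);
    d = std::min(d, per - d);
    if (d < best_d) { best_d = d; best_v = i; }
  }
  if (best_d < tol) s0 = (cum[best_v] >= per) ? cum[best_v] - per : cum[best_v];

  // sample C points at s0 + k per / C, linear along the polyline
  int seg = 0;
  double prev_s = -1.0;
  for (int k = 0; k < C; ++k) {
    double s = s0 + per * k / C;
    if (s >= per) s -= per;
    if (s < prev_s) seg = 0;            // wrapped past the start
    prev_s = s;
    while (seg < m - 1 && cum[seg + 1] < s) ++seg;
    double t = (s - cum[seg]) / (cum[seg + 1] - cum[seg]);
    int j = (seg + 1) % m;
    qx[k] = px[seg] + t * (px[j] - px[seg]);
    qy[k] = py[seg] + t * (py[j] - py[seg]);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix resample_closed_cpp(NumericMatrix P, int C, int max_iter,
                                  double tol) {
  int m = P.nrow();
  std::vector<double> px(m), py(m);
  for (int i = 0; i < m; ++i) { px[i] = P(i, 0); py[i] = P(i, 1); }
  std::vector<double> qx(C), qy(C), rx(C), ry(C);
  resample_pass(px, py, C, qx, qy);
  for (int it = 0; it < max_iter; ++it) {
    resample_pass(qx, qy, C, rx, ry);
    double moved = 0.0;
    for (int k = 0; k < C; ++k) {
      moved = std::max(moved, std::fabs(rx[k] - qx[k]));
      moved = std::max(moved, std::fabs(ry[k] - qy[k]));
    }
    qx.swap(rx);
    qy.swap(ry);
    if (moved < tol) break;
  }
  NumericMatrix out(C, 2);
  for (int k = 0; k < C; ++k) { out(k, 0) = qx[k]; out(k, 1) = qy[k]; }
  return out;
}

// cyclic shift of `ring` minimizing summed squared distance to `ref`
// (equivalently maximizing the circular cross-correlation)
// [[Rcpp::export]]
NumericMatrix best_rotation_cpp(NumericMatrix ring, NumericMatrix ref) {
  int C = ring.nrow();
  int best_k = 0;
  double best = R_NegInf;
  for (int k = 0; k < C; ++k) {
    double cross = 0.0;
    for (int j = 0; j < C; ++j) {
      int i = (j + k) % C;
      cross += ring(i, 0) * ref(j, 0) + ring(i, 1) * ref(j, 1);
    }
    if (cross > best) { best = cross; best_k = k; }
  }
  NumericMatrix out(C, 2);
  for (int j = 0; j < C; ++j) {
    int i = (j + best_k) % C;
    out(j, 0) = ring(i, 0);
    out(j, 1) = ring(i, 1);
  }
  return out;
}
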