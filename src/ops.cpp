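#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions shared with the R side:
//  - images / feature maps are R arrays (H, W, C) -> arma::cube(H, W, C)
//  - conv weights are (kh*kw*Cin, Cout) matrices; row index = c*kh*kw + ki*kw + kj
//  - im2col rows are "positions" in R column-major order: p = i + j*Ho (0-based)

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(Ho * Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int col = c * kh * kw + ki * kw + kj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            out.at(i + j * Ho, col) = x.at(ii, jj, c);
          }
        }
      }
    }
  }
  return out;
}

static void col2im_add(arma::cube& dx, const arma::mat& dm, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int col = c * kh * kw + ki * kw + kj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            dx.at(ii, jj, c) += dm.at(i + j * Ho, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_forward(const arma::cube& x, const arma::mat& w,
                        const arma::vec& bias, int kh, int kw,
                        int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat m = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat y = m * w;
  y.each_row() += bias.t();
  arma::cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), Ho, Wo);
  // the im2col matrix is reused by the backward pass
  return List::create(Named("out") = out, Named("m") = m);
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::mat& m, const arma::mat& w,
                         const arma::cube& dout, arma::ivec xdim,
                         int kh, int kw, int stride, int pad,
                         bool skip_dx = false) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  arma::mat dy(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    dy.col(c) = arma::vectorise(dout.slice(c));
  arma::mat dw = m.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  arma::cube dx(skip_dx ? 0 : xdim(0), skip_dx ? 0 : xdim(1), xdim(2),
                arma::fill::zeros);
  if (!skip_dx) {
    arma::mat dm = dy * w.t();
    col2im_add(dx, dm, kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
double cpp_sq_norm(List grads) {
  double s = 0.0;
  for (int i = 0; i < grads.size(); ++i) {
    List g = grads[i];
    for (int j = 0; j < g.size(); ++j) {
      NumericVector v = g[j];
      for (R_xlen_t k = 0; k < v.size(); ++k) s += v[k] * v[k];
    }
  }
  return s;
}

// Bin boundaries for average ROI pooling: ROI mapped to feature units,
// split into bins x bins integer cell ranges, each at least one cell wide.
static inline void bin_range(double f0, double f1, int nbins, int b, int limit,
                             int& lo, int& hi) {
  double span = f1 - f0;
  lo = (int)std::floor(f0 + span * b / nbins);
  hi = (int)std::ceil(f0 + span * (b + 1) / nbins);
  if (lo < 0) lo = 0;
  if (lo > limit - 1) lo = limit - 1;
  if (hi <= lo) hi = lo + 1;
  if (hi > limit) hi = limit;
  if (hi <= lo) { lo = limit - 1; hi = limit; }
}

// [[Rcpp::export]]
arma::mat cpp_roi_pool_forward(const arma::cube& feat, const arma::mat& rois,
                               double stride, int bins) {
  const int Hf = feat.n_rows, Wf = feat.n_cols, C = feat.n_slices;
  const int n = rois.n_rows;
  arma::mat out(n, bins * bins * C, arma::fill::zeros);
  for (int r = 0; r < n; ++r) {
    double fx0 = std::min(std::max(rois(r, 0) / stride, 0.0), (double)Wf);
    double fy0 = std::min(std::max(rois(r, 1) / stride, 0.0), (double)Hf);
    double fx1 = std::min(std::max(rois(r, 2) / stride, 0.0), (double)Wf);
    double fy1 = std::min(std::max(rois(r, 3) / stride, 0.0), (double)Hf);
    if (fx1 <= fx0) fx1 = fx0 + 1.0;
    if (fy1 <= fy0) fy1 = fy0 + 1.0;
    for (int bi = 0; bi < bins; ++bi) {
      int r0, r1;
      bin_range(fy0, fy1, bins, bi, Hf, r0, r1);
      for (int bj = 0; bj < bins; ++bj) {
        int c0, c1;
        bin_range(fx0, fx1, bins, bj, Wf, c0, c1);
        const double cnt = (double)((r1 - r0) * (c1 - c0));
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int jj = c0; jj < c1; ++jj)
            for (int ii = r0; ii < r1; ++ii)
              s += feat(ii, jj, c);
          out(r, c * bins * bins + bi * bins + bj) = s / cnt;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_roi_pool_backward(int Hf, int Wf, int C, const arma::mat& rois,
                                 double stride, int bins, const arma::mat& dout) {
  arma::cube dfeat(Hf, Wf, C, arma::fill::zeros);
  const int n = rois.n_rows;
  for (int r = 0; r < n; ++r) {
    double fx0 = std::min(std::max(rois(r, 0) / stride, 0.0), (double)Wf);
    double fy0 = std::min(std::max(rois(r, 1) / stride, 0.0), (double)Hf);
    double fx1 = std::min(std::max(rois(r, 2) / stride, 0.0), (double)Wf);
    double fy1 = std::min(std::max(rois(r, 3) / stride, 0.0), (double)Hf);
    if (fx1 <= fx0) fx1 = fx0 + 1.0;
    if (fy1 <= fy0) fy1 = fy0 + 1.0;
    for (int bi = 0; bi < bins; ++bi) {
      int r0, r1;
      bin_range(fy0, fy1, bins, bi, Hf, r0, r1);
      for (int bj = 0; bj < bins; ++bj) {
        int c0, c1;
        bin_range(fx0, fx1, bins, bj, Wf, c0, c1);
        const double cnt = (double)((r1 - r0) * (c1 - c0));
        for (int c = 0; c < C; ++c) {
          const double g = dout(r, c * bins * bins + bi * bins + bj) / cnt;
          for (int jj = c0; jj < c1; ++jj)
            for (int ii = r0; ii < r1; ++ii)
              dfeat(ii, jj, c) += g;
        }
      }
    }
  }
  return dfeat;
}

// Pairwise IoU between two box sets (columns x_min, y_min, x_max, y_max).
// [[Rcpp::export]]
arma::mat cpp_iou_matrix(const arma::mat& a, const arma::mat& b) {
  const int n = a.n_rows, m = b.n_rows;
  arma::mat out(n, m, arma::fill::zeros);
  arma::vec area_a = (a.col(2) - a.col(0)) % (a.col(3) - a.col(1));
  arma::vec area_b = (b.col(2) - b.col(0)) % (b.col(3) - b.col(1));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double iw = std::min(a(i, 2), b(j, 2)) - std::max(a(i, 0), b(j, 0));
      if (iw <= 0) continue;
      const double ih = std::min(a(i, 3), b(j, 3)) - std::max(a(i, 1), b(j, 1));
      if (ih <= 0) continue;
      const double inter = iw * ih;
      out(i, j) = inter / (area_a(i) + area_b(j) - inter);
    }
  }
  return out;
}

// Greedy NMS over boxes already sorted by decreasing score by the caller.
// Returns 1-based indices (into the supplied order) of kept boxes.
// [[Rcpp::export]]
IntegerVector cpp_nms_sorted(const arma::mat& boxes, double iou_thr, int max_keep) {
  const int n = boxes.n_rows;
  std::vector<int> keep;
  std::vector<bool> removed(n, false);
  arma::vec area = (boxes.col(2) - boxes.col(0)) % (boxes.col(3) - boxes.col(1));
  for (int i = 0; i < n; ++i) {
    if (removed[i]) continue;
    keep.push_back(i + 1);
    if ((int)keep.size() >= max_keep) break;
    for (int j = i + 1; j < n; ++j) {
      if (removed[j]) continue;
      const double iw = std::min(boxes(i, 2), boxes(j, 2)) - std::max(boxes(i, 0), boxes(j, 0));
      if (iw <= 0) continue;
      const double ih = std::min(boxes(i, 3), boxes(j, 3)) - std::max(boxes(i, 1), boxes(j, 1));
      if (ih <= 0) continue;
      const double inter = iw * ih;
      if (inter / (area(i) + area(j) - inter) > iou_thr) removed[j] = true;
    }
  }
  return wrap(keep);
}

// [[Rcpp::export]]
arma::cube cpp_relu(const arma::cube& x) {
  arma::cube y = x;
  y.for_each([](double& v) { if (v < 0) v = 0; });
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_relu_bw(const arma::cube& pre, const arma::cube& dout) {
  arma::cube g = dout;
  const double* p = pre.memptr();
  double* q = g.memptr();
  const arma::uword n = g.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (p[i] <= 0) q[i] = 0;
  return g;
}

// Decode center/size deltas against anchors and clip to [0, size] with a
// minimal retained extent. Mirrors decode_deltas()/clip_boxes() on the fast
// path used inside the training loop.
// [[Rcpp::export]]
arma::mat cpp_decode_clip(const arma::mat& anchors, const arma::mat& deltas,
                          double size, double dclamp, double min_size) {
  const int n = anchors.n_rows;
  arma::mat out(n, 4);
  for (int i = 0; i < n; ++i) {
    const double aw = anchors(i, 2) - anchors(i, 0);
    const double ah = anchors(i, 3) - anchors(i, 1);
    const double acx = anchors(i, 0) + aw / 2, acy = anchors(i, 1) + ah / 2;
    const double cx = acx + deltas(i, 0) * aw;
    const double cy = acy + deltas(i, 1) * ah;
    const double w = aw * std::exp(std::min(deltas(i, 2), dclamp));
    const double h = ah * std::exp(std::min(deltas(i, 3), dclamp));
    double x0 = std::min(std::max(cx - w / 2, 0.0), size);
    double x1 = std::min(std::max(cx + w / 2, 0.0), size);
    double y0 = std::min(std::max(cy - h / 2, 0.0), size);
    double y1 = std::min(std::max(cy + h / 2, 0.0), size);
    x1 = std::max(x1, std::min(x0 + min_size, size));
    x0 = std::min(x0, x1 - min_size);
    y1 = std::max(y1, std::min(y0 + min_size, size));
    y0 = std::min(y0, y1 - min_size);
    out(i, 0) = x0; out(i, 1) = y0; out(i, 2) = x1; out(i, 3) = y1;
  }
  return out;
}
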