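// Raster and conv-net kernels backing the classifier, segmenter, Grad-CAM
// and augmentation code. Layout conventions:
//   * image batches are R arrays dim (H, W, C, N), column-major, so each
//     sample is a contiguous H*W*C block;
//   * conv weights are matrices (k*k*Cin x Cout) whose row ordering matches
//     an R array dim (k, k, Cin, Cout) flattened (ki fastest, then kj, then
//     input channel) — identical to the im2col column ordering below.
// All convolutions are 3x3-style "same" convolutions with stride 1 and odd
// kernel size; pooling is 2x2 max with stride 2 on even spatial dims.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void check_dims4(const NumericVector& x, int& H, int& W,
                               int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: out is (H*W) x (k*k*C). Replicate (clamp-to-edge)
// padding: zero padding plants artificial edge features that saliency maps
// then latch onto, so borders are extended instead.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols) {
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        double* dst = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = clampi(w + kj - p, 0, W - 1);
          const double* src = xc + (size_t)ws * H;
          for (int h = 0; h < H; ++h)
            dst[(size_t)w * H + h] = src[clampi(h + ki - p, 0, H - 1)];
        }
      }
    }
  }
}

// scatter-add transpose of im2col_same
static void col2im_same(const arma::mat& cols, int H, int W, int C, int k,
                        double* gx) {
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        const double* src = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = clampi(w + kj - p, 0, W - 1);
          double* dstc = xc + (size_t)ws * H;
          for (int h = 0; h < H; ++h)
            dstc[clampi(h + ki - p, 0, H - 1)] += src[(size_t)w * H + h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fw")]]
NumericVector conv_fw(NumericVector x, NumericMatrix wt, NumericVector b,
                      int k) {
  int H, W, C, N;
  check_dims4(x, H, W, C, N);
  const int Cout = wt.ncol();
  if ((int)wt.nrow() != k * k * C) stop("weight/input channel mismatch");
  NumericVector y((R_xlen_t)((size_t)H * W * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat out(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                  true);
    out = cols * Wm;
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bw")]]
List conv_bw(NumericVector x, NumericMatrix wt, NumericVector gy, int k,
             bool need_gx) {
  int H, W, C, N;
  check_dims4(x, H, W, C, N);
  const int Cout = wt.ncol();
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::mat gW(wt.nrow(), Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((R_xlen_t)((size_t)H * W * C * N));
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    const arma::mat gym((double*)gy.begin() + (size_t)n * H * W * Cout,
                        H * W, Cout, false);
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    gW += cols.t() * gym;
    gb += arma::sum(gym, 0).t();
    if (need_gx) {
      arma::mat gcols = gym * Wm.t();
      col2im_same(gcols, H, W, C, k, gx.begin() + (size_t)n * H * W * C);
    }
  }
  List out = List::create(_["gW"] = wrap(gW), _["gb"] = wrap(gb));
  if (need_gx) out["gx"] = gx;
  return out;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  int H, W, C, N;
  check_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)((size_t)Ho * Wo * C * N));
  IntegerVector idx((R_xlen_t)((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = 0;
          double bv = -1e300;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const double v = xp[(size_t)(2 * w + dw) * H + 2 * h + dh];
              if (v > bv) { bv = v; best = dw * 2 + dh; }
            }
          yp[(size_t)w * Ho + h] = bv;
          ip[(size_t)w * Ho + h] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector gy, IntegerVector idx, int H, int W) {
  int Ho, Wo, C, N;
  check_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((R_xlen_t)((size_t)H * W * C * N));
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int b = ip[(size_t)w * Ho + h];
          xp[(size_t)(2 * w + b / 2) * H + 2 * h + b % 2] +=
              gp[(size_t)w * Ho + h];
        }
    }
  return gx;
}

// [[Rcpp::export(name = ".upsample_fw")]]
NumericVector upsample_fw(NumericVector x) {
  int H, W, C, N;
  check_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          yp[(size_t)w * Ho + h] = xp[(size_t)(w / 2) * H + h / 2];
    }
  return y;
}

// [[Rcpp::export(name = ".upsample_bw")]]
NumericVector upsample_bw(NumericVector gy) {
  int Ho, Wo, C, N;
  check_dims4(gy, Ho, Wo, C, N);
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((R_xlen_t)((size_t)H * W * C * N));
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          xp[(size_t)(w / 2) * H + h / 2] += gp[(size_t)w * Ho + h];
    }
  return gx;
}

// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix x, int ho, int wo) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(ho, wo);
  const double sh = (double)H / ho, sw = (double)W / wo;
  for (int w = 0; w < wo; ++w) {
    double ws = (w + 0.5) * sw - 0.5;
    int w0 = (int)std::floor(ws);
    double fw = ws - w0;
    int w1 = std::min(std::max(w0 + 1, 0), W - 1);
    w0 = std::min(std::max(w0, 0), W - 1);
    for (int h = 0; h < ho; ++h) {
      double hs = (h + 0.5) * sh - 0.5;
      int h0 = (int)std::floor(hs);
      double fh = hs - h0;
      int h1 = std::min(std::max(h0 + 1, 0), H - 1);
      h0 = std::min(std::max(h0, 0), H - 1);
      y(h, w) = (1 - fh) * (1 - fw) * x(h0, w0) + fh * (1 - fw) * x(h1, w0) +
                (1 - fh) * fw * x(h0, w1) + fh * fw * x(h1, w1);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".resize_nearest")]]
NumericMatrix resize_nearest(NumericMatrix x, int ho, int wo) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(ho, wo);
  for (int w = 0; w < wo; ++w) {
    int ws = std::min((int)((w + 0.5) * W / wo), W - 1);
    for (int h = 0; h < ho; ++h) {
      int hs = std::min((int)((h + 0.5) * H / ho), H - 1);
      y(h, w) = x(hs, ws);
    }
  }
  return y;
}

// Inverse-mapped affine warp about the image centre (rotation in degrees,
// isotropic scale, translation in pixels), bilinear sampling, zero fill.
// [[Rcpp::export(name = ".affine_warp")]]
NumericMatrix affine_warp(NumericMatrix x, double angle_deg, double scale,
                          double tx, double ty) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th) / scale, sa = std::sin(th) / scale;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double dx = w - cx - tx, dy = h - cy - ty;
      const double xs = ca * dx + sa * dy + cx;
      const double ys = -sa * dx + ca * dy + cy;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 < -1 || x0 > W - 1 || y0 < -1 || y0 > H - 1) continue;
      const double fx = xs - x0, fy = ys - y0;
      double v = 0.0;
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          const int xc = x0 + dw, yc = y0 + dh;
          if (xc < 0 || xc >= W || yc < 0 || yc >= H) continue;
          v += x(yc, xc) * (dw ? fx : 1 - fx) * (dh ? fy : 1 - fy);
        }
      y(h, w) = v;
    }
  return y;
}

// 4-connected component labelling of a logical raster.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      ++next;
      stack.push_back(w * H + h);
      lab(h, w) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int ph = p % H, pw = p / H;
        const int nb[4][2] = {{ph - 1, pw}, {ph + 1, pw},
                              {ph, pw - 1}, {ph, pw + 1}};
        for (auto& q : nb) {
          if (q[0] < 0 || q[0] >= H || q[1] < 0 || q[1] >= W) continue;
          if (mask(q[0], q[1]) && !lab(q[0], q[1])) {
            lab(q[0], q[1]) = next;
            stack.push_back(q[1] * H + q[0]);
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}
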