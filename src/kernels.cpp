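// Low-level image/tensor kernels.
//
// Convention used throughout the package: an image tensor is an R array of
// dimension (H, W, C), column-major, so it maps directly onto an arma::cube
// (rows = H, cols = W, slices = C).  Coordinates are 0-based (row, col) with
// the origin at the top-left; displacement fields store (dx = col offset,
// dy = row offset) in pixels.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// conv2d: im2col + GEMM
// ---------------------------------------------------------------------------

// transposed im2col: rows = output pixels (ho fastest), cols = kernel taps;
// stride-1 inner spans so the copies are contiguous on both sides
static arma::mat im2colT(const arma::cube &x, int kh, int kw, int stride,
                         int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const size_t N = (size_t)Ho * Wo;
  arma::mat cols(N, (size_t)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const size_t r = i + kh * (j + (size_t)kw * c);
        double *dst = cols.colptr(r);
        const double *src = x.slice_memptr(c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          // valid ho range: 0 <= ho*stride - pad + i < H
          int ho0 = (pad - i + stride - 1) / stride;
          if (ho0 < 0) ho0 = 0;
          int ho1 = (H - 1 + pad - i) / stride;
          if (ho1 > Ho - 1) ho1 = Ho - 1;
          if (stride == 1) {
            const int len = ho1 - ho0 + 1;
            if (len > 0)
              std::memcpy(dst + ho0 + (size_t)Ho * wo,
                          src + (ho0 - pad + i) + (size_t)H * wi,
                          len * sizeof(double));
          } else {
            for (int ho = ho0; ho <= ho1; ++ho)
              dst[ho + (size_t)Ho * wo] = src[(ho * stride - pad + i) +
                                              (size_t)H * wi];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_addT(arma::cube &gx, const arma::mat &gcols, int kh,
                        int kw, int stride, int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const size_t r = i + kh * (j + (size_t)kw * c);
        const double *src = gcols.colptr(r);
        double *dst = gx.slice_memptr(c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          int ho0 = (pad - i + stride - 1) / stride;
          if (ho0 < 0) ho0 = 0;
          int ho1 = (H - 1 + pad - i) / stride;
          if (ho1 > Ho - 1) ho1 = Ho - 1;
          for (int ho = ho0; ho <= ho1; ++ho)
            dst[(ho * stride - pad + i) + (size_t)H * wi] +=
                src[ho + (size_t)Ho * wo];
        }
      }
    }
  }
}

static void out_size(int H, int W, int kh, int kw, int stride, int pad,
                     int &Ho, int &Wo) {
  Ho = (H + 2 * pad - kh) / stride + 1;
  Wo = (W + 2 * pad - kw) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
arma::cube cpp_conv2d_fw(const arma::cube &x, const NumericVector &w,
                         const NumericVector &b, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)x.n_slices != Cin) stop("conv2d: input has %d channels, kernel expects %d",
                                   (int)x.n_slices, Cin);
  int Ho, Wo;
  out_size(x.n_rows, x.n_cols, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat cols = im2colT(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat y = cols * Wm;  // (Ho*Wo) x Cout, matches cube memory layout
  arma::cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(),
              (size_t)Ho * Wo * Cout * sizeof(double));
  for (int c = 0; c < Cout; ++c) out.slice(c) += b[c];
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::cube &x, const NumericVector &w,
                   const arma::cube &gy, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * Cin, Cout, false);
  // gy cube memory is already (Ho*Wo) x Cout in column-major order
  const arma::mat gyT(const_cast<double *>(gy.memptr()), (size_t)Ho * Wo,
                      Cout, false);
  arma::mat cols = im2colT(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat gW = cols.t() * gyT;        // (kh*kw*Cin) x Cout
  arma::vec gb = arma::sum(gyT, 0).t();
  arma::mat gcols = gyT * Wm.t();       // (Ho*Wo) x (kh*kw*Cin)
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_addT(gx, gcols, kh, kw, stride, pad, Ho, Wo);
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx((size_t)Ho * Wo * C);  // 0-based linear index into x
  size_t k = 0;
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300; int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int hi = 2 * ho + di, wi = 2 * wo + dj;
            const double v = x(hi, wi, c);
            if (v > best) { best = v; bi = hi + H * (wi + (size_t)W * c); }
          }
        }
        y(ho, wo, c) = best;
        idx[k++] = bi;
      }
    }
  }
  // fill in column-major order of y: need idx aligned to y's layout
  // (the loop above iterates c slow, wo middle, ho fast => y's layout order
  //  is ho fastest within (wo, c): matches column-major (Ho, Wo, C))
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
arma::cube cpp_maxpool2_bw(const arma::cube &gy, const IntegerVector &idx,
                           int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double *g = gy.memptr();
  double *out = gx.memptr();
  const size_t n = gy.n_elem;
  for (size_t k = 0; k < n; ++k) out[idx[k]] += g[k];
  return gx;
}

// ---------------------------------------------------------------------------
// bilinear 2x upsampling (align_corners = FALSE convention)
// ---------------------------------------------------------------------------

static void up2_coords(int Hin, std::vector<int> &i0, std::vector<int> &i1,
                       std::vector<double> &t) {
  const int Hout = 2 * Hin;
  i0.resize(Hout); i1.resize(Hout); t.resize(Hout);
  for (int o = 0; o < Hout; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > Hin - 1) src = Hin - 1;
    int a = (int)std::floor(src);
    if (a > Hin - 2) a = Hin - 2;
    if (a < 0) a = 0;
    i0[o] = a; i1[o] = (Hin == 1) ? 0 : a + 1;
    t[o] = (Hin == 1) ? 0.0 : src - a;
  }
}

// [[Rcpp::export(name = ".cpp_upsample2_fw")]]
arma::cube cpp_upsample2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_coords(H, r0, r1, tr);
  up2_coords(W, c0, c1, tc);
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < 2 * W; ++wo)
      for (int ho = 0; ho < 2 * H; ++ho) {
        const double a = x(r0[ho], c0[wo], c), b = x(r0[ho], c1[wo], c);
        const double d = x(r1[ho], c0[wo], c), e = x(r1[ho], c1[wo], c);
        y(ho, wo, c) = (1 - tr[ho]) * ((1 - tc[wo]) * a + tc[wo] * b) +
                       tr[ho] * ((1 - tc[wo]) * d + tc[wo] * e);
      }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bw")]]
arma::cube cpp_upsample2_bw(const arma::cube &gy, int H, int W) {
  const int C = gy.n_slices;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_coords(H, r0, r1, tr);
  up2_coords(W, c0, c1, tc);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < 2 * W; ++wo)
      for (int ho = 0; ho < 2 * H; ++ho) {
        const double g = gy(ho, wo, c);
        gx(r0[ho], c0[wo], c) += (1 - tr[ho]) * (1 - tc[wo]) * g;
        gx(r0[ho], c1[wo], c) += (1 - tr[ho]) * tc[wo] * g;
        gx(r1[ho], c0[wo], c) += tr[ho] * (1 - tc[wo]) * g;
        gx(r1[ho], c1[wo], c) += tr[ho] * tc[wo] * g;
      }
  return gx;
}

// ---------------------------------------------------------------------------
// grid sample: out(h, w, c) = img(h + dy(h,w), w + dx(h,w), c), bilinear,
// border replication for out-of-bounds samples.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_grid_sample_fw")]]
arma::cube cpp_grid_sample_fw(const arma::cube &img, const arma::mat &dx,
                              const arma::mat &dy) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out(H, W, C);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double yf = h + dy(h, w), xf = w + dx(h, w);
      if (yf < 0) yf = 0; if (yf > H - 1) yf = H - 1;
      if (xf < 0) xf = 0; if (xf > W - 1) xf = W - 1;
      int y0 = (int)std::floor(yf), x0 = (int)std::floor(xf);
      if (y0 > H - 2) y0 = H - 2; if (y0 < 0) y0 = 0;
      if (x0 > W - 2) x0 = W - 2; if (x0 < 0) x0 = 0;
      const double ty = (H == 1) ? 0.0 : yf - y0, tx = (W == 1) ? 0.0 : xf - x0;
      const int y1 = (H == 1) ? 0 : y0 + 1, x1 = (W == 1) ? 0 : x0 + 1;
      for (int c = 0; c < C; ++c) {
        out(h, w, c) = (1 - ty) * ((1 - tx) * img(y0, x0, c) + tx * img(y0, x1, c)) +
                       ty * ((1 - tx) * img(y1, x0, c) + tx * img(y1, x1, c));
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_grid_sample_bw")]]
List cpp_grid_sample_bw(const arma::cube &img, const arma::mat &dx,
                        const arma::mat &dy, const arma::cube &gout) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube gimg(H, W, C, arma::fill::zeros);
  arma::mat gdx(H, W, arma::fill::zeros), gdy(H, W, arma::fill::zeros);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double yf = h + dy(h, w), xf = w + dx(h, w);
      const bool yin = (yf > 0.0 && yf < H - 1), xin = (xf > 0.0 && xf < W - 1);
      if (yf < 0) yf = 0; if (yf > H - 1) yf = H - 1;
      if (xf < 0) xf = 0; if (xf > W - 1) xf = W - 1;
      int y0 = (int)std::floor(yf), x0 = (int)std::floor(xf);
      if (y0 > H - 2) y0 = H - 2; if (y0 < 0) y0 = 0;
      if (x0 > W - 2) x0 = W - 2; if (x0 < 0) x0 = 0;
      const double ty = (H == 1) ? 0.0 : yf - y0, tx = (W == 1) ? 0.0 : xf - x0;
      const int y1 = (H == 1) ? 0 : y0 + 1, x1 = (W == 1) ? 0 : x0 + 1;
      double sdx = 0.0, sdy = 0.0;
      for (int c = 0; c < C; ++c) {
        const double g = gout(h, w, c);
        const double v00 = img(y0, x0, c), v01 = img(y0, x1, c);
        const double v10 = img(y1, x0, c), v11 = img(y1, x1, c);
        gimg(y0, x0, c) += g * (1 - ty) * (1 - tx);
        gimg(y0, x1, c) += g * (1 - ty) * tx;
        gimg(y1, x0, c) += g * ty * (1 - tx);
        gimg(y1, x1, c) += g * ty * tx;
        sdx += g * ((1 - ty) * (v01 - v00) + ty * (v11 - v10));
        sdy += g * ((1 - tx) * (v10 - v00) + tx * (v11 - v01));
      }
      if (xin) gdx(h, w) = sdx;
      if (yin) gdy(h, w) = sdy;
    }
  }
  return List::create(_["gimg"] = gimg, _["gdx"] = gdx, _["gdy"] = gdy);
}

// ---------------------------------------------------------------------------
// 8-connected component labelling (two-stack flood fill)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int hh = p.first + di, ww = p.second + dj;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
            if (mask(hh, ww) && lab(hh, ww) == 0) {
              lab(hh, ww) = next;
              stack.push_back(std::make_pair(hh, ww));
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// determinism helper: pin OpenBLAS (if that is the BLAS in use) to one
// thread so training runs are bit-reproducible regardless of core count
// ---------------------------------------------------------------------------
#include <dlfcn.h>

// [[Rcpp::export(name = ".cpp_set_blas_threads")]]
bool cpp_set_blas_threads(int n) {
  typedef void (*set_fn)(int);
  void *self = dlopen(NULL, RTLD_NOW | RTLD_GLOBAL);
  if (!self) return false;
  set_fn f = (set_fn)dlsym(self, "openblas_set_num_threads");
  if (!f) f = (set_fn)dlsym(self, "openblas_set_num_threads64_");
  if (f) { f(n); return true; }
  return false;
}
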