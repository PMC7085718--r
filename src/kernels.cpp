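// Low-level numeric kernels shared by the geometric operators and the
// reverse-mode tape. Array convention throughout: R arrays dim (H, W, C),
// column-major, so arma::cube(H, W, C) maps 1:1. Coordinates are 0-based,
// x = column index, y = row index, origin top-left. Displacement fields are
// (H, W, 2) with slice 0 = Dx (columns), slice 1 = Dy (rows), pixel units.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: rows = output pixels (io + Ho*jo), cols = (ki + kh*(kj + kw*c)).
// Zero padding `pad` on all sides.
static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(kh) * kw * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t colidx = ki + static_cast<size_t>(kh) * (kj + static_cast<size_t>(kw) * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            col(io + static_cast<size_t>(Ho) * jo, colidx) = x(i, j, c);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat& col, int H, int W, int C, int kh,
                         int kw, int stride, int pad, int Ho, int Wo) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t colidx = ki + static_cast<size_t>(kh) * (kj + static_cast<size_t>(kw) * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            x(i, j, c) += col(io + static_cast<size_t>(Ho) * jo, colidx);
          }
        }
      }
    }
  }
  return x;
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int Ho = out_size(x.n_rows, kh, stride, pad);
  const int Wo = out_size(x.n_cols, kw, stride, pad);
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat out = col * w;
  out.each_row() += b.t();
  arma::cube y(Ho, Wo, Cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
               int kh, int kw, int stride, int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gym(const_cast<double*>(gy.memptr()), static_cast<size_t>(Ho) * Wo,
                Cout, false, true);
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat gw = col.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcol = gym * w.t();
  arma::cube gx = col2im(gcol, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride,
                         pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// forward that also returns the im2col matrix so the backward pass can skip
// rebuilding it
// [[Rcpp::export(name = ".cpp_conv2d_fw_col")]]
List conv2d_fw_col(const arma::cube& x, const arma::mat& w,
                   const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int Ho = out_size(x.n_rows, kh, stride, pad);
  const int Wo = out_size(x.n_cols, kw, stride, pad);
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat out = col * w;
  out.each_row() += b.t();
  arma::cube y(Ho, Wo, Cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return List::create(_["y"] = y, _["col"] = col);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw_cached")]]
List conv2d_bw_cached(const arma::mat& col, const arma::mat& w,
                      const arma::cube& gy, int H, int W, int C, int kh,
                      int kw, int stride, int pad, bool need_gx) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gym(const_cast<double*>(gy.memptr()), static_cast<size_t>(Ho) * Wo,
                Cout, false, true);
  arma::mat gw = col.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  arma::mat gcol = gym * w.t();
  arma::cube gx = col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Unit-stride average pooling with replicate (edge) padding; shape preserved.
// [[Rcpp::export(name = ".cpp_avgpool_fw")]]
arma::cube avgpool_fw(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = (k - 1) / 2;
  const double inv = 1.0 / (static_cast<double>(k) * k);
  arma::cube y(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int dj = -r; dj <= r; ++dj) {
          const int jj = clampi(j + dj, 0, W - 1);
          for (int di = -r; di <= r; ++di)
            s += x(clampi(i + di, 0, H - 1), jj, c);
        }
        y(i, j, c) = s * inv;
      }
  return y;
}

// Adjoint of avgpool_fw (replicate padding folds border reads back onto edges).
// [[Rcpp::export(name = ".cpp_avgpool_bw")]]
arma::cube avgpool_bw(const arma::cube& gy, int k) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices, r = (k - 1) / 2;
  const double inv = 1.0 / (static_cast<double>(k) * k);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double g = gy(i, j, c) * inv;
        for (int dj = -r; dj <= r; ++dj) {
          const int jj = clampi(j + dj, 0, W - 1);
          for (int di = -r; di <= r; ++di)
            gx(clampi(i + di, 0, H - 1), jj, c) += g;
        }
      }
  return gx;
}

// Backward bilinear warp: y(i,j,c) = src(i + Dy(i,j), j + Dx(i,j), c),
// sample position clamped to the image border (replication).
// [[Rcpp::export(name = ".cpp_warp_bilinear_fw")]]
arma::cube warp_bilinear_fw(const arma::cube& src, const arma::cube& field) {
  const int H = src.n_rows, W = src.n_cols, C = src.n_slices;
  arma::cube y(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double xs = j + field(i, j, 0), ys = i + field(i, j, 1);
      xs = std::min(std::max(xs, 0.0), static_cast<double>(W - 1));
      ys = std::min(std::max(ys, 0.0), static_cast<double>(H - 1));
      const int x0 = std::min(static_cast<int>(std::floor(xs)), W - 2 >= 0 ? W - 2 : 0);
      const int y0 = std::min(static_cast<int>(std::floor(ys)), H - 2 >= 0 ? H - 2 : 0);
      const double fx = xs - x0, fy = ys - y0;
      for (int c = 0; c < C; ++c) {
        const double v00 = src(y0, x0, c), v01 = src(y0, x0 + 1, c);
        const double v10 = src(y0 + 1, x0, c), v11 = src(y0 + 1, x0 + 1, c);
        y(i, j, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                     fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  return y;
}

// Gradients wrt both the source image and the field. Where the sample
// position is clamped at the border the positional derivative is zero.
// [[Rcpp::export(name = ".cpp_warp_bilinear_bw")]]
List warp_bilinear_bw(const arma::cube& src, const arma::cube& field,
                      const arma::cube& gy) {
  const int H = src.n_rows, W = src.n_cols, C = src.n_slices;
  arma::cube gsrc(H, W, C, arma::fill::zeros);
  arma::cube gfield(H, W, 2, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double xs = j + field(i, j, 0), ys = i + field(i, j, 1);
      const bool inx = (xs > 0.0 && xs < W - 1);
      const bool iny = (ys > 0.0 && ys < H - 1);
      xs = std::min(std::max(xs, 0.0), static_cast<double>(W - 1));
      ys = std::min(std::max(ys, 0.0), static_cast<double>(H - 1));
      const int x0 = std::min(static_cast<int>(std::floor(xs)), W - 2 >= 0 ? W - 2 : 0);
      const int y0 = std::min(static_cast<int>(std::floor(ys)), H - 2 >= 0 ? H - 2 : 0);
      const double fx = xs - x0, fy = ys - y0;
      double gdx = 0.0, gdy = 0.0;
      for (int c = 0; c < C; ++c) {
        const double g = gy(i, j, c);
        if (g == 0.0) continue;
        const double v00 = src(y0, x0, c), v01 = src(y0, x0 + 1, c);
        const double v10 = src(y0 + 1, x0, c), v11 = src(y0 + 1, x0 + 1, c);
        gsrc(y0, x0, c) += g * (1 - fy) * (1 - fx);
        gsrc(y0, x0 + 1, c) += g * (1 - fy) * fx;
        gsrc(y0 + 1, x0, c) += g * fy * (1 - fx);
        gsrc(y0 + 1, x0 + 1, c) += g * fy * fx;
        gdx += g * ((1 - fy) * (v01 - v00) + fy * (v11 - v10));
        gdy += g * ((1 - fx) * (v10 - v00) + fx * (v11 - v01));
      }
      if (inx) gfield(i, j, 0) = gdx;
      if (iny) gfield(i, j, 1) = gdy;
    }
  return List::create(_["gsrc"] = gsrc, _["gfield"] = gfield);
}

// [[Rcpp::export(name = ".cpp_warp_nearest")]]
arma::cube warp_nearest(const arma::cube& src, const arma::cube& field) {
  const int H = src.n_rows, W = src.n_cols, C = src.n_slices;
  arma::cube y(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int xs = clampi(static_cast<int>(std::lround(j + field(i, j, 0))), 0, W - 1);
      const int ys = clampi(static_cast<int>(std::lround(i + field(i, j, 1))), 0, H - 1);
      for (int c = 0; c < C; ++c) y(i, j, c) = src(ys, xs, c);
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_nearest_fw")]]
arma::cube upsample_nearest_fw(const arma::cube& x, int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H * f, W * f, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W * f; ++j)
      for (int i = 0; i < H * f; ++i) y(i, j, c) = x(i / f, j / f, c);
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_nearest_bw")]]
arma::cube upsample_nearest_bw(const arma::cube& gy, int f) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(Ho / f, Wo / f, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) gx(i / f, j / f, c) += gy(i, j, c);
  return gx;
}

// Bilinear resize to (Ho, Wo); pixel-center alignment
// (src = (dst + 0.5) * H/Ho - 0.5), clamped at borders.
// [[Rcpp::export(name = ".cpp_resize_bilinear_fw")]]
arma::cube resize_bilinear_fw(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double sy = static_cast<double>(H) / Ho, sx = static_cast<double>(W) / Wo;
  arma::cube y(Ho, Wo, C);
  for (int j = 0; j < Wo; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    xs = std::min(std::max(xs, 0.0), static_cast<double>(W - 1));
    const int x0 = std::min(static_cast<int>(std::floor(xs)), W - 2 >= 0 ? W - 2 : 0);
    const double fx = xs - x0;
    for (int i = 0; i < Ho; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      ys = std::min(std::max(ys, 0.0), static_cast<double>(H - 1));
      const int y0 = std::min(static_cast<int>(std::floor(ys)), H - 2 >= 0 ? H - 2 : 0);
      const double fy = ys - y0;
      for (int c = 0; c < C; ++c)
        y(i, j, c) = (1 - fy) * ((1 - fx) * x(y0, x0, c) + fx * x(y0, x0 + 1, c)) +
                     fy * ((1 - fx) * x(y0 + 1, x0, c) + fx * x(y0 + 1, x0 + 1, c));
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_bw")]]
arma::cube resize_bilinear_bw(const arma::cube& gy, int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  const double sy = static_cast<double>(H) / Ho, sx = static_cast<double>(W) / Wo;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    xs = std::min(std::max(xs, 0.0), static_cast<double>(W - 1));
    const int x0 = std::min(static_cast<int>(std::floor(xs)), W - 2 >= 0 ? W - 2 : 0);
    const double fx = xs - x0;
    for (int i = 0; i < Ho; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      ys = std::min(std::max(ys, 0.0), static_cast<double>(H - 1));
      const int y0 = std::min(static_cast<int>(std::floor(ys)), H - 2 >= 0 ? H - 2 : 0);
      const double fy = ys - y0;
      for (int c = 0; c < C; ++c) {
        const double g = gy(i, j, c);
        gx(y0, x0, c) += g * (1 - fy) * (1 - fx);
        gx(y0, x0 + 1, c) += g * (1 - fy) * fx;
        gx(y0 + 1, x0, c) += g * fy * (1 - fx);
        gx(y0 + 1, x0 + 1, c) += g * fy * fx;
      }
    }
  }
  return gx;
}

// Exact symmetric mean contour distance between two point sets given as
// n x 2 matrices of 0-based (x, y) pixel coordinates.
// [[Rcpp::export(name = ".cpp_symmetric_set_distance")]]
double symmetric_set_distance(const arma::mat& a, const arma::mat& b) {
  const size_t na = a.n_rows, nb = b.n_rows;
  double total = 0.0;
  for (size_t i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (size_t j = 0; j < nb; ++j) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      const double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    total += std::sqrt(best);
  }
  for (size_t j = 0; j < nb; ++j) {
    double best = std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < na; ++i) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      const double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    total += std::sqrt(best);
  }
  return total / static_cast<double>(na + nb);
}
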