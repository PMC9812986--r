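// Low-level kernels for the CPU convolutional-network engine and image warps.
// Tensor layout: arma::cube with (rows = H, cols = W, slices = channels),
// matching R arrays of dim c(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for stride-1 'same' zero-padded k x k convolution.
// Output: (H*W) x (k*k*Cin); column index = ci*k*k + kj*k + ki.
static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat out(H * W, k * k * C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& xc = x.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ci * k * k + kj * k + ki;
        // source pixel (i + ki - p, j + kj - p) for output pixel (i, j)
        const int i0 = std::max(0, p - ki), i1 = std::min(H, H + p - ki);
        const int j0 = std::max(0, p - kj), j1 = std::min(W, W + p - kj);
        for (int j = j0; j < j1; ++j) {
          const int sj = j + kj - p;
          double* dst = out.colptr(col) + j * H;
          const double* src = xc.colptr(sj);
          for (int i = i0; i < i1; ++i) dst[i] = src[i + ki - p];
        }
      }
    }
  }
  return out;
}

// scatter-add of a (H*W) x (k*k*Cin) matrix back into a H x W x Cin cube
static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int k) {
  const int p = (k - 1) / 2;
  cube out(H, W, C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    mat& xc = out.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ci * k * k + kj * k + ki;
        const int i0 = std::max(0, p - ki), i1 = std::min(H, H + p - ki);
        const int j0 = std::max(0, p - kj), j1 = std::min(W, W + p - kj);
        for (int j = j0; j < j1; ++j) {
          const int sj = j + kj - p;
          const double* src = cols.colptr(col) + j * H;
          double* dst = xc.colptr(sj);
          for (int i = i0; i < i1; ++i) dst[i + ki - p] += src[i];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_conv2d_fwd")]]
arma::cube nn_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col_same(x, k);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".nn_conv2d_bwd")]]
Rcpp::List nn_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  mat cols = im2col_same(x, k);
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  mat gcols = gym * w.t();
  cube gx = col2im_same(gcols, H, W, C, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 stride-2 max pooling; argmax stored as 0-based linear index into x slice
// [[Rcpp::export(name = ".nn_maxpool2_fwd")]]
Rcpp::List nn_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xc(2 * i, 2 * j);
        uword bi = 2 * i + (uword)(2 * j) * H;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = xc(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = (2 * i + di) + (uword)(2 * j + dj) * H; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".nn_maxpool2_bwd")]]
arma::cube nn_maxpool2_bwd(const arma::cube& gy, const arma::ucube& idx,
                           const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gc(idx(i, j, c)) += gy(i, j, c);
  }
  return gx;
}

// 2x2 stride-2 transposed convolution (non-overlapping upsample).
// w: (Cin) x (4*Cout), column = co*4 + dj*2 + di.
// [[Rcpp::export(name = ".nn_convtr2_fwd")]]
arma::cube nn_convtr2_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols / 4;
  mat xm(const_cast<double*>(x.memptr()), H * W, C, false, true);
  mat ym = xm * w;  // (H*W) x (4*Cout)
  cube out(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    mat& oc = out.slice(co);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const double* src = ym.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            oc(2 * i + di, 2 * j + dj) = src[i + j * H] + b(co);
      }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_convtr2_bwd")]]
Rcpp::List nn_convtr2_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat xm(const_cast<double*>(x.memptr()), H * W, C, false, true);
  mat gym(H * W, 4 * Cout);
  vec gb(Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const mat& gc = gy.slice(co);
    gb(co) = accu(gc);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double* dst = gym.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dst[i + j * H] = gc(2 * i + di, 2 * j + dj);
      }
  }
  mat gx = gym * w.t();
  mat gw = xm.t() * gym;
  cube gxc(H, W, C);
  std::memcpy(gxc.memptr(), gx.memptr(), sizeof(double) * gx.n_elem);
  return Rcpp::List::create(Rcpp::Named("gx") = gxc, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Inverse-mapping warp: out(i,j) = img(map_r(i,j), map_c(i,j)), 0-based
// fractional source coordinates; bilinear or nearest sampling; out-of-range
// coordinates are clamped to the image border.
// [[Rcpp::export(name = ".warp_sample")]]
arma::cube warp_sample(const arma::cube& img, const arma::mat& map_r,
                       const arma::mat& map_c, const bool nearest) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const int Ho = map_r.n_rows, Wo = map_r.n_cols;
  cube out(Ho, Wo, C);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double r = std::min(std::max(map_r(i, j), 0.0), (double)(H - 1));
      double c = std::min(std::max(map_c(i, j), 0.0), (double)(W - 1));
      if (nearest) {
        int ri = (int)std::lround(r), ci = (int)std::lround(c);
        for (int ch = 0; ch < C; ++ch) out(i, j, ch) = img(ri, ci, ch);
      } else {
        int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double fr = r - r0, fc = c - c0;
        for (int ch = 0; ch < C; ++ch) {
          double v = (1 - fr) * (1 - fc) * img(r0, c0, ch) +
                     fr * (1 - fc) * img(r1, c0, ch) +
                     (1 - fr) * fc * img(r0, c1, ch) +
                     fr * fc * img(r1, c1, ch);
          out(i, j, ch) = v;
        }
      }
    }
  }
  return out;
}
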