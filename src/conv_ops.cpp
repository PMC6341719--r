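// Minimal 2D conv-net primitives: 3x3 same-padding convolution, 2x2 max
// pooling and nearest-neighbour 2x upsampling, each with its adjoint.
// Feature maps are H x W x C cubes (R arrays, column-major); convolution
// weights are (C_out) x (C_in * 9) matrices so the forward pass is a single
// GEMM over an im2col buffer.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col for a 3x3 kernel with zero padding 1, transposed layout:
// (H*W) x (C*9), so each (c, dj, di, j) strip is a contiguous memcpy.
// Column order within a channel block: dj (column offset) outer, di inner,
// both in {-1,0,1}; matches the weight layout used throughout.
static mat im2col3T(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat colsT(H * W, C * 9, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword col = c * 9 + (uword)(dj + 1) * 3 + (uword)(di + 1);
        double* dst = colsT.colptr(col);
        const uword i0 = (di < 0) ? 1 : 0;            // valid output rows
        const uword i1 = (di > 0) ? H - 1 : H;
        const uword len = i1 - i0;
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          std::memcpy(dst + j * H + i0,
                      xs + (uword)sj * H + (uword)((int)i0 + di),
                      len * sizeof(double));
        }
      }
    }
  }
  return colsT;
}

// Adjoint of im2col3T: scatter-add an (H*W) x (C*9) matrix back to H x W x C.
static cube col2im3T(const mat& colsT, uword H, uword W, uword C) {
  cube x(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* xs = x.slice_memptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword col = c * 9 + (uword)(dj + 1) * 3 + (uword)(di + 1);
        const double* src = colsT.colptr(col);
        const uword i0 = (di < 0) ? 1 : 0;
        const uword i1 = (di > 0) ? H - 1 : H;
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          double* xd = xs + (std::ptrdiff_t)((long long)sj * (long long)H + di);
          const double* sp = src + j * H;
          for (uword i = i0; i < i1; ++i) xd[i] += sp[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b) {
  const uword H = x.n_rows, Wd = x.n_cols, Cout = W.n_rows;
  mat colsT = im2col3T(x);
  mat outT = colsT * W.t();    // (H*W) x Cout: slices are already contiguous
  outT.each_row() += b.t();
  return cube(outT.memptr(), H, Wd, Cout);
}

// [[Rcpp::export(name = ".conv_bwd")]]
Rcpp::List conv_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& gy) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const uword Cout = gy.n_slices;
  const mat gyT(gy.memptr(), H * Wd, Cout);
  mat colsT = im2col3T(x);
  mat gW = gyT.t() * colsT;
  vec gb = sum(gyT, 0).t();
  mat gcolsT = gyT * W;        // (H*W) x (Cin*9)
  cube gx = col2im3T(gcolsT, H, Wd, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2. H and W must be even (checked in R).
// idx records, per output element, the linear index of the winning input
// voxel within its slice (0-based, stored as double), for the adjoint pass.
// [[Rcpp::export(name = ".pool_fwd")]]
Rcpp::List pool_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);
  for (uword c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const uword bi = 2 * i, bj = 2 * j;
        double best = xs[bj * H + bi];
        uword besti = bj * H + bi;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword li = (bj + dj) * H + (bi + di);
            if (xs[li] > best) { best = xs[li]; besti = li; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = (double)besti;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".pool_bwd")]]
arma::cube pool_bwd(const arma::cube& gy, const arma::cube& idx,
                    int H, int W) {
  const uword C = gy.n_slices;
  cube gx((uword)H, (uword)W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* slc = gx.slice_memptr(c);
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i)
        slc[(uword)idx(i, j, c)] += gy(i, j, c);
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample_fwd")]]
arma::cube upsample_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
arma::cube upsample_bwd(const arma::cube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// Rectifier and its mask, in C++ to avoid large temporary allocations in R.
// [[Rcpp::export(name = ".relu_cube")]]
arma::cube relu_cube(const arma::cube& x) {
  cube y = x;
  y.for_each([](double& v) { if (v < 0) v = 0; });
  return y;
}

// gy masked by (act > 0), where act is the post-rectifier activation.
// [[Rcpp::export(name = ".relu_bwd")]]
arma::cube relu_bwd(const arma::cube& gy, const arma::cube& act) {
  cube gx = gy;
  const double* a = act.memptr();
  double* g = gx.memptr();
  const uword n = gx.n_elem;
  for (uword k = 0; k < n; ++k)
    if (a[k] <= 0) g[k] = 0;
  return gx;
}
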