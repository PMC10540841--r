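// Low-level numeric kernels: 3x3 same-padding convolution (via im2col so the
// inner product runs through BLAS), 2x2 max pooling, 2x2-stride-2 transposed
// convolution, and a bilinear affine raster warp. Layout conventions:
//   - images/feature maps are H x W x C arma::cubes (R arrays, column-major);
//   - a 3x3 kernel stack is a (9*Cin) x Cout matrix, row index ci*9 + (dj+1)*3 + (di+1)
//     where (di, dj) is the (row, col) tap offset in {-1, 0, 1};
//   - a 2x2 transposed-conv kernel stack is a (4*Cin) x Cout matrix, row index
//     ci*4 + b*2 + a for output offset (a, b) in {0, 1}^2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const arma::uword k = c * 9 + (dj + 1) * 3 + (di + 1);
        for (arma::uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          const arma::uword i0 = (di < 0) ? 1 : 0;
          const arma::uword i1 = (di > 0) ? H - 1 : H;
          if (i1 <= i0) continue;
          // rows i0..i1-1 of output column come from rows i0+di..i1-1+di
          std::copy(x.slice(c).colptr(sj) + i0 + di,
                    x.slice(c).colptr(sj) + i1 + di,
                    cols.colptr(k) + j * H + i0);
        }
      }
    }
  }
  return cols;
}

static void col2im3_add(const arma::mat& gcols, arma::cube& gx) {
  const arma::uword H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (arma::uword c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const arma::uword k = c * 9 + (dj + 1) * 3 + (di + 1);
        for (arma::uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          const arma::uword i0 = (di < 0) ? 1 : 0;
          const arma::uword i1 = (di > 0) ? H - 1 : H;
          if (i1 <= i0) continue;
          double* dst = gx.slice(c).colptr(sj) + i0 + di;
          const double* src = gcols.colptr(k) + j * H + i0;
          for (arma::uword i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  arma::mat y = im2col3(x) * w;          // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::mat gym(const_cast<double*>(gy.memptr()), H * W, gy.n_slices, false);
  arma::mat cols = im2col3(x);
  arma::mat gw = cols.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcols = gym * w.t();
  arma::cube gx(H, W, x.n_slices, arma::fill::zeros);
  col2im3_add(gcols, gx);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C); // 0..3: which corner (a + 2*b) won
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < w; ++j)
      for (arma::uword i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c); arma::uword bk = 0;
        const double v01 = x(2 * i + 1, 2 * j, c);
        const double v10 = x(2 * i, 2 * j + 1, c);
        const double v11 = x(2 * i + 1, 2 * j + 1, c);
        if (v01 > best) { best = v01; bk = 1; }
        if (v10 > best) { best = v10; bk = 2; }
        if (v11 > best) { best = v11; bk = 3; }
        y(i, j, c) = best; idx(i, j, c) = bk;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                        int H, int W) {
  const arma::uword h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < w; ++j)
      for (arma::uword i = 0; i < h; ++i) {
        const arma::uword k = idx(i, j, c);
        gx(2 * i + (k & 1u), 2 * j + (k >> 1), c) += gy(i, j, c);
      }
  return gx;
}

// [[Rcpp::export(name = ".upconv2_fwd")]]
arma::cube upconv2_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = w.n_cols;
  const arma::mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false);
  arma::cube y(2 * H, 2 * W, Cout);
  for (arma::uword co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  arma::uvec rows(Cin);
  for (arma::uword bb = 0; bb < 2; ++bb)
    for (arma::uword aa = 0; aa < 2; ++aa) {
      for (arma::uword c = 0; c < Cin; ++c) rows(c) = c * 4 + bb * 2 + aa;
      arma::mat yab = xm * w.rows(rows); // (H*W) x Cout
      for (arma::uword co = 0; co < Cout; ++co)
        for (arma::uword j = 0; j < W; ++j) {
          double* dst = y.slice(co).colptr(2 * j + bb) + aa;
          const double* src = yab.colptr(co) + j * H;
          for (arma::uword i = 0; i < H; ++i) dst[2 * i] += src[i];
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upconv2_bwd")]]
List upconv2_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = gy.n_slices;
  const arma::mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false);
  arma::mat gx(H * W, Cin, arma::fill::zeros);
  arma::mat gw(4 * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::uvec rows(Cin);
  arma::mat gyab(H * W, Cout);
  for (arma::uword bb = 0; bb < 2; ++bb)
    for (arma::uword aa = 0; aa < 2; ++aa) {
      for (arma::uword c = 0; c < Cin; ++c) rows(c) = c * 4 + bb * 2 + aa;
      for (arma::uword co = 0; co < Cout; ++co)
        for (arma::uword j = 0; j < W; ++j) {
          const double* src = gy.slice(co).colptr(2 * j + bb) + aa;
          double* dst = gyab.colptr(co) + j * H;
          for (arma::uword i = 0; i < H; ++i) dst[i] = src[2 * i];
        }
      gx += gyab * w.rows(rows).t();
      gw.rows(rows) += xm.t() * gyab;
      gb += arma::sum(gyab, 0).t();
    }
  arma::cube gxc(gx.memptr(), H, W, Cin);
  return List::create(_["gx"] = gxc, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear warp: `m` is the 2x3 matrix sending OUTPUT pixel coords (x, y)
// (0-based, pixel centers at integers) to source coords; outside pixels -> 0.
// [[Rcpp::export(name = ".warp_bilinear")]]
arma::cube warp_bilinear(const arma::cube& img, const arma::mat& m,
                         int out_h, int out_w) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out(out_h, out_w, C, arma::fill::zeros);
  for (int j = 0; j < out_w; ++j) {
    for (int i = 0; i < out_h; ++i) {
      const double sx = m(0, 0) * j + m(0, 1) * i + m(0, 2);
      const double sy = m(1, 0) * j + m(1, 1) * i + m(1, 2);
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      for (int c = 0; c < C; ++c) {
        double v = 0.0;
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int xx = x0 + dx, yy = y0 + dy;
            if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
            const double wgt = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy);
            v += wgt * img(yy, xx, c);
          }
        out(i, j, c) = v;
      }
    }
  }
  return out;
}
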