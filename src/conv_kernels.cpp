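// 3x3 same-padding convolution kernels used by the UNet / BB-UNet / detector
// implementations. Images are batched in (H, W, C, N) arrays (column-major,
// so each channel plane is contiguous). Convolution is im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill M (H*W x 9*C) with the 3x3 neighbourhoods of one image, zero padded.
// Column r = ki + 3*kj + 9*c matches the column-major layout of a
// (3, 3, C, Cout) weight array flattened to (9*C x Cout).
static void im2col3(const double* x, int H, int W, int C, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        double* Mc = M.colptr(ki + 3 * kj + 9 * c);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - 1;
          double* Mcol = Mc + (std::size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::fill(Mcol, Mcol + H, 0.0);
            continue;
          }
          const double* xcol = xc + (std::size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - 1;
            Mcol[i] = (si < 0 || si >= H) ? 0.0 : xcol[si];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient GM (H*W x 9*C) back onto gx.
static void col2im3(const arma::mat& GM, int H, int W, int C, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (std::size_t)c * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const double* Mc = GM.colptr(ki + 3 * kj + 9 * c);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - 1;
          if (sj < 0 || sj >= W) continue;
          const double* Mcol = Mc + (std::size_t)j * H;
          double* gcol = gc + (std::size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - 1;
            if (si < 0 || si >= H) continue;
            gcol[si] += Mcol[i];
          }
        }
      }
    }
  }
}

static void get_dims4(const NumericVector& x, int d[4], const char* what) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("%s must be a 4-D (H, W, C, N) array", what);
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export(name = ".conv3x3_fw")]]
NumericVector conv3x3_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx, "x");
  get_dims4(w, dw, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Co = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C)
    stop("weight dims do not match input channels");
  if (b.size() != Co) stop("bias length must equal output channels");

  NumericVector y((R_xlen_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat Wm(w.begin(), 9 * C, Co, false, true);
  arma::mat M(H * W, 9 * C);
  arma::rowvec bv(b.begin(), Co);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * H * W * C, H, W, C, M);
    arma::mat Y(y.begin() + (std::size_t)n * H * W * Co, H * W, Co, false, true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3x3_bw")]]
List conv3x3_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx, "x");
  get_dims4(w, dw, "w");
  get_dims4(gy, dg, "gy");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Co = dw[3];
  if (dg[0] != H || dg[1] != W || dg[2] != Co || dg[3] != N)
    stop("gradient dims do not match");

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((R_xlen_t)9 * C * Co);
  gw.attr("dim") = IntegerVector::create(3, 3, C, Co);
  NumericVector gb(Co);
  arma::mat Wm(w.begin(), 9 * C, Co, false, true);
  arma::mat GW(gw.begin(), 9 * C, Co, false, true);
  arma::rowvec GB(gb.begin(), Co, false, true);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * H * W * C, H, W, C, M);
    arma::mat Gy(gy.begin() + (std::size_t)n * H * W * Co, H * W, Co, false, true);
    GW += M.t() * Gy;
    GB += arma::sum(Gy, 0);
    arma::mat GM = Gy * Wm.t();
    col2im3(GM, H, W, C, gx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
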