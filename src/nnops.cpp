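// Low-level operators for the U-Net family: 2-D convolution (same padding)
// forward/backward via im2col + GEMM, 2x2 max pooling, nearest-neighbour
// upsampling, a bilateral filter, and a CRC32 used by the PNG writer.
//
// Array layout convention (column-major, matching R): feature maps are
// (H, W, C, N); convolution kernels are (K, K, Cin, Cout) with K odd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * (w + (arma::uword)W * (c + (arma::uword)C * n));
}

static void im2col(const double* x, int H, int W, int Cin, int K, arma::mat& M) {
  // M is (H*W) x (K*K*Cin); x points at one sample (H,W,Cin).
  // Column-major M means writes along h are contiguous.
  const int P = (K - 1) / 2;
  double* Mp = M.memptr();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col = ki + K * (kj + K * ci);
        double* Mc = Mp + (size_t)H * W * col;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - P;
          double* dst = Mc + (size_t)H * w;
          if (sw < 0 || sw >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * sw + (ki - P);
          const int h0 = std::max(0, P - ki), h1 = H + std::min(0, P - ki);
          std::fill(dst, dst + h0, 0.0);
          std::copy(src + h0, src + h1, dst + h0);
          std::fill(dst + h1, dst + H, 0.0);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[1] != K || wd[2] != Cin) stop("kernel dims inconsistent with input");
  NumericVector y(R_xlen_t(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), (arma::uword)(K * K * Cin), (arma::uword)Cout, false);
  arma::mat M((arma::uword)(H * W), (arma::uword)(K * K * Cin));
  for (int n = 0; n < N; ++n) {
    im2col(&x[idx4(0, 0, 0, n, H, W, Cin)], H, W, Cin, K, M);
    arma::mat Y(&y[idx4(0, 0, 0, n, H, W, Cout)], (arma::uword)(H * W),
                (arma::uword)Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3], P = (K - 1) / 2;
  NumericVector gx(R_xlen_t(H) * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw(R_xlen_t(K) * K * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), (arma::uword)(K * K * Cin), (arma::uword)Cout, false);
  arma::mat GW(gw.begin(), (arma::uword)(K * K * Cin), (arma::uword)Cout, false, true);
  arma::mat M((arma::uword)(H * W), (arma::uword)(K * K * Cin));
  for (int n = 0; n < N; ++n) {
    arma::mat GY(&gy[idx4(0, 0, 0, n, H, W, Cout)], (arma::uword)(H * W),
                 (arma::uword)Cout, false);
    im2col(&x[idx4(0, 0, 0, n, H, W, Cin)], H, W, Cin, K, M);
    GW += M.t() * GY;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(GY.col(co));
    // gradient wrt input: col2im of GY * Wm'
    arma::mat Gcol = GY * Wm.t();  // (H*W) x (K*K*Cin)
    double* gxp = &gx[idx4(0, 0, 0, n, H, W, Cin)];
    const double* Gp = Gcol.memptr();
    for (int ci = 0; ci < Cin; ++ci) {
      double* gxc = gxp + (size_t)H * W * ci;
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          const int col = ki + K * (kj + K * ci);
          const double* Gc = Gp + (size_t)H * W * col;
          for (int w_ = 0; w_ < W; ++w_) {
            const int sw = w_ + kj - P;
            if (sw < 0 || sw >= W) continue;
            const double* g = Gc + (size_t)H * w_;
            double* dst = gxc + (size_t)H * sw + (ki - P);
            const int h0 = std::max(0, P - ki), h1 = H + std::min(0, P - ki);
            for (int h = h0; h < h1; ++h) dst[h] += g[h];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".nn_maxpool_fwd")]]
List nn_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  IntegerVector idx(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          double best = -1e300; arma::uword bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              arma::uword i = idx4(2 * h + dh, 2 * w + dw, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          y[o] = best;
          idx[o] = (int)bi;  // linear 0-based index into x
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nn_maxpool_bwd")]]
NumericVector nn_maxpool_bwd(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  R_xlen_t n = R_xlen_t(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < gy.size(); ++o) gx[idx[o]] += gy[o];
  return gx;
}

// [[Rcpp::export(name = ".nn_upsample_fwd")]]
NumericVector nn_upsample_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = x[idx4(h, w, c, n, H, W, C)];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              y[idx4(2 * h + dh, 2 * w + dw, c, n, Ho, Wo, C)] = v;
        }
  return y;
}

// [[Rcpp::export(name = ".nn_upsample_bwd")]]
NumericVector nn_upsample_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              s += gy[idx4(2 * h + dh, 2 * w + dw, c, n, Ho, Wo, C)];
          gx[idx4(h, w, c, n, H, W, C)] = s;
        }
  return gx;
}

// [[Rcpp::export(name = ".bilateral_cpp")]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_spatial,
                            double sigma_range, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double ss2 = 2.0 * sigma_spatial * sigma_spatial;
  const double sr2 = 2.0 * sigma_range * sigma_range;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double v0 = img(i, j);
      double num = 0, den = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -radius; di <= radius; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          const double dv = img(ii, jj) - v0;
          const double wgt = std::exp(-(di * di + dj * dj) / ss2 - dv * dv / sr2);
          num += wgt * img(ii, jj);
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  return out;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector bytes) {
  static uint32_t tab[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      tab[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    crc = tab[(crc ^ bytes[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
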