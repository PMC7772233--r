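// Minimal 2-D convolution / pooling primitives for the segmentation network.
// Feature maps are arma::cube with dimensions (H, W, C); kernels arrive as a
// (kh*kw*Cin) x Cout matrix whose row index is di + kh*(dj + kw*c), i.e. the
// column-major flattening of an R array dim c(kh, kw, Cin).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(Ho * (size_t)Wo, (size_t)kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t q = di + (size_t)kh * (dj + (size_t)kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride + di - pad;
            if (si < 0 || si >= H) continue;
            col(i + (size_t)Ho * j, q) = xs(si, sj);
          }
        }
      }
    }
  }
  return col;
}

static int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& wt,
                      const arma::vec& bias, int kh, int kw,
                      int stride, int pad) {
  const int Ho = out_dim(x.n_rows, kh, stride, pad);
  const int Wo = out_dim(x.n_cols, kw, stride, pad);
  const int Cout = wt.n_cols;
  mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat y = col * wt;
  y.each_row() += bias.t();
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.col(co), Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& wt,
                      const arma::cube& gy, int kh, int kw,
                      int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat gym(Ho * (size_t)Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    gym.col(co) = vectorise(gy.slice(co));
  mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gw = col.t() * gym;
  vec gb = sum(gym, 0).t();
  mat gcol = gym * wt.t();           // (Ho*Wo) x (kh*kw*Cin)
  cube gx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    mat& gxs = gx.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t q = di + (size_t)kh * (dj + (size_t)kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride + di - pad;
            if (si < 0 || si >= H) continue;
            gxs(si, sj) += gcol(i + (size_t)Ho * j, q);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
Rcpp::List maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  cube y(Ho, Wo, C);
  ucube arg(Ho, Wo, C);              // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dj = 0; dj < k; ++dj) {
          const int sj = j * stride + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int si = i * stride + di - pad;
            if (si < 0 || si >= H) continue;
            const double v = xs(si, sj);
            if (v > best) { best = v; bidx = si + (uword)H * sj; }
          }
        }
        y(i, j, c) = best;
        arg(i, j, c) = bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("arg") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& gy, const arma::ucube& arg,
                       int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gxs = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gxs(arg(i, j, c)) += gy(i, j, c);
  }
  return gx;
}
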