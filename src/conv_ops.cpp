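// Compute kernels for the convolutional image branch: 3x3 same-padding
// convolution via im2col + GEMM, spatial batch normalization, ReLU and
// 2x2 max-pooling, each with its backward pass. Arrays follow R's
// column-major N x H x W x C layout, so channel c of a feature map is one
// contiguous block of N*H*W doubles and can be viewed as column c of an
// (N*H*W) x C matrix without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3(const double* xp, int N, int H, int W, int C,
                    arma::mat& cols) {
  // cols: (N*H*W) x (9*C), offset order dj (cols) outer, di (rows) inner,
  // matching the weight layout used by the R builders
  cols.zeros();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di, ++k) {
      for (int c = 0; c < C; ++c) {
        double* dst = cols.colptr((std::size_t)k * C + c);
        const double* src = xp + (std::size_t)N * H * W * c;
        for (int w = 0; w < W; ++w) {
          int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hs = h + di;
            if (hs < 0 || hs >= H) continue;
            std::memcpy(dst + (std::size_t)N * (h + (std::size_t)H * w),
                        src + (std::size_t)N * (hs + (std::size_t)H * ws),
                        (std::size_t)N * sizeof(double));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, const arma::mat& Wm,
                           const arma::vec& b) {
  IntegerVector dd = x.attr("dim");
  int N = dd[0], H = dd[1], W = dd[2], C = dd[3];
  int F = Wm.n_cols;
  arma::mat cols((std::size_t)N * H * W, 9 * (std::size_t)C);
  im2col3(x.begin(), N, H, W, C, cols);
  arma::mat y = cols * Wm;
  y.each_row() += b.t();
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(N, H, W, F);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, const arma::mat& Wm, NumericVector dy) {
  IntegerVector dd = x.attr("dim");
  int N = dd[0], H = dd[1], W = dd[2], C = dd[3];
  int F = Wm.n_cols;
  std::size_t M = (std::size_t)N * H * W;
  arma::mat cols(M, 9 * (std::size_t)C);
  im2col3(x.begin(), N, H, W, C, cols);
  arma::mat dym(dy.begin(), M, F, false);
  arma::mat dW = cols.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = dym * Wm.t();

  // col2im: scatter-add each offset block back onto the input grid
  NumericVector dx((std::size_t)M * C);
  double* dxp = dx.begin();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di, ++k) {
      for (int c = 0; c < C; ++c) {
        const double* src = dcols.colptr((std::size_t)k * C + c);
        double* dst = dxp + (std::size_t)N * H * W * c;
        for (int w = 0; w < W; ++w) {
          int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hs = h + di;
            if (hs < 0 || hs >= H) continue;
            double* d0 = dst + (std::size_t)N * (hs + (std::size_t)H * ws);
            const double* s0 = src + (std::size_t)N * (h + (std::size_t)H * w);
            for (int n = 0; n < N; ++n) d0[n] += s0[n];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, const arma::vec& gamma,
                const arma::vec& beta, double eps, bool training,
                const arma::vec& rmean, const arma::vec& rvar) {
  IntegerVector dd = x.attr("dim");
  int C = dd[dd.size() - 1];
  std::size_t M = (std::size_t)x.size() / C;
  arma::mat xm(x.begin(), M, C, false);
  arma::vec mu(C), var(C);
  if (training) {
    mu = arma::mean(xm, 0).t();
    var = arma::var(xm, 1, 0).t();   // population variance
  } else {
    mu = rmean;
    var = rvar;
  }
  arma::vec istd = 1.0 / arma::sqrt(var + eps);
  NumericVector y(x.size());
  arma::mat ym(y.begin(), M, C, false, true);
  for (int c = 0; c < C; ++c) {
    double a = gamma[c] * istd[c];
    double b0 = beta[c] - mu[c] * a;
    ym.col(c) = a * xm.col(c) + b0;
  }
  y.attr("dim") = dd;
  return List::create(_["out"] = y, _["mu"] = wrap(mu), _["var"] = wrap(var),
                      _["istd"] = wrap(istd));
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, const arma::vec& mu,
                const arma::vec& istd, const arma::vec& gamma) {
  IntegerVector dd = x.attr("dim");
  int C = dd[dd.size() - 1];
  std::size_t M = (std::size_t)x.size() / C;
  arma::mat xm(x.begin(), M, C, false);
  arma::mat dym(dy.begin(), M, C, false);
  NumericVector dx(x.size());
  arma::mat dxm(dx.begin(), M, C, false, true);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    arma::vec xhat = (xm.col(c) - mu[c]) * istd[c];
    dgamma[c] = arma::dot(dym.col(c), xhat);
    dbeta[c] = arma::accu(dym.col(c));
    // dx = gamma*istd/M * (M*dy - sum(dy) - xhat*sum(dy*xhat))
    dxm.col(c) = (gamma[c] * istd[c] / (double)M) *
      ((double)M * dym.col(c) - dbeta[c] - xhat * dgamma[c]);
  }
  dx.attr("dim") = dd;
  return List::create(_["dx"] = dx, _["dgamma"] = wrap(dgamma),
                      _["dbeta"] = wrap(dbeta));
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (std::size_t i = 0; i < (std::size_t)x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* gp = dx.begin();
  for (std::size_t i = 0; i < (std::size_t)x.size(); ++i)
    gp[i] = xp[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x) {
  IntegerVector dd = x.attr("dim");
  int N = dd[0], H = dd[1], W = dd[2], C = dd[3];
  int Ho = H / 2, Wo = W / 2;
  std::size_t Mo = (std::size_t)N * Ho * Wo * C;
  NumericVector y(Mo);
  IntegerVector idx(Mo);   // linear index into x of each max
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    std::size_t xoff = (std::size_t)N * H * W * c;
    std::size_t yoff = (std::size_t)N * Ho * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        std::size_t ybase = yoff + (std::size_t)N * (h + (std::size_t)Ho * w);
        for (int n = 0; n < N; ++n) {
          double best = -1e300;
          std::size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              std::size_t xi = xoff +
                (std::size_t)n +
                (std::size_t)N * ((2 * h + dh) + (std::size_t)H * (2 * w + dw));
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          }
          yp[ybase + n] = best;
          ip[ybase + n] = (int)bi;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(IntegerVector idx, NumericVector dy,
                           IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double* gp = dx.begin();
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  for (std::size_t i = 0; i < (std::size_t)dy.size(); ++i)
    gp[ip[i]] += dp[i];
  dx.attr("dim") = xdim;
  return dx;
}
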