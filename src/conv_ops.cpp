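// Low-level batched layer primitives for the encoder-decoder segmentation
// network: same-padding convolution via im2col/col2im, 2x2 max pooling,
// nearest-neighbour upsampling, 2x2 average pooling (for the concatenating
// path's multi-scale inputs) and batch normalisation. Activations are R
// arrays of dim (H, W, C, N), which map directly onto column-major
// Armadillo memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_k(const double* x, int H, int W, int C, int k) {
  // rows: H*W output positions; cols: k*k*C patch entries, offset-major
  const int pad = k / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dc = -pad; dc <= pad; ++dc) {
      for (int dr = -pad; dr <= pad; ++dr, ++col) {
        for (int j = 0; j < W; ++j) {
          int js = j + dc;
          if (js < 0 || js >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r0 >= r1) continue;
          std::copy(xc + (size_t)js * H + r0 + dr,
                    xc + (size_t)js * H + r1 + dr,
                    out.colptr(col) + (size_t)j * H + r0);
        }
      }
    }
  }
  return out;
}

static void col2im_k(const arma::mat& cols, double* gx, int H, int W, int C,
                     int k) {
  const int pad = k / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int dc = -pad; dc <= pad; ++dc) {
      for (int dr = -pad; dr <= pad; ++dr, ++col) {
        const double* src = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          int js = j + dc;
          if (js < 0 || js >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r) {
            xc[(size_t)js * H + r + dr] += src[(size_t)j * H + r];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                       int k) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("weight/channel mismatch");
  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_k(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat y = cols * wm;
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)n * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericMatrix w, NumericVector gy, int k) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat gw(w.nrow(), Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_k(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat gym(gy.begin() + (size_t)n * H * W * Cout, H * W, Cout, false);
    gw += cols.t() * gym;
    gb += arma::sum(gym, 0);
    arma::mat gcols = gym * wm.t();
    col2im_k(gcols, gx.begin() + (size_t)n * H * W * C, H, W, C, k);
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(w.nrow(), Cout, gw.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx(out.size());  // linear index into x of each max
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = base + (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t) if (xp[cand[t]] > xp[best]) best = cand[t];
          *op++ = xp[best];
          *ip++ = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx,
                           IntegerVector in_dim) {
  NumericVector gx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  double* gp = gx.begin();
  for (R_xlen_t t = 0; t < gy.size(); ++t) gp[idx[t]] += gy[t];
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out = alloc4(2 * H, 2 * W, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* os = op + s * 4 * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = xs[(size_t)j * H + i];
        size_t p = (size_t)(2 * j) * 2 * H + 2 * i;
        os[p] = v; os[p + 1] = v;
        os[p + 2 * H] = v; os[p + 2 * H + 1] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  IntegerVector d = dims4(gy);
  int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector out = alloc4(H, W, C, N);
  const double* gp = gy.begin();
  double* op = out.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* gs = gp + s * (size_t)H2 * W2;
    double* os = op + s * (size_t)H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        size_t p = (size_t)(2 * j) * H2 + 2 * i;
        os[(size_t)j * H + i] = gs[p] + gs[p + 1] + gs[p + H2] + gs[p + H2 + 1];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + s * (size_t)H * W;
    double* os = op + s * (size_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        size_t p = (size_t)(2 * j) * H + 2 * i;
        os[(size_t)j * Ho + i] =
          0.25 * (xs[p] + xs[p + 1] + xs[p + H] + xs[p + H + 1]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector out = alloc4(H, W, C, N);
  NumericVector mean(C), var(C);
  double M = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) { s += xs[t]; s2 += xs[t] * xs[t]; }
    }
    double m = s / M, v = s2 / M - m * m;
    mean[c] = m; var[c] = v;
    double inv = gamma[c] / std::sqrt(v + eps);
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * plane;
      double* os = out.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) os[t] = (xs[t] - m) * inv + beta[c];
    }
  }
  return List::create(_["y"] = out, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
            NumericVector mean, NumericVector var, double eps) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  double M = (double)plane * N;
  NumericVector gx = alloc4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(var[c] + eps);
    double sum_gy = 0, sum_gy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * plane;
      const double* gs = gy.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        double xhat = (xs[t] - mean[c]) * istd;
        sum_gy += gs[t];
        sum_gy_xhat += gs[t] * xhat;
      }
    }
    ggamma[c] = sum_gy_xhat;
    gbeta[c] = sum_gy;
    double k1 = gamma[c] * istd;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * plane;
      const double* gs = gy.begin() + ((size_t)n * C + c) * plane;
      double* os = gx.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        double xhat = (xs[t] - mean[c]) * istd;
        os[t] = k1 * (gs[t] - sum_gy / M - xhat * sum_gy_xhat / M);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// BN inference transform with running statistics.
// [[Rcpp::export]]
NumericVector bn_infer(NumericVector x, NumericVector gamma,
                       NumericVector beta, NumericVector mean,
                       NumericVector var, double eps) {
  IntegerVector d = dims4(x);
  int C = d[2], N = d[3];
  size_t plane = (size_t)d[0] * d[1];
  NumericVector out = alloc4(d[0], d[1], C, N);
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * plane;
      double* os = out.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) os[t] = (xs[t] - mean[c]) * inv + beta[c];
    }
  }
  return out;
}
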