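// Low-level numerical kernels for the denoising network and the simulator.
//
// Arrays follow R's column-major layout.  A feature map batch is a 4-D
// array [H, W, C, N]; convolution weights are a matrix [k*k*Cin, Cout]
// whose rows are ordered tap-fastest within each input channel
// (column q = c*k*k + tj*k + ti, with ti the row offset index and tj the
// column offset index).  All convolutions are "same size": the padding is
// dilation*(k-1)/2 and out-of-field taps read zeros.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void get_dim4(const Rcpp::NumericVector& x, int& H, int& W, int& C,
                     int& N) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-d array [H, W, C, N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static Rcpp::NumericVector make4(int H, int W, int C, int N) {
  Rcpp::NumericVector v((std::size_t)H * W * C * N);
  v.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  return v;
}

static Rcpp::IntegerVector make4i(int H, int W, int C, int N) {
  Rcpp::IntegerVector v((std::size_t)H * W * C * N);
  v.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  return v;
}

// Fill `col` ([H*W, k*k*C]) with the im2col expansion of one sample.
// Single precision: the convolution GEMMs run in float32 (as deep-learning
// frameworks do); parameters and activations stay double at the R level.
static void im2col_fill(const float* x, int H, int W, int C, int k, int dil,
                        fmat& col) {
  const int K = k * k, r = (k - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (std::size_t)c * H * W;
    for (int tj = 0; tj < k; ++tj) {
      for (int ti = 0; ti < k; ++ti) {
        const int q = c * K + tj * k + ti;
        const int di = (ti - r) * dil, dj = (tj - r) * dil;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i1 <= i0) continue;
        float* dst0 = col.colptr(q);
        for (int j = j0; j < j1; ++j) {
          const float* src = xc + (std::size_t)(j + dj) * H + (i0 + di);
          std::memcpy(dst0 + (std::size_t)j * H + i0, src,
                      sizeof(float) * (i1 - i0));
        }
      }
    }
  }
}

// Scatter-accumulate the transpose of im2col (used for input gradients).
static void col2im_acc(const fmat& col, float* gx, int H, int W, int C, int k,
                       int dil) {
  const int K = k * k, r = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    float* gc = gx + (std::size_t)c * H * W;
    for (int tj = 0; tj < k; ++tj) {
      for (int ti = 0; ti < k; ++ti) {
        const int q = c * K + tj * k + ti;
        const int di = (ti - r) * dil, dj = (tj - r) * dil;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i1 <= i0) continue;
        const float* src0 = col.colptr(q);
        for (int j = j0; j < j1; ++j) {
          float* dst = gc + (std::size_t)(j + dj) * H + (i0 + di);
          const float* src = src0 + (std::size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_fw(Rcpp::NumericVector x,
                                  const arma::mat& w,
                                  const arma::vec& b, int k, int dil) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const int Cout = w.n_cols;
  if ((int)w.n_rows != k * k * C)
    Rcpp::stop("weight rows do not match k*k*Cin");
  Rcpp::NumericVector y = make4(H, W, Cout, N);
  fmat col(H * W, k * k * C);
  const fmat wf = conv_to<fmat>::from(w);
  const frowvec bf = conv_to<frowvec>::from(b.t());
  const std::size_t xs = (std::size_t)H * W * C;
  const std::size_t ys = (std::size_t)H * W * Cout;
  std::vector<float> xf(xs);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xs;
    for (std::size_t t = 0; t < xs; ++t) xf[t] = (float)xn[t];
    im2col_fill(xf.data(), H, W, C, k, dil, col);
    fmat ymat = col * wf;
    ymat.each_row() += bf;
    double* yn = y.begin() + n * ys;
    const float* ym = ymat.memptr();
    for (std::size_t t = 0; t < ys; ++t) yn[t] = (double)ym[t];
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(Rcpp::NumericVector x, const arma::mat& w,
                         Rcpp::NumericVector gy, int k, int dil,
                         bool need_gx) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const int Cout = w.n_cols;
  Rcpp::NumericVector gx = make4(H, W, C, N);
  fmat gwf(w.n_rows, w.n_cols, fill::zeros);
  fvec gbf(Cout, fill::zeros);
  fmat col(H * W, k * k * C);
  const fmat wf = conv_to<fmat>::from(w);
  const std::size_t xs = (std::size_t)H * W * C;
  const std::size_t ys = (std::size_t)H * W * Cout;
  std::vector<float> xf(xs), gxf(xs);
  fmat gymat(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xs;
    for (std::size_t t = 0; t < xs; ++t) xf[t] = (float)xn[t];
    im2col_fill(xf.data(), H, W, C, k, dil, col);
    const double* gyn = gy.begin() + n * ys;
    float* gym = gymat.memptr();
    for (std::size_t t = 0; t < ys; ++t) gym[t] = (float)gyn[t];
    gwf += col.t() * gymat;
    gbf += sum(gymat, 0).t();
    if (need_gx) {
      fmat gcol = gymat * wf.t();
      std::fill(gxf.begin(), gxf.end(), 0.0f);
      col2im_acc(gcol, gxf.data(), H, W, C, k, dil);
      double* gxn = gx.begin() + n * xs;
      for (std::size_t t = 0; t < xs; ++t) gxn[t] = (double)gxf[t];
    }
  }
  mat gw = conv_to<mat>::from(gwf);
  vec gb = conv_to<vec>::from(gbf);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling with stride 2.  H and W must be even; `idx` records the
// 0-based linear index of the winning input element within each sample.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(Rcpp::NumericVector x) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  if (H % 2 || W % 2) Rcpp::stop("maxpool expects even spatial extents");
  const int Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector y = make4(Ho, Wo, C, N);
  Rcpp::IntegerVector idx = make4i(Ho, Wo, C, N);
  const std::size_t xs = (std::size_t)H * W * C;
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xs;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (std::size_t)c * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          const int i2 = 2 * i, j2 = 2 * j;
          std::size_t best = (std::size_t)j2 * H + i2;
          const std::size_t cand[3] = {best + 1, best + H, best + H + 1};
          double bv = xc[best];
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          y[o] = bv;
          idx[o] = (int)((std::size_t)c * H * W + best);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool2_bw(Rcpp::IntegerVector idx,
                                    Rcpp::NumericVector gy, int H, int W) {
  int Ho, Wo, C, N;
  get_dim4(gy, Ho, Wo, C, N);
  Rcpp::NumericVector gx = make4(H, W, C, N);
  const std::size_t xs = (std::size_t)H * W * C;
  const std::size_t ys = (std::size_t)Ho * Wo * C;
  for (int n = 0; n < N; ++n) {
    double* gxn = gx.begin() + n * xs;
    const double* gyn = gy.begin() + n * ys;
    const int* in = idx.begin() + n * ys;
    for (std::size_t t = 0; t < ys; ++t) gxn[in[t]] += gyn[t];
  }
  return gx;
}

// Index/weight pairs for 2x bilinear upsampling (align_corners = FALSE,
// edges clamped): output o samples input at (o + 0.5)/2 - 0.5.
static void up2_coef(int Hin, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w1) {
  const int Ho = 2 * Hin;
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double fr = s - f;
    int a = std::min(std::max(f, 0), Hin - 1);
    int b = std::min(std::max(f + 1, 0), Hin - 1);
    i0[o] = a; i1[o] = b; w1[o] = fr;
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_fw(Rcpp::NumericVector x) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  Rcpp::NumericVector y = make4(Ho, Wo, C, N);
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_coef(H, ri0, ri1, rw);
  up2_coef(W, cj0, cj1, cw);
  const std::size_t xs = (std::size_t)H * W, planes = (std::size_t)C * N;
  for (std::size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * xs;
    double* yp = y.begin() + p * (std::size_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* ca = xp + (std::size_t)cj0[j] * H;
      const double* cb = xp + (std::size_t)cj1[j] * H;
      const double wj = cw[j];
      double* yc = yp + (std::size_t)j * Ho;
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        const double va = ca[ri0[i]] * (1 - wi) + ca[ri1[i]] * wi;
        const double vb = cb[ri0[i]] * (1 - wi) + cb[ri1[i]] * wi;
        yc[i] = va * (1 - wj) + vb * wj;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_bw(Rcpp::NumericVector gy) {
  int Ho, Wo, C, N;
  get_dim4(gy, Ho, Wo, C, N);
  const int H = Ho / 2, W = Wo / 2;
  Rcpp::NumericVector gx = make4(H, W, C, N);
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  up2_coef(H, ri0, ri1, rw);
  up2_coef(W, cj0, cj1, cw);
  const std::size_t xs = (std::size_t)H * W, planes = (std::size_t)C * N;
  for (std::size_t p = 0; p < planes; ++p) {
    double* gxp = gx.begin() + p * xs;
    const double* gyp = gy.begin() + p * (std::size_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      double* ca = gxp + (std::size_t)cj0[j] * H;
      double* cb = gxp + (std::size_t)cj1[j] * H;
      const double wj = cw[j];
      const double* gc = gyp + (std::size_t)j * Ho;
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        const double g = gc[i];
        ca[ri0[i]] += g * (1 - wi) * (1 - wj);
        ca[ri1[i]] += g * wi * (1 - wj);
        cb[ri0[i]] += g * (1 - wi) * wj;
        cb[ri1[i]] += g * wi * wj;
      }
    }
  }
  return gx;
}

// Rigid translation of one frame by (dy, dx) pixels: output(i, j) samples
// input(i - dy, j - dx) with edge replication, nearest or bilinear.
// [[Rcpp::export]]
arma::mat cpp_translate(const arma::mat& x, double dy, double dx,
                        bool bilinear) {
  const int H = x.n_rows, W = x.n_cols;
  mat y(H, W);
  for (int j = 0; j < W; ++j) {
    const double sj = j - dx;
    for (int i = 0; i < H; ++i) {
      const double si = i - dy;
      if (bilinear) {
        int fi = (int)std::floor(si), fj = (int)std::floor(sj);
        double ri = si - fi, rj = sj - fj;
        int i0 = std::min(std::max(fi, 0), H - 1);
        int i1 = std::min(std::max(fi + 1, 0), H - 1);
        int j0 = std::min(std::max(fj, 0), W - 1);
        int j1 = std::min(std::max(fj + 1, 0), W - 1);
        y(i, j) = x(i0, j0) * (1 - ri) * (1 - rj) + x(i1, j0) * ri * (1 - rj) +
                  x(i0, j1) * (1 - ri) * rj + x(i1, j1) * ri * rj;
      } else {
        int ni = std::min(std::max((int)std::lround(si), 0), H - 1);
        int nj = std::min(std::max((int)std::lround(sj), 0), W - 1);
        y(i, j) = x(ni, nj);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_lrelu_fw(Rcpp::NumericVector x, double slope) {
  Rcpp::NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const std::size_t n = x.size();
  for (std::size_t t = 0; t < n; ++t)
    yi[t] = xi[t] >= 0 ? xi[t] : slope * xi[t];
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_lrelu_bw(Rcpp::NumericVector x,
                                 Rcpp::NumericVector gy, double slope) {
  Rcpp::NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  const double* gi = gy.begin();
  double* go = gx.begin();
  const std::size_t n = x.size();
  for (std::size_t t = 0; t < n; ++t)
    go[t] = xi[t] >= 0 ? gi[t] : slope * gi[t];
  return gx;
}
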