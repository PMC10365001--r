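// Hot kernels for the conv-net engine: im2col + BLAS GEMM convolution
// (forward), col2im scatter-add (backward), and instance normalization.
// Tensors arrive as R arrays with layout (H, W, N, C), column-major. The
// im2col matrix has one row per output position (h2 fastest, then w2,
// then batch) and one column per (kernel-offset, input-channel) pair,
// offsets outermost.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector b,
                  int k, int s, int p) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int H2 = (H + 2 * p - k) / s + 1;
  const int W2 = (W + 2 * p - k) / s + 1;
  const int Cout = Wm.ncol();
  const R_xlen_t n = (R_xlen_t)H2 * W2 * N;
  const int ncol = C * k * k;

  NumericVector Xcol(no_init(n * ncol));
  double* Xp = Xcol.begin();
  const double* xp = x.begin();
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int j = dy * k + dx;
      for (int c = 0; c < C; ++c) {
        double* col = Xp + (R_xlen_t)(j * C + c) * n;
        for (int nn = 0; nn < N; ++nn) {
          const double* xbase = xp + ((R_xlen_t)c * N + nn) * H * W;
          for (int w2 = 0; w2 < W2; ++w2) {
            const int ws = w2 * s + dx - p;
            double* dst = col + (R_xlen_t)nn * H2 * W2 + (R_xlen_t)w2 * H2;
            if (ws < 0 || ws >= W) {
              std::fill(dst, dst + H2, 0.0);
              continue;
            }
            const double* src = xbase + (R_xlen_t)ws * H;
            for (int h2 = 0; h2 < H2; ++h2) {
              const int hs = h2 * s + dy - p;
              dst[h2] = (hs >= 0 && hs < H) ? src[hs] : 0.0;
            }
          }
        }
      }
    }
  }

  arma::mat Xa(Xp, n, ncol, false, true);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false, true);
  NumericVector out(no_init(n * Cout));
  arma::mat Oa(out.begin(), n, Cout, false, true);
  Oa = Xa * Wa;
  for (int co = 0; co < Cout; ++co) Oa.col(co) += b[co];
  out.attr("dim") = IntegerVector::create(H2, W2, N, Cout);
  Xcol.attr("dim") = IntegerVector::create((int)n, ncol);
  return List::create(_["out"] = out, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector Xcol, NumericVector dout, NumericMatrix Wm,
                  IntegerVector din, int k, int s, int p) {
  const int H = din[0], W = din[1], N = din[2], C = din[3];
  const int H2 = (H + 2 * p - k) / s + 1;
  const int W2 = (W + 2 * p - k) / s + 1;
  const int Cout = Wm.ncol();
  const R_xlen_t n = (R_xlen_t)H2 * W2 * N;
  const int ncol = C * k * k;

  arma::mat Xa(Xcol.begin(), n, ncol, false, true);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false, true);
  arma::mat Da(dout.begin(), n, Cout, false, true);

  NumericMatrix dW(ncol, Cout);
  arma::mat dWa(dW.begin(), ncol, Cout, false, true);
  dWa = Xa.t() * Da;
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(Da.col(co));

  arma::mat dXcol = Da * Wa.t();

  NumericVector dx((R_xlen_t)H * W * N * C);  // zero-initialized
  double* dxp = dx.begin();
  for (int dy = 0; dy < k; ++dy) {
    for (int dx_ = 0; dx_ < k; ++dx_) {
      const int j = dy * k + dx_;
      for (int c = 0; c < C; ++c) {
        const double* col = dXcol.colptr(j * C + c);
        for (int nn = 0; nn < N; ++nn) {
          double* xbase = dxp + ((R_xlen_t)c * N + nn) * H * W;
          for (int w2 = 0; w2 < W2; ++w2) {
            const int ws = w2 * s + dx_ - p;
            if (ws < 0 || ws >= W) continue;
            const double* src = col + (R_xlen_t)nn * H2 * W2 +
              (R_xlen_t)w2 * H2;
            double* dst = xbase + (R_xlen_t)ws * H;
            for (int h2 = 0; h2 < H2; ++h2) {
              const int hs = h2 * s + dy - p;
              if (hs >= 0 && hs < H) dst[hs] += src[h2];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = din;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Instance norm: each (batch, channel) plane is standardized over its
// H x W extent, then scaled/shifted per channel.

// [[Rcpp::export]]
List in_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  const int nc = N * C;
  NumericVector out(no_init(hw * nc));
  NumericVector xhat(no_init(hw * nc));
  NumericVector isd(nc);
  const double* xp = x.begin();
  double* op = out.begin();
  double* hp = xhat.begin();
  for (int col = 0; col < nc; ++col) {
    const int c = col / N;
    const double* xc = xp + (R_xlen_t)col * hw;
    double sum = 0, sumsq = 0;
    for (R_xlen_t i = 0; i < hw; ++i) { sum += xc[i]; sumsq += xc[i] * xc[i]; }
    const double mu = sum / hw;
    const double var = sumsq / hw - mu * mu;
    const double s = 1.0 / std::sqrt(var + eps);
    isd[col] = s;
    const double g = gamma[c], bt = beta[c];
    double* oc = op + (R_xlen_t)col * hw;
    double* hc = hp + (R_xlen_t)col * hw;
    for (R_xlen_t i = 0; i < hw; ++i) {
      const double xh = (xc[i] - mu) * s;
      hc[i] = xh;
      oc[i] = xh * g + bt;
    }
  }
  out.attr("dim") = dims;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["isd"] = isd);
}

// [[Rcpp::export]]
List in_bwd_cpp(NumericVector dout, NumericVector xhat, NumericVector isd,
                NumericVector gamma, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  const int nc = N * C;
  NumericVector dx(no_init(hw * nc));
  NumericVector dgamma(C), dbeta(C);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  double* xp = dx.begin();
  for (int col = 0; col < nc; ++col) {
    const int c = col / N;
    const double g = gamma[c], s = isd[col];
    const double* dc = dp + (R_xlen_t)col * hw;
    const double* hc = hp + (R_xlen_t)col * hw;
    double sd = 0, sdh = 0;
    for (R_xlen_t i = 0; i < hw; ++i) { sd += dc[i]; sdh += dc[i] * hc[i]; }
    dgamma[c] += sdh;
    dbeta[c] += sd;
    const double m1 = g * sd / hw;
    const double m2 = g * sdh / hw;
    double* xc = xp + (R_xlen_t)col * hw;
    for (R_xlen_t i = 0; i < hw; ++i)
      xc[i] = (g * dc[i] - m1 - hc[i] * m2) * s;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
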