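// Compute kernels for the 1-D convolution and max-pooling layers.
// Activation tensors are [length, batch, channels] in R's column-major
// layout; convolution weights are [k * in_ch, out_ch] with the kernel
// offset varying fastest within a channel block. GEMMs go through
// Armadillo (BLAS); the patch gather/scatter is plain loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// zero-pad [L,B,C] -> [L+2p,B,C]
static std::vector<double> pad_cpp(const double* x, int L, int B, int C,
                                   int pad, int& Lp) {
  Lp = L + 2 * pad;
  std::vector<double> out(static_cast<size_t>(Lp) * B * C, 0.0);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* src = x + static_cast<size_t>(c) * L * B +
        static_cast<size_t>(b) * L;
      double* dst = out.data() + static_cast<size_t>(c) * Lp * B +
        static_cast<size_t>(b) * Lp + pad;
      std::copy(src, src + L, dst);
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List pool1d_fwd(NumericVector X, int L, int B, int C, int k, int stride) {
  const int out_len = (L - k) / stride + 1;
  NumericVector Y(static_cast<size_t>(out_len) * B * C);
  IntegerVector arg(Y.size());
  const double* x = X.begin();
  double* y = Y.begin();
  int* a = arg.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* col = x + static_cast<size_t>(c) * L * B +
        static_cast<size_t>(b) * L;
      double* ycol = y + static_cast<size_t>(c) * out_len * B +
        static_cast<size_t>(b) * out_len;
      int* acol = a + static_cast<size_t>(c) * out_len * B +
        static_cast<size_t>(b) * out_len;
      for (int p = 0; p < out_len; ++p) {
        const double* w = col + static_cast<size_t>(p) * stride;
        double best = w[0];
        int besti = 0;
        for (int i = 1; i < k; ++i) {
          if (w[i] > best) { best = w[i]; besti = i; }
        }
        ycol[p] = best;
        acol[p] = besti;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(out_len, B, C);
  return List::create(Named("out") = Y, Named("arg") = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector pool1d_bwd(NumericVector dY, IntegerVector arg,
                         int L, int B, int C, int k, int stride) {
  const int out_len = (L - k) / stride + 1;
  NumericVector dX(static_cast<size_t>(L) * B * C);
  const double* dy = dY.begin();
  const int* a = arg.begin();
  double* dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* dycol = dy + static_cast<size_t>(c) * out_len * B +
        static_cast<size_t>(b) * out_len;
      const int* acol = a + static_cast<size_t>(c) * out_len * B +
        static_cast<size_t>(b) * out_len;
      double* dxcol = dx + static_cast<size_t>(c) * L * B +
        static_cast<size_t>(b) * L;
      for (int p = 0; p < out_len; ++p) {
        dxcol[static_cast<size_t>(p) * stride + acol[p]] += dycol[p];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(L, B, C);
  return dX;
}

// One fused Adam update for a single parameter leaf: returns the new
// parameter, first- and second-moment vectors in one pass.
// [[Rcpp::export(rng = false)]]
List adam_leaf_cpp(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double beta1, double beta2,
                   double eps, double t) {
  const R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(Named("p") = p2, Named("m") = m2, Named("v") = v2);
}

// Forward convolution that also hands the patch matrix back to the caller
// so the backward pass can reuse it instead of rebuilding it.
// [[Rcpp::export(rng = false)]]
List conv1d_fwd_cache(NumericVector X, NumericMatrix W, NumericVector b,
                      int L, int B, int C, int pad) {
  const int k = W.nrow() / C;
  const int O = W.ncol();
  int Lp = L;
  const double* xp = X.begin();
  std::vector<double> padded;
  if (pad > 0) {
    padded = pad_cpp(X.begin(), L, B, C, pad, Lp);
    xp = padded.data();
  }
  const int out_len = Lp - k + 1;
  // patch matrix built directly in R-owned memory so it can be cached
  // for the backward pass without a copy
  NumericMatrix XcolR(static_cast<size_t>(out_len) * B,
                      static_cast<size_t>(k) * C);
  arma::mat Xcol(XcolR.begin(), XcolR.nrow(), XcolR.ncol(), false, true);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < k; ++i) {
      double* dst = Xcol.colptr(c * k + i);
      for (int b2 = 0; b2 < B; ++b2) {
        const double* src = xp + static_cast<size_t>(c) * Lp * B +
          static_cast<size_t>(b2) * Lp + i;
        std::copy(src, src + out_len, dst + static_cast<size_t>(b2) * out_len);
      }
    }
  }
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(),
                     false, true);
  arma::mat Y = Xcol * Wm;
  for (int o = 0; o < O; ++o) Y.col(o) += b[o];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(out_len, B, O);
  return List::create(Named("out") = out, Named("Xcol") = XcolR);
}

// Backward convolution reusing the cached patch matrix.
// [[Rcpp::export(rng = false)]]
List conv1d_bwd_cached(NumericMatrix Xcol, NumericMatrix W, NumericVector dY,
                       int L, int B, int C, int pad, bool need_dx) {
  const int k = W.nrow() / C;
  const int Lp = L + 2 * pad;
  const int out_len = Lp - k + 1;
  const arma::mat Xc(const_cast<double*>(Xcol.begin()), Xcol.nrow(),
                     Xcol.ncol(), false, true);
  const arma::mat dYm(const_cast<double*>(dY.begin()),
                      static_cast<size_t>(out_len) * B, W.ncol(), false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(),
                     false, true);
  arma::mat gW = Xc.t() * dYm;
  arma::rowvec gb = arma::sum(dYm, 0);
  NumericMatrix gWr(gW.n_rows, gW.n_cols);
  std::copy(gW.begin(), gW.end(), gWr.begin());
  NumericVector gbr(gb.begin(), gb.end());
  if (!need_dx) {
    return List::create(Named("W") = gWr, Named("b") = gbr,
                        Named("dX") = R_NilValue);
  }
  arma::mat dXcol = dYm * Wm.t();
  std::vector<double> dXp(static_cast<size_t>(Lp) * B * C, 0.0);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < k; ++i) {
      const double* src = dXcol.colptr(c * k + i);
      for (int b2 = 0; b2 < B; ++b2) {
        double* dst = dXp.data() + static_cast<size_t>(c) * Lp * B +
          static_cast<size_t>(b2) * Lp + i;
        const double* sp = src + static_cast<size_t>(b2) * out_len;
        for (int p = 0; p < out_len; ++p) dst[p] += sp[p];
      }
    }
  }
  NumericVector dX(static_cast<size_t>(L) * B * C);
  for (int c = 0; c < C; ++c) {
    for (int b2 = 0; b2 < B; ++b2) {
      const double* src = dXp.data() + static_cast<size_t>(c) * Lp * B +
        static_cast<size_t>(b2) * Lp + pad;
      std::copy(src, src + L,
                dX.begin() + static_cast<size_t>(c) * L * B +
                  static_cast<size_t>(b2) * L);
    }
  }
  dX.attr("dim") = IntegerVector::create(L, B, C);
  return List::create(Named("W") = gWr, Named("b") = gbr, Named("dX") = dX);
}

// One-pass ReLU; the backward pass recovers the mask from the forward
// output (out > 0 iff the preactivation was positive).
// [[Rcpp::export(rng = false)]]
NumericVector relu_fwd_cpp(NumericVector X) {
  NumericVector out(X.size());
  const double* x = X.begin();
  double* y = out.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  out.attr("dim") = X.attr("dim");
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector relu_bwd_cpp(NumericVector dY, NumericVector out) {
  NumericVector dX(dY.size());
  const double* d = dY.begin();
  const double* o = out.begin();
  double* r = dX.begin();
  for (R_xlen_t i = 0; i < dY.size(); ++i) r[i] = o[i] > 0 ? d[i] : 0.0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}
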