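// Multi-column convolutional valence/arousal recognizer.
//
// Each column maps one 32x32 (channels x time) window through four valid
// 3x3 convolutions, one 2x2 max-pool after the second convolution, and four
// fully connected layers. Hidden stages use ReLU (band power is an even
// function of the signal, which rectifying units express directly); the
// output stage uses tanh, so the final (valence, arousal) pair lies in
// (-1, 1). Columns are independent; the model output is the arithmetic mean
// of the k column outputs, trained jointly under a mean-squared-error loss.
//
// Activations between convolution stages are kept in "block" layout: a
// (n * H * W) x C matrix whose row index is s * H * W + h + H * w. im2col
// reads straight from this layout, so no per-layer reshuffling is needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int c1, c2, c3, c4, f1, f2, f3;
  // spatial sizes after each stage (valid 3x3 convs, one 2x2 pool)
  static const int H0 = 32, H1 = 30, H2 = 28, Hp = 14, H3 = 12, H4 = 10;
  int flat() const { return H4 * H4 * c4; }
  int n_par() const {
    return 9 * c1 + c1 + 9 * c1 * c2 + c2 + 9 * c2 * c3 + c3 +
           9 * c3 * c4 + c4 + flat() * f1 + f1 + f1 * f2 + f2 +
           f2 * f3 + f3 + f3 * 2 + 2;
  }
};

Dims make_dims(const Rcpp::IntegerVector& conv, const Rcpp::IntegerVector& fc) {
  if (conv.size() != 4 || fc.size() != 3)
    Rcpp::stop("expected 4 convolution widths and 3 hidden FC widths");
  Dims d;
  d.c1 = conv[0]; d.c2 = conv[1]; d.c3 = conv[2]; d.c4 = conv[3];
  d.f1 = fc[0]; d.f2 = fc[1]; d.f3 = fc[2];
  return d;
}

// View slices of a parameter vector as matrices without copying.
struct Params {
  mat W1, W2, W3, W4, Wf1, Wf2, Wf3, Wf4;
  rowvec b1, b2, b3, b4, bf1, bf2, bf3, bf4;
};

Params unpack(double* th, const Dims& d) {
  Params p;
  double* q = th;
  auto M = [&](int r, int c) { mat m(q, r, c, false, true); q += r * c; return m; };
  auto B = [&](int c) { rowvec v(q, c, false, true); q += c; return v; };
  p.W1 = M(9, d.c1);            p.b1 = B(d.c1);
  p.W2 = M(9 * d.c1, d.c2);     p.b2 = B(d.c2);
  p.W3 = M(9 * d.c2, d.c3);     p.b3 = B(d.c3);
  p.W4 = M(9 * d.c3, d.c4);     p.b4 = B(d.c4);
  p.Wf1 = M(d.flat(), d.f1);    p.bf1 = B(d.f1);
  p.Wf2 = M(d.f1, d.f2);        p.bf2 = B(d.f2);
  p.Wf3 = M(d.f2, d.f3);        p.bf3 = B(d.f3);
  p.Wf4 = M(d.f3, 2);           p.bf4 = B(2);
  return p;
}

// im2col from block layout: A is (n*H*H) x C, output (n*Ho*Ho) x 9C with
// column index kh + 3*kw + 9*c.
mat im2col(const mat& A, int n, int H, int C) {
  const int Ho = H - 2, P = H * H, Po = Ho * Ho;
  mat col(static_cast<uword>(n) * Po, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh) {
        double* dst = col.colptr(kh + 3 * kw + 9 * c);
        for (int s = 0; s < n; ++s)
          for (int wo = 0; wo < Ho; ++wo) {
            const double* a = src + static_cast<size_t>(s) * P +
                              (kh) + H * (wo + kw);
            double* o = dst + static_cast<size_t>(s) * Po + Ho * wo;
            std::memcpy(o, a, sizeof(double) * Ho);
          }
      }
  }
  return col;
}

// Scatter-add transpose of im2col: dcol is (n*Ho*Ho) x 9C -> dA (n*H*H) x C.
mat col2im(const mat& dcol, int n, int H, int C) {
  const int Ho = H - 2, P = H * H, Po = Ho * Ho;
  mat dA(static_cast<uword>(n) * P, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dA.colptr(c);
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh) {
        const double* src = dcol.colptr(kh + 3 * kw + 9 * c);
        for (int s = 0; s < n; ++s)
          for (int wo = 0; wo < Ho; ++wo) {
            double* a = dst + static_cast<size_t>(s) * P + kh + H * (wo + kw);
            const double* o = src + static_cast<size_t>(s) * Po + Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) a[ho] += o[ho];
          }
      }
  }
  return dA;
}

// 2x2 max-pool, block layout in (n*H*H) x C (H even), out (n*(H/2)^2) x C.
void maxpool(const mat& A, int n, int H, int C, mat& out, umat& amax) {
  const int Hp = H / 2, P = H * H, Pp = Hp * Hp;
  out.set_size(static_cast<uword>(n) * Pp, C);
  amax.set_size(static_cast<uword>(n) * Pp, C);
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < n; ++s)
      for (int wp = 0; wp < Hp; ++wp)
        for (int hp = 0; hp < Hp; ++hp) {
          uword best = static_cast<uword>(s) * P + (2 * hp) + H * (2 * wp);
          double bv = A(best, c);
          const int dh[3] = {1, 0, 1}, dw[3] = {0, 1, 1};
          for (int t = 0; t < 3; ++t) {
            uword idx = static_cast<uword>(s) * P + (2 * hp + dh[t]) +
                        H * (2 * wp + dw[t]);
            if (A(idx, c) > bv) { bv = A(idx, c); best = idx; }
          }
          uword r = static_cast<uword>(s) * Pp + hp + Hp * wp;
          out(r, c) = bv;
          amax(r, c) = best;
        }
}

struct Cache {
  mat X0;                       // input in block layout (n*1024) x 1
  mat c1col, c2col, c3col, c4col;
  mat a1, a2, ap, a3, a4;       // conv activations (block layout)
  umat amax;
  mat F, h1, h2, h3, out;       // FC side
};

// Forward one column. X is n x 1024 (row = window, column-major 32x32).
void col_forward(const Params& p, const Dims& d, const mat& X, Cache& cc) {
  const int n = X.n_rows;
  // block layout of the input: row s*1024 + idx, one channel
  mat X0(static_cast<uword>(n) * 1024, 1);
  for (int s = 0; s < n; ++s)
    for (int i = 0; i < 1024; ++i)
      X0(static_cast<uword>(s) * 1024 + i, 0) = X(s, i);
  cc.X0 = X0;
  cc.c1col = im2col(X0, n, 32, 1);
  cc.a1 = cc.c1col * p.W1; cc.a1.each_row() += p.b1; cc.a1 = clamp(cc.a1, 0.0, datum::inf);
  cc.c2col = im2col(cc.a1, n, 30, d.c1);
  cc.a2 = cc.c2col * p.W2; cc.a2.each_row() += p.b2; cc.a2 = clamp(cc.a2, 0.0, datum::inf);
  maxpool(cc.a2, n, 28, d.c2, cc.ap, cc.amax);
  cc.c3col = im2col(cc.ap, n, 14, d.c2);
  cc.a3 = cc.c3col * p.W3; cc.a3.each_row() += p.b3; cc.a3 = clamp(cc.a3, 0.0, datum::inf);
  cc.c4col = im2col(cc.a3, n, 12, d.c3);
  cc.a4 = cc.c4col * p.W4; cc.a4.each_row() += p.b4; cc.a4 = clamp(cc.a4, 0.0, datum::inf);
  // flatten: F(s, p + 100*c) = a4(s*100 + p, c)
  const int P4 = Dims::H4 * Dims::H4;
  cc.F.set_size(n, d.flat());
  for (int c = 0; c < d.c4; ++c)
    for (int pp = 0; pp < P4; ++pp)
      for (int s = 0; s < n; ++s)
        cc.F(s, pp + P4 * c) = cc.a4(static_cast<uword>(s) * P4 + pp, c);
  cc.h1 = cc.F * p.Wf1; cc.h1.each_row() += p.bf1; cc.h1 = clamp(cc.h1, 0.0, datum::inf);
  cc.h2 = cc.h1 * p.Wf2; cc.h2.each_row() += p.bf2; cc.h2 = clamp(cc.h2, 0.0, datum::inf);
  cc.h3 = cc.h2 * p.Wf3; cc.h3.each_row() += p.bf3; cc.h3 = clamp(cc.h3, 0.0, datum::inf);
  cc.out = cc.h3 * p.Wf4; cc.out.each_row() += p.bf4; cc.out = tanh(cc.out);
}

// Backward one column; dOut is n x 2. Gradient written into gth (same
// layout as theta).
void col_backward(const Params& p, const Dims& d, const Cache& cc,
                  const mat& dOut, double* gth) {
  const int n = dOut.n_rows;
  Params g = unpack(gth, d);
  mat dz = dOut % (1 - square(cc.out));
  g.Wf4 = cc.h3.t() * dz;      g.bf4 = sum(dz, 0);
  mat dh3 = dz * p.Wf4.t();
  dz = dh3 % conv_to<mat>::from(cc.h3 > 0);
  g.Wf3 = cc.h2.t() * dz;      g.bf3 = sum(dz, 0);
  mat dh2 = dz * p.Wf3.t();
  dz = dh2 % conv_to<mat>::from(cc.h2 > 0);
  g.Wf2 = cc.h1.t() * dz;      g.bf2 = sum(dz, 0);
  mat dh1 = dz * p.Wf2.t();
  dz = dh1 % conv_to<mat>::from(cc.h1 > 0);
  g.Wf1 = cc.F.t() * dz;       g.bf1 = sum(dz, 0);
  mat dF = dz * p.Wf1.t();
  // unflatten
  const int P4 = Dims::H4 * Dims::H4;
  mat da4(static_cast<uword>(n) * P4, d.c4);
  for (int c = 0; c < d.c4; ++c)
    for (int pp = 0; pp < P4; ++pp)
      for (int s = 0; s < n; ++s)
        da4(static_cast<uword>(s) * P4 + pp, c) = dF(s, pp + P4 * c);
  mat dzc = da4 % conv_to<mat>::from(cc.a4 > 0);
  g.W4 = cc.c4col.t() * dzc;   g.b4 = sum(dzc, 0);
  mat da3 = col2im(dzc * p.W4.t(), n, 12, d.c3);
  dzc = da3 % conv_to<mat>::from(cc.a3 > 0);
  g.W3 = cc.c3col.t() * dzc;   g.b3 = sum(dzc, 0);
  mat dap = col2im(dzc * p.W3.t(), n, 14, d.c2);
  // max-pool backward: route gradient to the argmax positions
  mat da2(static_cast<uword>(n) * 28 * 28, d.c2, fill::zeros);
  for (int c = 0; c < d.c2; ++c)
    for (uword r = 0; r < dap.n_rows; ++r)
      da2(cc.amax(r, c), c) += dap(r, c);
  dzc = da2 % conv_to<mat>::from(cc.a2 > 0);
  g.W2 = cc.c2col.t() * dzc;   g.b2 = sum(dzc, 0);
  mat da1 = col2im(dzc * p.W2.t(), n, 30, d.c1);
  dzc = da1 % conv_to<mat>::from(cc.a1 > 0);
  g.W1 = cc.c1col.t() * dzc;   g.b1 = sum(dzc, 0);
}

} // namespace

//' Parameter vector length of one recognizer column (internal).
//' @noRd
// [[Rcpp::export]]
int cpp_theta_length(Rcpp::IntegerVector conv, Rcpp::IntegerVector fc) {
  return make_dims(conv, fc).n_par();
}

// Fused forward pass of the multi-column model.
// thetas: list of k parameter vectors; Xs: list of k matrices (n x 1024).
// [[Rcpp::export]]
arma::mat cpp_mc_forward(Rcpp::List thetas, Rcpp::IntegerVector conv,
                         Rcpp::IntegerVector fc, Rcpp::List Xs) {
  Dims d = make_dims(conv, fc);
  const int k = thetas.size();
  if (Xs.size() != k) Rcpp::stop("window count does not match column count");
  mat fused;
  for (int j = 0; j < k; ++j) {
    Rcpp::NumericVector th = thetas[j];
    if ((int)th.size() != d.n_par()) Rcpp::stop("bad parameter vector length");
    Params p = unpack(th.begin(), d);
    mat X = Rcpp::as<mat>(Xs[j]);
    Cache cc;
    col_forward(p, d, X, cc);
    if (j == 0) fused = cc.out; else fused += cc.out;
  }
  return fused / k;
}

// Joint MSE loss and parameter gradients of the multi-column model.
// [[Rcpp::export]]
Rcpp::List cpp_mc_loss_grad(Rcpp::List thetas, Rcpp::IntegerVector conv,
                            Rcpp::IntegerVector fc, Rcpp::List Xs,
                            arma::mat Y) {
  Dims d = make_dims(conv, fc);
  const int k = thetas.size();
  if (Xs.size() != k) Rcpp::stop("window count does not match column count");
  const int n = Y.n_rows;
  std::vector<Cache> caches(k);
  std::vector<Params> ps(k);
  std::vector<Rcpp::NumericVector> ths(k);
  mat fused(n, 2, fill::zeros);
  for (int j = 0; j < k; ++j) {
    ths[j] = Rcpp::NumericVector(thetas[j]);
    if ((int)ths[j].size() != d.n_par()) Rcpp::stop("bad parameter vector length");
    ps[j] = unpack(ths[j].begin(), d);
    mat X = Rcpp::as<mat>(Xs[j]);
    if ((int)X.n_rows != n) Rcpp::stop("X/Y row mismatch");
    col_forward(ps[j], d, X, caches[j]);
    fused += caches[j].out;
  }
  fused /= k;
  mat err = fused - Y;
  double loss = accu(square(err)) / (n * 2.0);
  mat dOut = 2.0 * err / (n * 2.0 * k);
  Rcpp::List grads(k);
  for (int j = 0; j < k; ++j) {
    Rcpp::NumericVector g(d.n_par());
    col_backward(ps[j], d, caches[j], dOut, g.begin());
    grads[j] = g;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("fused") = fused,
                            Rcpp::Named("grads") = grads);
}
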