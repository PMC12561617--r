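// Low-level dense tensor kernels for the network core: 2-D convolution
// (stride 1, arbitrary rectangular kernels, asymmetric zero padding,
// grouped/depthwise variants) and 2x2 max pooling, with exact backward
// passes. Feature maps are stored H x W x C x N in R's column-major order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Copy one image (H x W x C) into a zero-padded buffer (Hp x Wp x C).
void pad_image(const double* x, arma::cube& out,
               int H, int W, int C, int pt, int pl) {
  out.zeros();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        out(h + pt, w + pl, c) = x[h + H * (w + W * c)];
}

// im2col over channels [c0, c0+Cg): rows indexed (kh, kw, c) column-major,
// columns indexed (ho, wo) column-major. Matches arma reshape of the
// (Kh, Kw, Cg, Cout) weight array to (Kh*Kw*Cg) x Cout.
void im2col(const arma::cube& xp, arma::mat& cols,
            int c0, int Cg, int Kh, int Kw, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      for (int c = 0; c < Cg; ++c)
        for (int kw = 0; kw < Kw; ++kw)
          for (int kh = 0; kh < Kh; ++kh)
            *dst++ = xp(ho + kh, wo + kw, c0 + c);
    }
}

} // namespace

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias, IntegerVector pad,
                                 int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Kh = wd[0], Kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  if (C != Cg * groups) stop("channel count inconsistent with groups");
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  const int CoutG = Cout / groups;
  const int Hp = H + pt + pb, Wp = W + pl + pr;
  const int Ho = Hp - Kh + 1, Wo = Wp - Kw + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel support");
  const bool has_bias = bias.size() == Cout;

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::cube xp(Hp, Wp, C);
  arma::mat cols(Kh * Kw * Cg, Ho * Wo);
  // weight matrix per group: (Kh*Kw*Cg) x CoutG
  const arma::mat wmat(const_cast<double*>(w.begin()),
                       Kh * Kw * Cg, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    pad_image(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
              xp, H, W, C, pt, pl);
    for (int g = 0; g < groups; ++g) {
      im2col(xp, cols, g * Cg, Cg, Kh, Kw, Ho, Wo);
      arma::mat out = wmat.cols(g * CoutG, (g + 1) * CoutG - 1).t() * cols;
      for (int co = 0; co < CoutG; ++co) {
        const int oc = g * CoutG + co;
        double* dst = y.begin() +
          static_cast<R_xlen_t>(Ho) * Wo * (oc + static_cast<R_xlen_t>(Cout) * n);
        const double b = has_bias ? bias[oc] : 0.0;
        for (int i = 0; i < Ho * Wo; ++i) dst[i] = out(co, i) + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         IntegerVector pad, int groups, bool has_bias,
                         bool need_dx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Kh = wd[0], Kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  const int CoutG = Cout / groups;
  const int Hp = H + pt + pb, Wp = W + pl + pr;
  const int Ho = Hp - Kh + 1, Wo = Wp - Kw + 1;

  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(static_cast<R_xlen_t>(Kh) * Kw * Cg * Cout);
  dw.attr("dim") = IntegerVector::create(Kh, Kw, Cg, Cout);
  NumericVector db(Cout);

  arma::cube xp(Hp, Wp, C), dxp(Hp, Wp, C);
  arma::mat cols(Kh * Kw * Cg, Ho * Wo);
  const arma::mat wmat(const_cast<double*>(w.begin()),
                       Kh * Kw * Cg, Cout, false, true);
  arma::mat dwmat(dw.begin(), Kh * Kw * Cg, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    pad_image(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
              xp, H, W, C, pt, pl);
    dxp.zeros();
    for (int g = 0; g < groups; ++g) {
      im2col(xp, cols, g * Cg, Cg, Kh, Kw, Ho, Wo);
      // dY for this group as (CoutG x Ho*Wo)
      arma::mat dyg(CoutG, Ho * Wo);
      for (int co = 0; co < CoutG; ++co) {
        const int oc = g * CoutG + co;
        const double* src = dy.begin() +
          static_cast<R_xlen_t>(Ho) * Wo * (oc + static_cast<R_xlen_t>(Cout) * n);
        for (int i = 0; i < Ho * Wo; ++i) dyg(co, i) = src[i];
        if (has_bias) {
          double s = 0.0;
          for (int i = 0; i < Ho * Wo; ++i) s += src[i];
          db[oc] += s;
        }
      }
      dwmat.cols(g * CoutG, (g + 1) * CoutG - 1) += cols * dyg.t();
      if (!need_dx) continue;
      // col2im accumulation into padded gradient
      arma::mat dcols = wmat.cols(g * CoutG, (g + 1) * CoutG - 1) * dyg;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double* src = dcols.colptr(ho + Ho * wo);
          for (int c = 0; c < Cg; ++c)
            for (int kw = 0; kw < Kw; ++kw)
              for (int kh = 0; kh < Kh; ++kh)
                dxp(ho + kh, wo + kw, g * Cg + c) += *src++;
        }
    }
    if (!need_dx) continue;
    double* dst = dx.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w2 = 0; w2 < W; ++w2)
        for (int h = 0; h < H; ++h)
          dst[h + H * (w2 + W * c)] = dxp(h + pt, w2 + pl, c);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_forward_cpp")]]
List maxpool2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small for 2x2 pooling");

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // 1-based linear index into x of each max
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);


  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = static_cast<R_xlen_t>(H) * W *
        (c + static_cast<R_xlen_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              const R_xlen_t i = base + (2 * ho + dh) +
                static_cast<R_xlen_t>(H) * (2 * wo + dw2);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          // column-major output order: ho fastest, then wo, c, n
          const R_xlen_t oi = ho + static_cast<R_xlen_t>(Ho) *
            (wo + static_cast<R_xlen_t>(Wo) * (c + static_cast<R_xlen_t>(C) * n));
          y[oi] = best;
          idx[oi] = static_cast<int>(bi + 1);

        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward_cpp")]]
NumericVector maxpool2_backward_cpp(NumericVector dy, IntegerVector idx,
                                    IntegerVector in_dim) {
  R_xlen_t len = 1;
  for (int i = 0; i < in_dim.size(); ++i) len *= in_dim[i];
  NumericVector dx(len);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
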