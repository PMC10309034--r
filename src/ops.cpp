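// Convolution kernels for the two-stream lesion network.
//
// Layout conventions (column-major, matching R arrays):
//   feature map  : cube (H, W, C)
//   conv weight  : array (kh, kw, Cin/groups, Cout)
//   tconv weight : array (kh, kw, Cout, Cin)
//   offsets      : cube (Ho, Wo, 2N), N = kh*kw, tap k = ki + kh*kj,
//                  channel 2k = row offset, 2k+1 = col offset
// Coordinates are 0-based with pixel centers at integers; reads outside the
// array contribute zero (matching the zero-padding convention of conv).

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// im2col over an explicit output grid: A(k, p) with
// k = ki + kh*(kj + kw*ci_local), p = r + Hgrid*c,
// reading channels [c0, c0+nc) of x at (r*stride - pad + ki, c*stride - pad + kj).
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Hgrid, int Wgrid, int c0, int nc) {
  const int H = x.n_rows, W = x.n_cols;
  mat A(kh * kw * nc, (size_t)Hgrid * Wgrid, arma::fill::zeros);
  for (int ci = 0; ci < nc; ++ci) {
    const mat& Xc = x.slice(c0 + ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * ci);
        for (int c = 0; c < Wgrid; ++c) {
          const int cc = c * stride - pad + kj;
          if (cc < 0 || cc >= W) continue;
          for (int r = 0; r < Hgrid; ++r) {
            const int rr = r * stride - pad + ki;
            if (rr < 0 || rr >= H) continue;
            A(krow, r + (size_t)Hgrid * c) = Xc(rr, cc);
          }
        }
      }
    }
  }
  return A;
}

// Scatter-add inverse of im2col (same indexing conventions).
static void col2im(const mat& A, cube& out, int kh, int kw, int stride, int pad,
                   int Hgrid, int Wgrid, int c0, int nc) {
  const int H = out.n_rows, W = out.n_cols;
  for (int ci = 0; ci < nc; ++ci) {
    mat& Xc = out.slice(c0 + ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * ci);
        for (int c = 0; c < Wgrid; ++c) {
          const int cc = c * stride - pad + kj;
          if (cc < 0 || cc >= W) continue;
          for (int r = 0; r < Hgrid; ++r) {
            const int rr = r * stride - pad + ki;
            if (rr < 0 || rr >= H) continue;
            Xc(rr, cc) += A(krow, r + (size_t)Hgrid * c);
          }
        }
      }
    }
  }
}

static void out_geom(int H, int W, int kh, int kw, int stride, int pad,
                     int& Ho, int& Wo) {
  Ho = (H + 2 * pad - kh) / stride + 1;
  Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::cube& wraw,
                      Rcpp::IntegerVector wdim, const arma::vec& bias,
                      int stride, int pad, int groups) {
  const int kh = wdim[0], kw = wdim[1], cing = wdim[2], cout = wdim[3];
  const int cin = x.n_slices;
  if (cin % groups != 0 || cout % groups != 0 || cin / groups != cing)
    stop("groups must divide the input and output channel counts");
  int Ho, Wo;
  out_geom(x.n_rows, x.n_cols, kh, kw, stride, pad, Ho, Wo);
  const size_t P = (size_t)Ho * Wo;
  const int K = kh * kw * cing, coutg = cout / groups;
  const mat Wfull(const_cast<double*>(wraw.memptr()), K, cout, false, true);
  cube y(Ho, Wo, cout);
  for (int g = 0; g < groups; ++g) {
    mat A = im2col(x, kh, kw, stride, pad, Ho, Wo, g * cing, cing);
    mat Y = A.t() * Wfull.cols(g * coutg, (g + 1) * coutg - 1); // P x coutg
    for (int co = 0; co < coutg; ++co) {
      mat sl(Y.colptr(co), Ho, Wo, false, true);
      y.slice(g * coutg + co) = sl;
      if (bias.n_elem) y.slice(g * coutg + co) += bias(g * coutg + co);
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::cube& wraw,
                      Rcpp::IntegerVector wdim, const arma::cube& gy,
                      int stride, int pad, int groups, bool has_bias) {
  const int kh = wdim[0], kw = wdim[1], cing = wdim[2], cout = wdim[3];
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const size_t P = (size_t)Ho * Wo;
  const int K = kh * kw * cing, coutg = cout / groups;
  const mat Wfull(const_cast<double*>(wraw.memptr()), K, cout, false, true);
  cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  cube gw(kh, kw, (size_t)cing * cout, arma::fill::zeros); // reshaped on return
  mat GWfull(gw.memptr(), K, cout, false, true);
  vec gb(has_bias ? cout : 0, arma::fill::zeros);
  for (int g = 0; g < groups; ++g) {
    mat Gy(P, coutg);
    for (int co = 0; co < coutg; ++co) {
      const mat& sl = gy.slice(g * coutg + co);
      std::copy(sl.memptr(), sl.memptr() + P, Gy.colptr(co));
      if (has_bias) gb(g * coutg + co) = arma::accu(sl);
    }
    mat A = im2col(x, kh, kw, stride, pad, Ho, Wo, g * cing, cing);
    GWfull.cols(g * coutg, (g + 1) * coutg - 1) = A * Gy;
    mat Gcols = Wfull.cols(g * coutg, (g + 1) * coutg - 1) * Gy.t(); // K x P
    col2im(Gcols, gx, kh, kw, stride, pad, Ho, Wo, g * cing, cing);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution: y(pi*stride - pad + k) += x(pi) * w(k, co, ci).
// [[Rcpp::export]]
arma::cube tconv2d_fwd(const arma::cube& x, const arma::cube& wraw,
                       Rcpp::IntegerVector wdim, const arma::vec& bias,
                       int stride, int pad) {
  const int kh = wdim[0], kw = wdim[1], cout = wdim[2], cin = wdim[3];
  const int H = x.n_rows, W = x.n_cols;
  if ((int)x.n_slices != cin) stop("input channel count mismatch");
  const int Hout = (H - 1) * stride - 2 * pad + kh;
  const int Wout = (W - 1) * stride - 2 * pad + kw;
  const int K = kh * kw * cout;
  const size_t P = (size_t)H * W;
  const mat Wmat(const_cast<double*>(wraw.memptr()), K, cin, false, true);
  const mat X(const_cast<double*>(x.memptr()), P, cin, false, true);
  mat cols = Wmat * X.t(); // K x P
  cube y(Hout, Wout, cout, arma::fill::zeros);
  col2im(cols, y, kh, kw, stride, pad, H, W, 0, cout);
  if (bias.n_elem)
    for (int co = 0; co < cout; ++co) y.slice(co) += bias(co);
  return y;
}

// [[Rcpp::export]]
Rcpp::List tconv2d_bwd(const arma::cube& x, const arma::cube& wraw,
                       Rcpp::IntegerVector wdim, const arma::cube& gy,
                       int stride, int pad, bool has_bias) {
  const int kh = wdim[0], kw = wdim[1], cout = wdim[2], cin = wdim[3];
  const int H = x.n_rows, W = x.n_cols;
  const int K = kh * kw * cout;
  const size_t P = (size_t)H * W;
  const mat Wmat(const_cast<double*>(wraw.memptr()), K, cin, false, true);
  const mat X(const_cast<double*>(x.memptr()), P, cin, false, true);
  mat A = im2col(gy, kh, kw, stride, pad, H, W, 0, cout); // K x P
  mat GX = A.t() * Wmat;                                  // P x cin
  cube gx(H, W, cin);
  std::copy(GX.memptr(), GX.memptr() + GX.n_elem, gx.memptr());
  cube gw(kh, kw, (size_t)cout * cin);
  mat GW(gw.memptr(), K, cin, false, true);
  GW = A * X;
  vec gb(has_bias ? cout : 0, arma::fill::zeros);
  if (has_bias)
    for (int co = 0; co < cout; ++co) gb(co) = arma::accu(gy.slice(co));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline double bsample(const mat& X, double r, double c) {
  const int H = X.n_rows, W = X.n_cols;
  if (r <= -1.0 || c <= -1.0 || r >= (double)H || c >= (double)W) return 0.0;
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const double ar = r - r0, ac = c - c0;
  double v = 0.0;
  const bool r0in = r0 >= 0 && r0 < H, r1in = r0 + 1 >= 0 && r0 + 1 < H;
  const bool c0in = c0 >= 0 && c0 < W, c1in = c0 + 1 >= 0 && c0 + 1 < W;
  if (r0in && c0in) v += (1 - ar) * (1 - ac) * X(r0, c0);
  if (r0in && c1in) v += (1 - ar) * ac * X(r0, c0 + 1);
  if (r1in && c0in) v += ar * (1 - ac) * X(r0 + 1, c0);
  if (r1in && c1in) v += ar * ac * X(r0 + 1, c0 + 1);
  return v;
}

// [[Rcpp::export]]
double bilinear_sample_cpp(const arma::mat& x, double r, double c) {
  return bsample(x, r, c);
}

// Deformable convolution (groups = 1): per output position p and tap k the
// read location is p*stride - pad + tap + offset(p, k); fractional reads via
// bilinear interpolation, zero outside bounds.
// [[Rcpp::export]]
arma::cube dconv2d_fwd(const arma::cube& x, const arma::cube& wraw,
                       Rcpp::IntegerVector wdim, const arma::vec& bias,
                       const arma::cube& off, int stride, int pad) {
  const int kh = wdim[0], kw = wdim[1], cin = wdim[2], cout = wdim[3];
  if ((int)x.n_slices != cin) stop("input channel count mismatch");
  int Ho, Wo;
  out_geom(x.n_rows, x.n_cols, kh, kw, stride, pad, Ho, Wo);
  const int N = kh * kw;
  if ((int)off.n_rows != Ho || (int)off.n_cols != Wo || (int)off.n_slices != 2 * N)
    stop("offset field must be Ho x Wo x 2N");
  const int K = N * cin;
  const size_t P = (size_t)Ho * Wo;
  mat A(K, P, arma::fill::zeros);
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      const int k = ki + kh * kj;
      for (int c = 0; c < Wo; ++c) {
        for (int r = 0; r < Ho; ++r) {
          const size_t p = r + (size_t)Ho * c;
          const double pr = r * stride - pad + ki + off(r, c, 2 * k);
          const double pc = c * stride - pad + kj + off(r, c, 2 * k + 1);
          for (int ci = 0; ci < cin; ++ci)
            A(k + N * ci, p) = bsample(x.slice(ci), pr, pc);
        }
      }
    }
  }
  // weight (ki,kj,ci,co): row index ki + kh*(kj + kw*ci) == k + N*ci; matches A.
  const mat Wmat(const_cast<double*>(wraw.memptr()), K, cout, false, true);
  mat Y = A.t() * Wmat;
  cube y(Ho, Wo, cout);
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, y.memptr());
  if (bias.n_elem)
    for (int co = 0; co < cout; ++co) y.slice(co) += bias(co);
  return y;
}

// [[Rcpp::export]]
Rcpp::List dconv2d_bwd(const arma::cube& x, const arma::cube& wraw,
                       Rcpp::IntegerVector wdim, const arma::cube& off,
                       const arma::cube& gy, int stride, int pad, bool has_bias) {
  const int kh = wdim[0], kw = wdim[1], cin = wdim[2], cout = wdim[3];
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const int N = kh * kw, K = N * cin;
  const size_t P = (size_t)Ho * Wo;
  const mat Wmat(const_cast<double*>(wraw.memptr()), K, cout, false, true);
  const mat Gy(const_cast<double*>(gy.memptr()), P, cout, false, true);

  // Rebuild the sampled column matrix (forward caches nothing large).
  mat A(K, P, arma::fill::zeros);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      const int k = ki + kh * kj;
      for (int c = 0; c < Wo; ++c)
        for (int r = 0; r < Ho; ++r) {
          const size_t p = r + (size_t)Ho * c;
          const double pr = r * stride - pad + ki + off(r, c, 2 * k);
          const double pc = c * stride - pad + kj + off(r, c, 2 * k + 1);
          for (int ci = 0; ci < cin; ++ci)
            A(k + N * ci, p) = bsample(x.slice(ci), pr, pc);
        }
    }

  cube gw(kh, kw, (size_t)cin * cout);
  mat GW(gw.memptr(), K, cout, false, true);
  GW = A * Gy;
  vec gb(has_bias ? cout : 0, arma::fill::zeros);
  if (has_bias)
    for (int co = 0; co < cout; ++co) gb(co) = arma::accu(gy.slice(co));

  mat Gcols = Wmat * Gy.t(); // K x P
  cube gx(H, W, cin, arma::fill::zeros);
  cube goff(Ho, Wo, 2 * N, arma::fill::zeros);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      const int k = ki + kh * kj;
      for (int c = 0; c < Wo; ++c)
        for (int r = 0; r < Ho; ++r) {
          const size_t p = r + (size_t)Ho * c;
          const double pr = r * stride - pad + ki + off(r, c, 2 * k);
          const double pc = c * stride - pad + kj + off(r, c, 2 * k + 1);
          if (pr <= -1.0 || pc <= -1.0 || pr >= (double)H || pc >= (double)W)
            continue;
          const int r0 = (int)std::floor(pr), c0 = (int)std::floor(pc);
          const double ar = pr - r0, ac = pc - c0;
          const bool r0in = r0 >= 0 && r0 < H, r1in = r0 + 1 >= 0 && r0 + 1 < H;
          const bool c0in = c0 >= 0 && c0 < W, c1in = c0 + 1 >= 0 && c0 + 1 < W;
          double dr = 0.0, dc = 0.0;
          for (int ci = 0; ci < cin; ++ci) {
            const double g = Gcols(k + N * ci, p);
            if (g == 0.0) continue;
            mat& GXc = gx.slice(ci);
            const mat& Xc = x.slice(ci);
            double x00 = 0, x01 = 0, x10 = 0, x11 = 0;
            if (r0in && c0in) { GXc(r0, c0) += g * (1 - ar) * (1 - ac); x00 = Xc(r0, c0); }
            if (r0in && c1in) { GXc(r0, c0 + 1) += g * (1 - ar) * ac;   x01 = Xc(r0, c0 + 1); }
            if (r1in && c0in) { GXc(r0 + 1, c0) += g * ar * (1 - ac);   x10 = Xc(r0 + 1, c0); }
            if (r1in && c1in) { GXc(r0 + 1, c0 + 1) += g * ar * ac;     x11 = Xc(r0 + 1, c0 + 1); }
            dr += g * (-(1 - ac) * x00 - ac * x01 + (1 - ac) * x10 + ac * x11);
            dc += g * (-(1 - ar) * x00 + (1 - ar) * x01 - ar * x10 + ar * x11);
          }
          goff(r, c, 2 * k) += dr;
          goff(r, c, 2 * k + 1) += dc;
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["goff"] = goff);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  int Ho, Wo;
  out_geom(x.n_rows, x.n_cols, k, k, stride, pad, Ho, Wo);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C); // linear index into each slice, stored as double
  for (int ci = 0; ci < C; ++ci) {
    const mat& Xc = x.slice(ci);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bi = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int cc = c * stride - pad + kj;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int rr = r * stride - pad + ki;
            if (rr < 0 || rr >= H) continue;
            if (Xc(rr, cc) > best) { best = Xc(rr, cc); bi = rr + (size_t)H * cc; }
          }
        }
        y(r, c, ci) = best;
        idx(r, c, ci) = (double)bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::cube& gy, const arma::cube& idx,
                       int H, int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    mat& GXc = gx.slice(ci);
    const mat& Gc = gy.slice(ci);
    const mat& Ic = idx.slice(ci);
    for (size_t j = 0; j < Gc.n_elem; ++j)
      GXc((size_t)Ic(j)) += Gc(j);
  }
  return gx;
}

// Affine bilinear warp: output (r, c) samples input at
// (a11*r + a12*c + tr, a21*r + a22*c + tc); out-of-bounds reads return `fill`.
// Shared resampling path for rotation / crop-resize augmentation.
// [[Rcpp::export]]
arma::cube warp_affine(const arma::cube& x, int Hout, int Wout,
                       double a11, double a12, double tr,
                       double a21, double a22, double tc, double fill) {
  const int C = x.n_slices;
  cube y(Hout, Wout, C);
  for (int ci = 0; ci < C; ++ci) {
    const mat& Xc = x.slice(ci);
    const int H = Xc.n_rows, W = Xc.n_cols;
    for (int c = 0; c < Wout; ++c)
      for (int r = 0; r < Hout; ++r) {
        const double pr = a11 * r + a12 * c + tr;
        const double pc = a21 * r + a22 * c + tc;
        if (pr < 0 || pc < 0 || pr > H - 1 || pc > W - 1)
          y(r, c, ci) = fill;
        else
          y(r, c, ci) = bsample(Xc, pr, pc);
      }
  }
  return y;
}
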