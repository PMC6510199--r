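#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2-D cross-correlation layers (im2col + GEMM)
//
// Arrays follow R column-major conventions throughout:
//   input  x : H x W x Cin cube
//   weights w: flat vector of an R array dim (kh, kw, Cin, Cout), so that
//              viewed as a matrix it is (kh*kw*Cin) x Cout column-major
//   output   : Ho x Wo x Cout cube, Ho = H + 2*ph - kh + 1, Wo likewise.
// The im2col matrix is built transposed (pixels x taps) so every write is a
// contiguous column; wide inputs are processed in output-column chunks to
// bound the buffer at ~64 MB.
// ---------------------------------------------------------------------------

static arma::cube pad_zeros(const arma::cube& x, int ph, int pw) {
  arma::cube xp(x.n_rows + 2 * ph, x.n_cols + 2 * pw, x.n_slices,
                arma::fill::zeros);
  xp.subcube(ph, pw, 0, ph + x.n_rows - 1, pw + x.n_cols - 1,
             x.n_slices - 1) = x;
  return xp;
}

// fill rows [row0, row0 + Ho*(wo1-wo0)) of Kt (pixels x taps) for output
// columns [wo0, wo1); taps ordered (ki fastest, then kj, then c) to match
// the R weight array layout (kh, kw, Cin, Cout)
static void im2col_t(const arma::cube& xp, int kh, int kw, int Ho,
                     int wo0, int wo1, arma::mat& Kt, arma::uword row0) {
  const int cin = xp.n_slices;
  const int Hp = xp.n_rows;
  for (int c = 0; c < cin; ++c) {
    const double* xs = xp.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword r =
            (arma::uword)c * kh * kw + (arma::uword)kj * kh + ki;
        double* dst = Kt.colptr(r) + row0;
        for (int wo = wo0; wo < wo1; ++wo) {
          const double* src = xs + (size_t)(wo + kj) * Hp + ki;
          std::copy(src, src + Ho, dst);
          dst += Ho;
        }
      }
    }
  }
}

// scatter-add dKt rows [row0, ...) back onto a padded gradient cube
static void col2im_add(arma::cube& dxp, const arma::mat& dKt, int kh, int kw,
                       int Ho, int Wo, arma::uword row0) {
  const int cin = dxp.n_slices;
  const int Hp = dxp.n_rows;
  for (int c = 0; c < cin; ++c) {
    double* xs = dxp.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword r =
            (arma::uword)c * kh * kw + (arma::uword)kj * kh + ki;
        const double* src = dKt.colptr(r) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          double* dst = xs + (size_t)(wo + kj) * Hp + ki;
          for (int i = 0; i < Ho; ++i) dst[i] += src[i];
          src += Ho;
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::vec& w,
                              const arma::vec& bias, int kh, int kw,
                              int ph, int pw) {
  const int cin = x.n_slices, cout = bias.n_elem;
  const int Ho = (int)x.n_rows + 2 * ph - kh + 1;
  const int Wo = (int)x.n_cols + 2 * pw - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel exceeds padded input size");
  if ((int)w.n_elem != kh * kw * cin * cout) stop("weight size mismatch");
  const arma::uword taps = (arma::uword)kh * kw * cin;
  arma::mat Wm(const_cast<double*>(w.memptr()), taps, cout, false, true);
  arma::cube xp = pad_zeros(x, ph, pw);
  arma::cube out(Ho, Wo, cout);
  int cols_per = std::max(1, (int)(8000000 / (taps * (arma::uword)Ho)));
  for (int wo0 = 0; wo0 < Wo; wo0 += cols_per) {
    int wo1 = std::min(Wo, wo0 + cols_per);
    arma::mat Kt((arma::uword)Ho * (wo1 - wo0), taps);
    im2col_t(xp, kh, kw, Ho, wo0, wo1, Kt, 0);
    arma::mat O = Kt * Wm;  // npix x cout
    for (int co = 0; co < cout; ++co) {
      out.slice(co).cols(wo0, wo1 - 1) =
          arma::reshape(O.col(co) + bias[co], Ho, wo1 - wo0);
    }
  }
  return out;
}

// gradients of sum(dout * conv(x)) w.r.t. weights, bias and input
// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::vec& w,
                         const arma::cube& dout, int kh, int kw,
                         int ph, int pw) {
  const int cin = x.n_slices, cout = dout.n_slices;
  const int Ho = dout.n_rows, Wo = dout.n_cols;
  if ((int)x.n_rows + 2 * ph - kh + 1 != Ho ||
      (int)x.n_cols + 2 * pw - kw + 1 != Wo)
    stop("gradient shape inconsistent with input/kernel");
  const arma::uword taps = (arma::uword)kh * kw * cin;
  arma::mat Wm(const_cast<double*>(w.memptr()), taps, cout, false, true);
  arma::cube xp = pad_zeros(x, ph, pw);
  arma::mat Kt((arma::uword)Ho * Wo, taps);
  im2col_t(xp, kh, kw, Ho, 0, Wo, Kt, 0);
  arma::mat dOut((arma::uword)Ho * Wo, cout);
  for (int co = 0; co < cout; ++co)
    dOut.col(co) = arma::vectorise(dout.slice(co));
  arma::mat dW = Kt.t() * dOut;           // taps x cout
  arma::vec db = arma::sum(dOut, 0).t();  // cout
  // input gradient: scatter-add columns of dKt back onto the padded grid
  arma::mat dKt = dOut * Wm.t();  // npix x taps
  arma::cube dxp(xp.n_rows, xp.n_cols, cin, arma::fill::zeros);
  col2im_add(dxp, dKt, kh, kw, Ho, Wo, 0);
  arma::cube dx = dxp.subcube(ph, pw, 0, ph + x.n_rows - 1,
                              pw + x.n_cols - 1, cin - 1);
  return List::create(Named("dw") = arma::vec(dW.memptr(), dW.n_elem),
                      Named("db") = db, Named("dx") = dx);
}

// Batched variants: x is an R array (H, W, Cin, B); the minibatch shares one
// GEMM per layer. Output (Ho, Wo, Cout, B); weight gradients are summed over
// the batch.

static arma::cube slice4(const NumericVector& x, int H, int W, int C, int b) {
  return arma::cube(const_cast<double*>(&x[0]) +
                        (size_t)b * H * W * C,
                    H, W, C, false, true);
}

// Height-only im2col: Kh is (kh*cin) x (Ho*Wp), column = pixel (ho, wp)
// over the *padded* width. The width part of the convolution then becomes
// kw GEMMs on zero-copy contiguous column blocks Kh[:, kj*Ho .. ), which
// keeps the workspace ~kw times smaller than a full im2col.
static void im2col_h(const arma::cube& xp, int kh, int Ho, arma::mat& Kh) {
  const int cin = xp.n_slices, Wp = xp.n_cols;
  const arma::uword th = Kh.n_rows;  // kh*cin
  for (int c = 0; c < cin; ++c) {
    const double* xs = xp.slice_memptr(c);
    for (int ki = 0; ki < kh; ++ki) {
      double* base = Kh.memptr() + (arma::uword)(c * kh + ki);
      for (int wp = 0; wp < Wp; ++wp) {
        const double* src = xs + (size_t)wp * xp.n_rows + ki;
        double* dst = base + (arma::uword)wp * Ho * th;
        for (int ho = 0; ho < Ho; ++ho) dst[(arma::uword)ho * th] = src[ho];
      }
    }
  }
}

static void col2im_h_add(arma::cube& dxp, const arma::mat& dKh, int kh,
                         int Ho) {
  const int cin = dxp.n_slices, Wp = dxp.n_cols;
  const arma::uword th = dKh.n_rows;
  for (int c = 0; c < cin; ++c) {
    double* xs = dxp.slice_memptr(c);
    for (int ki = 0; ki < kh; ++ki) {
      const double* base = dKh.memptr() + (arma::uword)(c * kh + ki);
      for (int wp = 0; wp < Wp; ++wp) {
        double* dst = xs + (size_t)wp * dxp.n_rows + ki;
        const double* src = base + (arma::uword)wp * Ho * th;
        for (int ho = 0; ho < Ho; ++ho) dst[ho] += src[(arma::uword)ho * th];
      }
    }
  }
}

// weights regrouped per kernel column: Wk[kj] is (cout x kh*cin) with
// column index ki + kh*c, from the R layout (kh, kw, cin, cout)
static std::vector<arma::mat> weights_by_kj(const arma::vec& w, int kh,
                                            int kw, int cin, int cout) {
  std::vector<arma::mat> Wk(kw);
  for (int kj = 0; kj < kw; ++kj) Wk[kj].set_size(cout, (arma::uword)kh * cin);
  for (int co = 0; co < cout; ++co)
    for (int c = 0; c < cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wk[kj](co, (arma::uword)c * kh + ki) =
              w[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)cin * co))];
  return Wk;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward_batch(const NumericVector& x,
                                       const arma::vec& w,
                                       const arma::vec& bias, int kh, int kw,
                                       int ph, int pw) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4-D array (H, W, Cin, B)");
  const int H = d[0], W = d[1], cin = d[2], B = d[3];
  const int cout = bias.n_elem;
  const int Ho = H + 2 * ph - kh + 1, Wo = W + 2 * pw - kw + 1;
  const int Wp = W + 2 * pw;
  if (Ho < 1 || Wo < 1) stop("kernel exceeds padded input size");
  if ((int)w.n_elem != kh * kw * cin * cout) stop("weight size mismatch");
  const arma::uword th = (arma::uword)kh * cin;
  const arma::uword npix = (arma::uword)Ho * Wo;
  std::vector<arma::mat> Wk = weights_by_kj(w, kh, kw, cin, cout);
  NumericVector out((R_xlen_t)npix * B * cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, B);
  arma::mat Kh(th, (arma::uword)Ho * Wp);
  arma::mat O(cout, npix);
  for (int b = 0; b < B; ++b) {
    arma::cube xp = pad_zeros(slice4(x, H, W, cin, b), ph, pw);
    im2col_h(xp, kh, Ho, Kh);
    O.zeros();
    for (int kj = 0; kj < kw; ++kj) {
      const arma::mat block(const_cast<double*>(Kh.colptr(kj * Ho)), th,
                            npix, false, true);
      O += Wk[kj] * block;
    }
    double* po = &out[0] + (size_t)b * cout * npix;
    for (int co = 0; co < cout; ++co) {
      double* dst = po + (size_t)co * npix;
      const double* src = O.memptr() + co;
      for (arma::uword i = 0; i < npix; ++i)
        dst[i] = src[(arma::uword)i * cout] + bias[co];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward_batch(const NumericVector& x, const arma::vec& w,
                               const NumericVector& dout, int kh, int kw,
                               int ph, int pw) {
  IntegerVector d = x.attr("dim"), dd = dout.attr("dim");
  if (d.size() != 4 || dd.size() != 4) stop("4-D arrays expected");
  const int H = d[0], W = d[1], cin = d[2], B = d[3];
  const int Ho = dd[0], Wo = dd[1], cout = dd[2];
  const int Wp = W + 2 * pw;
  if (dd[3] != B || H + 2 * ph - kh + 1 != Ho || W + 2 * pw - kw + 1 != Wo)
    stop("gradient shape inconsistent with input/kernel");
  const arma::uword th = (arma::uword)kh * cin;
  const arma::uword npix = (arma::uword)Ho * Wo;
  std::vector<arma::mat> dWk(kw);
  for (int kj = 0; kj < kw; ++kj)
    dWk[kj].zeros(th, cout);
  std::vector<arma::mat> Wk = weights_by_kj(w, kh, kw, cin, cout);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * cin * B);
  dx.attr("dim") = IntegerVector::create(H, W, cin, B);
  arma::mat Kh(th, (arma::uword)Ho * Wp);
  arma::mat dKh(th, (arma::uword)Ho * Wp);
  arma::mat dOt(npix, cout);
  for (int b = 0; b < B; ++b) {
    arma::cube xp = pad_zeros(slice4(x, H, W, cin, b), ph, pw);
    im2col_h(xp, kh, Ho, Kh);
    const double* pd = &dout[0] + (size_t)b * cout * npix;
    for (int co = 0; co < cout; ++co) {
      std::copy(pd + (size_t)co * npix, pd + (size_t)(co + 1) * npix,
                dOt.colptr(co));
      db[co] += arma::accu(dOt.col(co));
    }
    dKh.zeros();
    arma::mat dO = dOt.t();  // cout x npix, shared across kernel columns
    for (int kj = 0; kj < kw; ++kj) {
      const arma::mat block(const_cast<double*>(Kh.colptr(kj * Ho)), th,
                            npix, false, true);
      dWk[kj] += block * dOt;  // (th x npix)(npix x cout)
      arma::mat dblock(dKh.colptr(kj * Ho), th, npix, false, true);
      dblock += Wk[kj].t() * dO;
    }
    arma::cube dxp(H + 2 * ph, Wp, cin, arma::fill::zeros);
    col2im_h_add(dxp, dKh, kh, Ho);
    arma::cube dxb = dxp.subcube(ph, pw, 0, ph + H - 1, pw + W - 1, cin - 1);
    std::copy(dxb.memptr(), dxb.memptr() + dxb.n_elem,
              &dx[0] + (size_t)b * H * W * cin);
  }
  // reassemble dW in the R weight layout (kh, kw, cin, cout)
  arma::vec dw((arma::uword)kh * kw * cin * cout);
  for (int co = 0; co < cout; ++co)
    for (int c = 0; c < cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dw[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)cin * co))] =
              dWk[kj]((arma::uword)c * kh + ki, co);
  return List::create(Named("dw") = dw, Named("db") = db,
                      Named("dx") = dx);
}

// ---------------------------------------------------------------------------
// Analytic parallel-beam projector over quadric primitives.
//
// A primitive is one row of an 11-column matrix:
//   [kind, cx, cy, cz, a, b, c, density, clip_axis, clip_sign, clip_bound]
// kind 1 = axis-aligned ellipsoid (sphere: a=b=c), kind 2 = finite cylinder
// with axis along z (radius a, half-height c). clip_axis 0 = none, 1/2/3 =
// keep the half-space clip_sign * (coord - clip_bound) >= 0.
// ---------------------------------------------------------------------------

static double chord_length(const double* P, const double* o, const double* d) {
  const int kind = (int)P[0];
  const double ux = o[0] - P[1], uy = o[1] - P[2], uz = o[2] - P[3];
  const double a = P[4], b = P[5], c = P[6];
  double t1, t2;
  if (kind == 1) {
    const double A = d[0] * d[0] / (a * a) + d[1] * d[1] / (b * b) +
                     d[2] * d[2] / (c * c);
    const double B = 2.0 * (ux * d[0] / (a * a) + uy * d[1] / (b * b) +
                            uz * d[2] / (c * c));
    const double C = ux * ux / (a * a) + uy * uy / (b * b) +
                     uz * uz / (c * c) - 1.0;
    const double disc = B * B - 4.0 * A * C;
    if (A <= 0.0 || disc <= 0.0) return 0.0;
    const double sq = std::sqrt(disc);
    t1 = (-B - sq) / (2.0 * A);
    t2 = (-B + sq) / (2.0 * A);
  } else {
    const double A = d[0] * d[0] + d[1] * d[1];
    if (A < 1e-30) {  // ray parallel to the cylinder axis
      if (ux * ux + uy * uy > a * a || std::abs(d[2]) < 1e-30) return 0.0;
      t1 = (-c - uz) / d[2];
      t2 = (c - uz) / d[2];
      if (t1 > t2) std::swap(t1, t2);
    } else {
      const double B = 2.0 * (ux * d[0] + uy * d[1]);
      const double C = ux * ux + uy * uy - a * a;
      const double disc = B * B - 4.0 * A * C;
      if (disc <= 0.0) return 0.0;
      const double sq = std::sqrt(disc);
      t1 = (-B - sq) / (2.0 * A);
      t2 = (-B + sq) / (2.0 * A);
      if (std::abs(d[2]) < 1e-30) {
        if (std::abs(uz) > c) return 0.0;
      } else {  // intersect with the |z - cz| <= c slab
        double s1 = (-c - uz) / d[2], s2 = (c - uz) / d[2];
        if (s1 > s2) std::swap(s1, s2);
        t1 = std::max(t1, s1);
        t2 = std::min(t2, s2);
      }
    }
  }
  const int axis = (int)P[8];
  if (axis > 0) {
    const double sign = P[9], bound = P[10];
    const double oa = o[axis - 1], da = d[axis - 1];
    if (std::abs(da) < 1e-30) {
      if (sign * (oa - bound) < 0.0) return 0.0;
    } else {
      const double tb = (bound - oa) / da;
      if (sign * da > 0.0) t1 = std::max(t1, tb);
      else t2 = std::min(t2, tb);
    }
  }
  const double len = t2 - t1;
  return len > 0.0 ? len * P[7] : 0.0;
}

// [[Rcpp::export]]
double cpp_line_integral(const arma::rowvec& prim, const arma::vec& origin,
                         const arma::vec& dir) {
  return chord_length(prim.memptr(), origin.memptr(), dir.memptr());
}

// Sinogram-ordered output: cube (n_heights, n_angles, width), element
// (h, t, u) = sum over primitives of density x chord along the parallel ray
// at height z_h, angle theta_t, detector offset s_u.
// [[Rcpp::export]]
arma::cube cpp_project_scene(const arma::mat& prims, int n_heights,
                             int n_angles, int width, double pixel_size,
                             double z0, double dz) {
  arma::cube out(n_heights, n_angles, width, arma::fill::zeros);
  if (prims.n_rows == 0) return out;
  const double u0 = (width - 1) / 2.0;
  arma::mat P = prims.t();  // column per primitive, contiguous access
  for (int t = 0; t < n_angles; ++t) {
    const double theta = (n_angles > 1)
        ? t * M_PI / (double)(n_angles - 1) : 0.0;
    const double ct = std::cos(theta), st = std::sin(theta);
    const double d[3] = {ct, st, 0.0};
    for (arma::uword k = 0; k < P.n_cols; ++k) {
      const double* pk = P.colptr(k);
      // detector-axis footprint of the primitive at this angle
      const double sc = -pk[1] * st + pk[2] * ct;
      const double rs = std::max(pk[4], pk[5]);
      int ulo = std::max(0, (int)std::floor((sc - rs) / pixel_size + u0));
      int uhi = std::min(width - 1,
                         (int)std::ceil((sc + rs) / pixel_size + u0));
      const double zlo = pk[3] - pk[6], zhi = pk[3] + pk[6];
      for (int h = 0; h < n_heights; ++h) {
        const double z = z0 + h * dz;
        if (z < zlo || z > zhi) continue;
        for (int u = ulo; u <= uhi; ++u) {
          const double s = (u - u0) * pixel_size;
          const double o[3] = {-s * st, s * ct, z};
          const double v = chord_length(pk, o, d);
          if (v != 0.0) out(h, t, u) += v;
        }
      }
    }
  }
  return out;
}
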