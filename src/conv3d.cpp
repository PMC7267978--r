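// 3D convolution kernels for the residual decoder.
//
// Activation layout is channel-fastest: an R array dim c(C, X, Y, Z, N).
// Weights for a k x k x k conv are an R array dim c(Cout, Cin, k, k, k),
// viewed here as a (Cout x Cin*k^3) matrix whose column index is
// ci + Cin*(kx + k*(ky + k*kz)) -- identical to the im2col row order, so a
// single GEMM per sample performs the convolution. Arithmetic is single
// precision: the GEMM dominates runtime and float halves it without
// affecting training at these problem sizes; results are returned as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather one sample (C,X,Y,Z) into columns of `col` ((Cin*k^3) x S_out).
void im2col(const float* x, int C, int X, int Y, int Z,
            int k, int stride, int pad,
            int OX, int OY, int OZ, arma::fmat& col) {
  col.zeros();
  const long sxy = static_cast<long>(C) * X;
  const long sxyz = sxy * Y;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const long s = ox + static_cast<long>(OX) * (oy + static_cast<long>(OY) * oz);
        float* cptr = col.colptr(s);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= X) continue;
              const float* src = x + C * static_cast<long>(ix) + sxy * iy + sxyz * iz;
              float* dst = cptr + C * (kx + k * (ky + static_cast<long>(k) * kz));
              std::memcpy(dst, src, sizeof(float) * C);
            }
          }
        }
      }
    }
  }
}

// Scatter-add columns of `col` back into one sample's gradient.
void col2im(const arma::fmat& col, float* gx, int C, int X, int Y, int Z,
            int k, int stride, int pad, int OX, int OY, int OZ) {
  const long sxy = static_cast<long>(C) * X;
  const long sxyz = sxy * Y;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const long s = ox + static_cast<long>(OX) * (oy + static_cast<long>(OY) * oz);
        const float* cptr = col.colptr(s);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= X) continue;
              float* dst = gx + C * static_cast<long>(ix) + sxy * iy + sxyz * iz;
              const float* src = cptr + C * (kx + k * (ky + static_cast<long>(k) * kz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

arma::fvec as_float(const NumericVector& v) {
  arma::fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = static_cast<float>(v[i]);
  return out;
}

} // namespace

// [[Rcpp::export(name = ".conv3d_fwd")]]
List conv3d_fwd(NumericVector x, IntegerVector xdim,
                NumericVector w, int cout,
                Nullable<NumericVector> bias,
                int k, int stride, int pad) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("convolution output extent is empty (%dx%dx%d)", OX, OY, OZ);
  const long S = static_cast<long>(OX) * OY * OZ;
  const long in_stride = static_cast<long>(C) * X * Y * Z;

  arma::fvec xf = as_float(x);
  arma::fvec wf = as_float(w);
  arma::fmat W(wf.memptr(), cout, C * k * k * k, false, true);
  arma::fvec b;
  if (bias.isNotNull()) b = as_float(bias.get());

  NumericVector out(static_cast<R_xlen_t>(cout) * S * N);
  arma::fmat col(C * k * k * k, S);
  arma::fmat o(cout, S);
  for (int n = 0; n < N; ++n) {
    im2col(xf.memptr() + in_stride * n, C, X, Y, Z, k, stride, pad, OX, OY, OZ, col);
    o = W * col;
    if (bias.isNotNull()) o.each_col() += b;
    double* dst = REAL(out) + static_cast<long>(cout) * S * n;
    const float* src = o.memptr();
    for (long i = 0; i < static_cast<long>(cout) * S; ++i) dst[i] = src[i];
  }
  out.attr("dim") = IntegerVector::create(cout, OX, OY, OZ, N);
  return List::create(_["out"] = out,
                      _["odim"] = IntegerVector::create(cout, OX, OY, OZ, N));
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, int cout,
                NumericVector gout, bool has_bias,
                int k, int stride, int pad, bool need_gx) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const long S = static_cast<long>(OX) * OY * OZ;
  const long in_stride = static_cast<long>(C) * X * Y * Z;
  const long out_stride = static_cast<long>(cout) * S;

  arma::fvec xf = as_float(x);
  arma::fvec wf = as_float(w);
  arma::fvec gf = as_float(gout);
  arma::fmat W(wf.memptr(), cout, C * k * k * k, false, true);

  arma::fmat gW(cout, C * k * k * k, arma::fill::zeros);
  arma::fvec gb(cout, arma::fill::zeros);
  arma::fvec gx;
  if (need_gx) gx.zeros(xf.size());

  arma::fmat col(C * k * k * k, S);
  arma::fmat gcol;
  for (int n = 0; n < N; ++n) {
    arma::fmat go(gf.memptr() + out_stride * n, cout, S, false, true);
    im2col(xf.memptr() + in_stride * n, C, X, Y, Z, k, stride, pad, OX, OY, OZ, col);
    gW += go * col.t();
    if (has_bias) gb += arma::sum(go, 1);
    if (need_gx) {
      gcol = W.t() * go;
      col2im(gcol, gx.memptr() + in_stride * n, C, X, Y, Z, k, stride, pad, OX, OY, OZ);
    }
  }

  NumericVector gw_out(gW.n_elem);
  std::copy(gW.begin(), gW.end(), gw_out.begin());
  gw_out.attr("dim") = IntegerVector::create(cout, C, k, k, k);
  List res = List::create(_["gw"] = gw_out);
  if (has_bias) {
    NumericVector gb_out(cout);
    std::copy(gb.begin(), gb.end(), gb_out.begin());
    res["gb"] = gb_out;
  }
  if (need_gx) {
    NumericVector gx_out(gx.n_elem);
    std::copy(gx.begin(), gx.end(), gx_out.begin());
    gx_out.attr("dim") = xdim;
    res["gx"] = gx_out;
  }
  return res;
}
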