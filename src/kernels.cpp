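// Compiled kernels for 3D tensor arithmetic, distance transforms and
// resampling.  Layout convention shared with the R side:
//   * a volume with dims (nx, ny, nz) is stored x-fastest, so linear voxel
//     index v = x + nx * (y + ny * z) (identical to an R array(dim = c(nx,ny,nz)));
//   * a feature grid with C channels is an N x C matrix (N = nx*ny*nz),
//     column-major, so each channel is one contiguous column.
// Convolutions are 3x3x3 (optionally dilated) with "same" zero padding;
// the weight matrix is c(3,3,3,Cin,Cout) flattened to (27*Cin) x Cout with
// tap order k = kx + 3*ky + 9*kz.  Parameters and gradients stay double
// precision on the R side; the GEMM operands are single precision.

#include <RcppArmadillo.h>
#include <cfloat>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Padded transposed image layout for convolution: Xp is (channels x
// Npad) single precision, where the spatial grid is zero-padded by the
// dilation d on every side.  Each of the 27 kernel taps then corresponds to
// a constant column offset, so the convolution is 27 submatrix GEMMs with
// no data rearrangement; slab-wise column blocking keeps the operands
// cache-resident.  Outputs computed in the pad region are discarded.

static void pack_padded_into(const double* x, int nx, int ny, int nz, int C,
                             int d, float* xp, long Npad) {
  const int pnx = nx + 2 * d, pny = ny + 2 * d;
  const size_t N = (size_t)nx * ny * nz;
  std::memset(xp, 0, sizeof(float) * (size_t)C * Npad);
  const int VB = 16;   // voxel block: write window (VB*C floats) stays in L1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t srow = (size_t)nx * (y + (size_t)ny * z);
      const size_t base = d + (size_t)pnx * ((y + d) + (size_t)pny * (z + d));
      for (int i0 = 0; i0 < nx; i0 += VB) {
        const int i1 = std::min(nx, i0 + VB);
        for (int c = 0; c < C; ++c) {
          const double* __restrict__ s = x + (size_t)c * N + srow + i0;
          float* __restrict__ t = xp + c + (base + i0) * C;
          for (int i = 0; i < i1 - i0; ++i) t[(size_t)i * C] = (float)s[i];
        }
      }
    }
}

static void pack_padded(const double* x, int nx, int ny, int nz, int C,
                        int d, arma::fmat& Xp) {
  pack_padded_into(x, nx, ny, nz, C, d, Xp.memptr(), (long)Xp.n_cols);
}

static void unpack_padded(const arma::fmat& Yt, int nx, int ny, int nz, int C,
                          int d, const double* bias, double* y) {
  const int pnx = nx + 2 * d, pny = ny + 2 * d;
  const size_t N = (size_t)nx * ny * nz;
  const float* yp = Yt.memptr();
  const int VB = 16;
  for (int z = 0; z < nz; ++z)
    for (int y_ = 0; y_ < ny; ++y_) {
      const size_t drow = (size_t)nx * (y_ + (size_t)ny * z);
      const size_t base = d + (size_t)pnx * ((y_ + d) + (size_t)pny * (z + d));
      for (int i0 = 0; i0 < nx; i0 += VB) {
        const int i1 = std::min(nx, i0 + VB);
        for (int c = 0; c < C; ++c) {
          const float* __restrict__ s = yp + c + (base + i0) * C;
          double* __restrict__ t = y + (size_t)c * N + drow + i0;
          const double bc = bias ? bias[c] : 0.0;
          for (int i = 0; i < i1 - i0; ++i) t[i] = (double)s[(size_t)i * C] + bc;
        }
      }
    }
}

// 27 column offsets for taps (kx, ky, kz) in {-1,0,1} * d on the padded grid
static void tap_offsets(int pnx, int pny, int d, long* off) {
  int k = 0;
  for (int kz = -1; kz <= 1; ++kz)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx, ++k)
        off[k] = (long)kx * d + (long)pnx * ((long)ky * d + (long)pny * kz * d);
}


// Direct convolution on the padded transposed layout: for every real output
// column v, Yt(:, v) = sum_k Wk * Xp(:, v + off_k).  All 27 taps accumulate
// in registers (voxel-blocked, channel-vectorised), so each input column is
// read 27 times from cache but the accumulators never leave registers.
// Real columns occupy exactly [vlo, vhi); pad columns are never read by
// unpack_padded, so they are left untouched.
template <int COUT>
static void conv_direct_t(const float* __restrict__ Xp, const float* __restrict__ W,
                          int cin, long vlo, long vhi, const long* off,
                          float* __restrict__ Yt) {
  long v = vlo;
  for (; v + 4 <= vhi; v += 4) {
    float acc0[COUT] = {0}, acc1[COUT] = {0}, acc2[COUT] = {0}, acc3[COUT] = {0};
    for (int k = 0; k < 27; ++k) {
      const float* __restrict__ xc = Xp + (v + off[k]) * cin;
      const float* __restrict__ wk = W + (size_t)k * cin * COUT;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci], x1 = xc[cin + ci],
                    x2 = xc[2 * cin + ci], x3 = xc[3 * cin + ci];
        const float* __restrict__ wv = wk + (size_t)ci * COUT;
        for (int c = 0; c < COUT; ++c) {
          acc0[c] += wv[c] * x0; acc1[c] += wv[c] * x1;
          acc2[c] += wv[c] * x2; acc3[c] += wv[c] * x3;
        }
      }
    }
    float* y = Yt + v * COUT;
    for (int c = 0; c < COUT; ++c) { y[c] = acc0[c]; y[COUT + c] = acc1[c];
      y[2 * COUT + c] = acc2[c]; y[3 * COUT + c] = acc3[c]; }
  }
  for (; v < vhi; ++v) {
    float acc[COUT] = {0};
    for (int k = 0; k < 27; ++k) {
      const float* __restrict__ xc = Xp + (v + off[k]) * cin;
      const float* __restrict__ wk = W + (size_t)k * cin * COUT;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci];
        const float* __restrict__ wv = wk + (size_t)ci * COUT;
        for (int c = 0; c < COUT; ++c) acc[c] += wv[c] * x0;
      }
    }
    float* __restrict__ y = Yt + v * COUT;
    for (int c = 0; c < COUT; ++c) y[c] = acc[c];
  }
}

static void conv_direct_g(const float* __restrict__ Xp, const float* __restrict__ W,
                          int cin, int cout, long vlo, long vhi, const long* off,
                          float* __restrict__ Yt) {
  std::vector<float> acc(4 * cout);
  long v = vlo;
  for (; v + 4 <= vhi; v += 4) {
    std::fill(acc.begin(), acc.end(), 0.0f);
    float* a0 = acc.data(); float* a1 = a0 + cout; float* a2 = a1 + cout; float* a3 = a2 + cout;
    for (int k = 0; k < 27; ++k) {
      const float* xc = Xp + (v + off[k]) * cin;
      const float* wk = W + (size_t)k * cin * cout;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci], x1 = xc[cin + ci],
                    x2 = xc[2 * cin + ci], x3 = xc[3 * cin + ci];
        const float* wv = wk + (size_t)ci * cout;
        for (int c = 0; c < cout; ++c) {
          a0[c] += wv[c] * x0; a1[c] += wv[c] * x1;
          a2[c] += wv[c] * x2; a3[c] += wv[c] * x3;
        }
      }
    }
    float* y = Yt + v * cout;
    for (int c = 0; c < cout; ++c) { y[c] = a0[c]; y[cout + c] = a1[c];
      y[2 * cout + c] = a2[c]; y[3 * cout + c] = a3[c]; }
  }
  for (; v < vhi; ++v) {
    std::fill(acc.begin(), acc.begin() + cout, 0.0f);
    float* a0 = acc.data();
    for (int k = 0; k < 27; ++k) {
      const float* xc = Xp + (v + off[k]) * cin;
      const float* wk = W + (size_t)k * cin * cout;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci];
        const float* wv = wk + (size_t)ci * cout;
        for (int c = 0; c < cout; ++c) a0[c] += wv[c] * x0;
      }
    }
    float* y = Yt + v * cout;
    for (int c = 0; c < cout; ++c) y[c] = a0[c];
  }
}

static void conv_direct(const float* Xp, const float* W, int cin, int cout,
                        long vlo, long vhi, const long* off, float* Yt) {
  switch (cout) {
    case 1:  conv_direct_t<1>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 2:  conv_direct_t<2>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 3:  conv_direct_t<3>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 4:  conv_direct_t<4>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 8:  conv_direct_t<8>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 12: conv_direct_t<12>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 16: conv_direct_t<16>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 24: conv_direct_t<24>(Xp, W, cin, vlo, vhi, off, Yt); break;
    case 32: conv_direct_t<32>(Xp, W, cin, vlo, vhi, off, Yt); break;
    default: conv_direct_g(Xp, W, cin, cout, vlo, vhi, off, Yt);
  }
}


// Direct weight gradient: one streaming pass over the real columns,
// 4-voxel blocked, accumulating all 27 tap outer products in a
// cache-resident block (27*cin*cout floats).
template <int COUT>
static void conv_dw_direct_t(const float* __restrict__ Xp,
                             const float* __restrict__ dYp,
                             int cin, long vlo, long vhi,
                             const long* off, float* __restrict__ acc) {
  long v = vlo;
  for (; v + 4 <= vhi; v += 4) {
    const float* __restrict__ dy0 = dYp + v * COUT;
    const float* __restrict__ dy1 = dy0 + COUT;
    const float* __restrict__ dy2 = dy1 + COUT;
    const float* __restrict__ dy3 = dy2 + COUT;
    for (int k = 0; k < 27; ++k) {
      const float* __restrict__ xc = Xp + (v + off[k]) * cin;
      float* __restrict__ ak = acc + (size_t)k * cin * COUT;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci], x1 = xc[cin + ci],
                    x2 = xc[2 * cin + ci], x3 = xc[3 * cin + ci];
        float* __restrict__ av = ak + (size_t)ci * COUT;
        for (int c = 0; c < COUT; ++c)
          av[c] += dy0[c] * x0 + dy1[c] * x1 + dy2[c] * x2 + dy3[c] * x3;
      }
    }
  }
  for (; v < vhi; ++v) {
    const float* __restrict__ dy = dYp + v * COUT;
    for (int k = 0; k < 27; ++k) {
      const float* __restrict__ xc = Xp + (v + off[k]) * cin;
      float* __restrict__ ak = acc + (size_t)k * cin * COUT;
      for (int ci = 0; ci < cin; ++ci) {
        const float x0 = xc[ci];
        float* __restrict__ av = ak + (size_t)ci * COUT;
        for (int c = 0; c < COUT; ++c) av[c] += dy[c] * x0;
      }
    }
  }
}

static bool conv_dw_direct(const float* Xp, const float* dYp, int cin, int cout,
                           long vlo, long vhi, const long* off, float* acc) {
  switch (cout) {
    case 4:  conv_dw_direct_t<4>(Xp, dYp, cin, vlo, vhi, off, acc); return true;
    case 8:  conv_dw_direct_t<8>(Xp, dYp, cin, vlo, vhi, off, acc); return true;
    case 16: conv_dw_direct_t<16>(Xp, dYp, cin, vlo, vhi, off, acc); return true;
    case 32: conv_dw_direct_t<32>(Xp, dYp, cin, vlo, vhi, off, acc); return true;
    default: return false;
  }
}

// weight blocks in tap-major layout W[k][ci][c]
static std::vector<float> tap_weights(const NumericMatrix& w, int cin, int cout) {
  std::vector<float> W((size_t)27 * cin * cout);
  for (int k = 0; k < 27; ++k)
    for (int ci = 0; ci < cin; ++ci)
      for (int c = 0; c < cout; ++c)
        W[(size_t)k * cin * cout + (size_t)ci * cout + c] = (float)w(k + 27 * ci, c);
  return W;
}

// transposed weight blocks with mirrored taps, for the input gradient:
// dX(u) = sum_k Wk^T dY(u - off_k)
static std::vector<float> tap_weights_T(const NumericMatrix& w, int cin, int cout) {
  std::vector<float> W((size_t)27 * cin * cout);
  for (int k = 0; k < 27; ++k)
    for (int ci = 0; ci < cin; ++ci)
      for (int c = 0; c < cout; ++c)
        W[(size_t)k * cin * cout + (size_t)c * cin + ci] = (float)w(k + 27 * ci, c);
  return W;
}

// [[Rcpp::export]]
List conv3d_fw(NumericMatrix x, IntegerVector dims, NumericMatrix w,
               NumericVector bias, int dilation) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], d = dilation;
  const int N = nx * ny * nz, cin = x.ncol(), cout = w.ncol();
  if (x.nrow() != N) stop("conv3d_fw: voxel count mismatch");
  if (w.nrow() != 27 * cin) stop("conv3d_fw: weight shape mismatch");
  const int pnx = nx + 2 * d, pny = ny + 2 * d, pnz = nz + 2 * d;
  const long Npad = (long)pnx * pny * pnz;
  RawVector xpad(sizeof(float) * (size_t)cin * Npad);
  float* Xp = reinterpret_cast<float*>(xpad.begin());
  pack_padded_into(x.begin(), nx, ny, nz, cin, d, Xp, Npad);
  long off[27];
  tap_offsets(pnx, pny, d, off);
  const long vlo = (long)d * (1 + (long)pnx * (1 + (long)pny));
  const long vhi = Npad - vlo;
  arma::fmat Yt(cout, Npad);
  if (cout <= 32) {
    std::vector<float> W = tap_weights(w, cin, cout);
    conv_direct(Xp, W.data(), cin, cout, vlo, vhi, off, Yt.memptr());
  } else {
    Yt.zeros();
    arma::fmat Xpv(Xp, cin, Npad, false, true);
    std::vector<arma::fmat> Wk(27, arma::fmat(cout, cin));
    for (int k = 0; k < 27; ++k)
      for (int ci = 0; ci < cin; ++ci)
        for (int c = 0; c < cout; ++c) Wk[k](c, ci) = (float)w(k + 27 * ci, c);
    const long slab = 8192;
    arma::fmat P(cout, slab);
    for (long c0 = 0; c0 < Npad; c0 += slab) {
      const long c1 = std::min(Npad, c0 + slab);
      for (int k = 0; k < 27; ++k) {
        const long o = off[k];
        const long lo = std::max(c0, o < 0 ? -o : 0L);
        const long hi = std::min(c1, Npad - (o > 0 ? o : 0L));
        if (hi <= lo) continue;
        arma::fmat Pv(P.memptr(), cout, hi - lo, false, true);
        Pv = Wk[k] * Xpv.cols(lo + o, hi + o - 1);
        Yt.cols(lo, hi - 1) += Pv;
      }
    }
  }
  NumericMatrix y(N, cout);
  unpack_padded(Yt, nx, ny, nz, cout, d, bias.begin(), y.begin());
  return List::create(_["y"] = y, _["xpad"] = xpad);
}

// [[Rcpp::export]]
List conv3d_bw(RawVector xpad, NumericMatrix dy, IntegerVector dims,
               int cin, NumericMatrix w, int dilation, bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], d = dilation;
  const int N = nx * ny * nz, cout = w.ncol();
  const int pnx = nx + 2 * d, pny = ny + 2 * d, pnz = nz + 2 * d;
  const long Npad = (long)pnx * pny * pnz;
  if ((long)xpad.size() != (long)sizeof(float) * cin * Npad)
    stop("conv3d_bw: packed input size mismatch");
  const float* Xp = reinterpret_cast<const float*>(xpad.begin());
  arma::fmat dYp(cout, Npad);
  pack_padded(dy.begin(), nx, ny, nz, cout, d, dYp);
  long off[27], noff[27];
  tap_offsets(pnx, pny, d, off);
  for (int k = 0; k < 27; ++k) noff[k] = -off[k];
  const long vlo = (long)d * (1 + (long)pnx * (1 + (long)pny));
  const long vhi = Npad - vlo;
  NumericMatrix dxm(need_dx ? N : 1, need_dx ? cin : 1);
  if (need_dx) {
    arma::fmat dXp(cin, Npad);
    std::vector<float> Wt = tap_weights_T(w, cin, cout);
    if (cin <= 32) {
      conv_direct(dYp.memptr(), Wt.data(), cout, cin, vlo, vhi, noff, dXp.memptr());
    } else {
      dXp.zeros();
      std::vector<arma::fmat> WkT(27, arma::fmat(cin, cout));
      for (int k = 0; k < 27; ++k)
        for (int ci = 0; ci < cin; ++ci)
          for (int c = 0; c < cout; ++c) WkT[k](ci, c) = (float)w(k + 27 * ci, c);
      const long slab = 8192;
      arma::fmat P(cin, slab);
      for (long c0 = 0; c0 < Npad; c0 += slab) {
        const long c1 = std::min(Npad, c0 + slab);
        for (int k = 0; k < 27; ++k) {
          const long o = noff[k];
          const long lo = std::max(c0, o < 0 ? -o : 0L);
          const long hi = std::min(c1, Npad - (o > 0 ? o : 0L));
          if (hi <= lo) continue;
          arma::fmat Pv(P.memptr(), cin, hi - lo, false, true);
          Pv = WkT[k] * dYp.cols(lo + o, hi + o - 1);
          dXp.cols(lo, hi - 1) += Pv;
        }
      }
    }
    std::vector<double> zero_bias(cin, 0.0);
    unpack_padded(dXp, nx, ny, nz, cin, d, zero_bias.data(), dxm.begin());
  }
  NumericMatrix dwm(27 * cin, cout);
  bool dw_done = false;
  if ((size_t)cin * cout <= 1024) {
    std::vector<float> acc((size_t)27 * cin * cout, 0.0f);
    dw_done = conv_dw_direct(Xp, dYp.memptr(), cin, cout, vlo, vhi, off, acc.data());
    if (dw_done)
    for (int k = 0; k < 27; ++k)
      for (int ci = 0; ci < cin; ++ci)
        for (int c = 0; c < cout; ++c)
          dwm(k + 27 * ci, c) = (double)acc[(size_t)k * cin * cout + (size_t)ci * cout + c];
  }
  if (!dw_done) {
    arma::fmat Xpv(const_cast<float*>(Xp), cin, Npad, false, true);
    std::vector<arma::fmat> dWk(27, arma::fmat(cout, cin, arma::fill::zeros));
    const long slab = 65536;
    for (long c0 = 0; c0 < Npad; c0 += slab) {
      const long c1 = std::min(Npad, c0 + slab);
      for (int k = 0; k < 27; ++k) {
        const long o = off[k];
        const long lo = std::max(c0, o < 0 ? -o : 0L);
        const long hi = std::min(c1, Npad - (o > 0 ? o : 0L));
        if (hi > lo)
          dWk[k] += dYp.cols(lo, hi - 1) * Xpv.cols(lo + o, hi + o - 1).t();
      }
    }
    for (int k = 0; k < 27; ++k)
      for (int ci = 0; ci < cin; ++ci)
        for (int c = 0; c < cout; ++c) dwm(k + 27 * ci, c) = (double)dWk[k](c, ci);
  }
  NumericVector dbv(cout);
  arma::mat dYm(dy.begin(), N, cout, false, true);
  arma::rowvec db = arma::sum(dYm, 0);
  std::copy(db.begin(), db.end(), dbv.begin());
  return List::create(_["dx"] = dxm, _["dw"] = dwm, _["db"] = dbv);
}

// Fused instance normalisation + LeakyReLU over an N x C feature matrix
// (statistics per channel over all voxels of the sample).  The backward
// pass reconstructs the normalised activation from the output itself
// (LeakyReLU with positive slope is invertible), so no intermediates other
// than the per-channel statistics are stored.
// [[Rcpp::export]]
List inorm_act_fw(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  double slope, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(n, C);
  NumericVector istd(C), mu(C);
  for (int c = 0; c < C; ++c) {
    const double* __restrict__ xc = &x(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    double va = s2 / n - m * m;
    if (va < 0) va = 0;
    const double is = 1.0 / std::sqrt(va + eps);
    mu[c] = m; istd[c] = is;
    const double g = gamma[c], b = beta[c];
    const double a = is * g;          // y = a*(x-m) + b, then leaky relu
    double* __restrict__ yc = &y(0, c);
    for (int i = 0; i < n; ++i) {
      const double z = a * (xc[i] - m) + b;
      yc[i] = z > 0 ? z : slope * z;
    }
  }
  return List::create(_["y"] = y, _["istd"] = istd, _["mu"] = mu);
}

// [[Rcpp::export]]
List inorm_act_bw(NumericMatrix g, NumericMatrix y, NumericVector istd,
                  NumericVector gamma, NumericVector beta, double slope) {
  const int n = g.nrow(), C = g.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* __restrict__ gc = &g(0, c);
    const double* __restrict__ yc = &y(0, c);
    const double ga = gamma[c], be = beta[c], is = istd[c];
    const double inv_ga = 1.0 / ga;
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      const bool p = yc[i] > 0;
      const double z = p ? yc[i] : yc[i] / slope;
      const double xh = (z - be) * inv_ga;
      const double dz = gc[i] * (p ? 1.0 : slope);
      const double dxh = dz * ga;
      s1 += dxh; s2 += dxh * xh; sg += dz * xh; sb += dz;
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double m1 = s1 / n, m2 = s2 / n;
    double* __restrict__ dxc = &dx(0, c);
    for (int i = 0; i < n; ++i) {
      const bool p = yc[i] > 0;
      const double z = p ? yc[i] : yc[i] / slope;
      const double xh = (z - be) * inv_ga;
      const double dz = gc[i] * (p ? 1.0 : slope);
      dxc[i] = (dz * ga - m1 - xh * m2) * is;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x max pooling with ceil semantics (windows clipped at the far border).
// Returns pooled values plus the flat argmax input index (0-based) per
// output voxel and channel, for the backward scatter.
// [[Rcpp::export]]
List maxpool2_fw(NumericMatrix x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = x.ncol();
  const int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  const int M = ox * oy * oz;
  NumericMatrix y(M, C);
  IntegerMatrix idx(M, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &x(0, c);
    for (int z = 0; z < oz; ++z) {
      for (int yy = 0; yy < oy; ++yy) {
        for (int xx = 0; xx < ox; ++xx) {
          double best = -DBL_MAX; int bi = -1;
          for (int dz = 0; dz < 2; ++dz) {
            int sz = 2 * z + dz; if (sz >= nz) break;
            for (int dy = 0; dy < 2; ++dy) {
              int sy = 2 * yy + dy; if (sy >= ny) break;
              for (int dx = 0; dx < 2; ++dx) {
                int sx = 2 * xx + dx; if (sx >= nx) break;
                int v = sx + nx * (sy + ny * sz);
                if (src[v] > best) { best = src[v]; bi = v; }
              }
            }
          }
          int o = xx + ox * (yy + oy * z);
          y(o, c) = best; idx(o, c) = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["outdims"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bw(NumericMatrix dy, IntegerMatrix idx, int n_in) {
  const int M = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n_in, C);
  for (int c = 0; c < C; ++c)
    for (int o = 0; o < M; ++o)
      dx(idx(o, c), c) += dy(o, c);
  return dx;
}

struct LinAxis { std::vector<int> i0, i1; std::vector<double> w1; };

static LinAxis lin_axis(int n_in, int n_out) {
  LinAxis a; a.i0.resize(n_out); a.i1.resize(n_out); a.w1.resize(n_out);
  const double r = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * r - 0.5;
    if (s < 0) s = 0; if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    a.i0[o] = i0; a.i1[o] = i1; a.w1[o] = s - i0;
  }
  return a;
}

// trilinear resize to arbitrary output dims (half-pixel centre alignment)
// [[Rcpp::export]]
NumericMatrix resize3_fw(NumericMatrix x, IntegerVector dims, IntegerVector outdims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = x.ncol();
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  LinAxis ax = lin_axis(nx, ox), ay = lin_axis(ny, oy), az = lin_axis(nz, oz);
  NumericMatrix y(ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* s = &x(0, c);
    double* t = &y(0, c);
    size_t o = 0;
    for (int z = 0; z < oz; ++z) {
      const int z0 = az.i0[z], z1 = az.i1[z]; const double wz = az.w1[z];
      for (int yy = 0; yy < oy; ++yy) {
        const int y0 = ay.i0[yy], y1 = ay.i1[yy]; const double wy = ay.w1[yy];
        const size_t b00 = (size_t)nx * (y0 + (size_t)ny * z0);
        const size_t b10 = (size_t)nx * (y1 + (size_t)ny * z0);
        const size_t b01 = (size_t)nx * (y0 + (size_t)ny * z1);
        const size_t b11 = (size_t)nx * (y1 + (size_t)ny * z1);
        for (int xx = 0; xx < ox; ++xx, ++o) {
          const int x0 = ax.i0[xx], x1 = ax.i1[xx]; const double wx = ax.w1[xx];
          const double v00 = s[b00 + x0] * (1 - wx) + s[b00 + x1] * wx;
          const double v10 = s[b10 + x0] * (1 - wx) + s[b10 + x1] * wx;
          const double v01 = s[b01 + x0] * (1 - wx) + s[b01 + x1] * wx;
          const double v11 = s[b11 + x0] * (1 - wx) + s[b11 + x1] * wx;
          t[o] = (v00 * (1 - wy) + v10 * wy) * (1 - wz) + (v01 * (1 - wy) + v11 * wy) * wz;
        }
      }
    }
  }
  return y;
}

// transpose of resize3_fw: scatter output gradients with identical weights
// [[Rcpp::export]]
NumericMatrix resize3_bw(NumericMatrix dy, IntegerVector dims, IntegerVector outdims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dy.ncol();
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  LinAxis ax = lin_axis(nx, ox), ay = lin_axis(ny, oy), az = lin_axis(nz, oz);
  NumericMatrix dx(nx * ny * nz, C);
  for (int c = 0; c < C; ++c) {
    double* t = &dx(0, c);
    const double* g = &dy(0, c);
    size_t o = 0;
    for (int z = 0; z < oz; ++z) {
      const int z0 = az.i0[z], z1 = az.i1[z]; const double wz = az.w1[z];
      for (int yy = 0; yy < oy; ++yy) {
        const int y0 = ay.i0[yy], y1 = ay.i1[yy]; const double wy = ay.w1[yy];
        const size_t b00 = (size_t)nx * (y0 + (size_t)ny * z0);
        const size_t b10 = (size_t)nx * (y1 + (size_t)ny * z0);
        const size_t b01 = (size_t)nx * (y0 + (size_t)ny * z1);
        const size_t b11 = (size_t)nx * (y1 + (size_t)ny * z1);
        for (int xx = 0; xx < ox; ++xx, ++o) {
          const int x0 = ax.i0[xx], x1 = ax.i1[xx]; const double wx = ax.w1[xx];
          const double gv = g[o];
          t[b00 + x0] += gv * (1 - wx) * (1 - wy) * (1 - wz);
          t[b00 + x1] += gv * wx * (1 - wy) * (1 - wz);
          t[b10 + x0] += gv * (1 - wx) * wy * (1 - wz);
          t[b10 + x1] += gv * wx * wy * (1 - wz);
          t[b01 + x0] += gv * (1 - wx) * (1 - wy) * wz;
          t[b01 + x1] += gv * wx * (1 - wy) * wz;
          t[b11 + x0] += gv * (1 - wx) * wy * wz;
          t[b11 + x1] += gv * wx * wy * wz;
        }
      }
    }
  }
  return dx;
}

// Affine resampling of a single-channel volume: output voxel (i,j,k) is read
// from source index-space coordinate M %*% c(i,j,k) + t.
// mode 0 = trilinear with `fill` outside, 1 = nearest with `fill` outside,
// mode 2 = trilinear with coordinates clamped to the border, 3 = nearest clamped.
// [[Rcpp::export]]
NumericVector affine_sample(NumericVector vol, IntegerVector dims,
                            NumericMatrix M, NumericVector t,
                            IntegerVector outdims, int mode, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double* o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  const bool clamp = mode >= 2;
  size_t p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++p) {
        double sx = m00 * i + m01 * j + m02 * k + t[0];
        double sy = m10 * i + m11 * j + m12 * k + t[1];
        double sz = m20 * i + m21 * j + m22 * k + t[2];
        if (clamp) {
          sx = std::min(std::max(sx, 0.0), (double)nx - 1);
          sy = std::min(std::max(sy, 0.0), (double)ny - 1);
          sz = std::min(std::max(sz, 0.0), (double)nz - 1);
        }
        if (mode == 1 || mode == 3) {
          const int xi = (int)std::lround(sx), yi = (int)std::lround(sy),
                    zi = (int)std::lround(sz);
          o[p] = (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
                   ? fill : v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          const double wx = sx - x0, wy = sy - y0, wz = sz - z0;
          double acc = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const double w = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy) * (dz ? wz : 1 - wz);
                if (w == 0) continue;
                const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                const double val =
                  (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
                    ? fill : v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
                acc += w * val;
              }
          o[p] = acc;
        }
      }
  return out;
}

// nearest-neighbour warp of a label volume by a per-voxel displacement field
// (in voxel units); out-of-range reads clamp to the border.
// [[Rcpp::export]]
NumericVector warp_nearest(NumericVector vol, IntegerVector dims, NumericMatrix disp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  const double* v = vol.begin();
  size_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        int xi = (int)std::lround(i + disp(p, 0));
        int yi = (int)std::lround(j + disp(p, 1));
        int zi = (int)std::lround(k + disp(p, 2));
        xi = std::min(std::max(xi, 0), nx - 1);
        yi = std::min(std::max(yi, 0), ny - 1);
        zi = std::min(std::max(zi, 0), nz - 1);
        out[p] = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
  return out;
}

static void smooth_axis(std::vector<double>& buf, double* v, int n, int stride,
                        const std::vector<double>& ker) {
  const int r = (int)ker.size() / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0) j = -j - 1;            // reflect
      if (j >= n) j = 2 * n - 1 - j;
      acc += ker[k + r] * v[(size_t)j * stride];
    }
    buf[i] = acc;
  }
  for (int i = 0; i < n; ++i) v[(size_t)i * stride] = buf[i];
}

// separable Gaussian smoothing, sigma per axis in voxels, reflect boundary
// [[Rcpp::export]]
NumericVector gauss_smooth3(NumericVector x, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(x);
  double* v = out.begin();
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int k = -r; k <= r; ++k) { ker[k + r] = std::exp(-0.5 * k * k / (s * s)); sum += ker[k + r]; }
    for (auto& kv : ker) kv /= sum;
    const int n = (ax == 0 ? nx : ax == 1 ? ny : nz);
    std::vector<double> buf(n);
    if (ax == 0) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          smooth_axis(buf, v + (size_t)nx * (y + (size_t)ny * z), n, 1, ker);
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z)
        for (int x0 = 0; x0 < nx; ++x0)
          smooth_axis(buf, v + x0 + (size_t)nx * ny * z, n, nx, ker);
    } else {
      for (int y = 0; y < ny; ++y)
        for (int x0 = 0; x0 < nx; ++x0)
          smooth_axis(buf, v + x0 + (size_t)nx * y, n, nx * ny, ker);
    }
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with
// anisotropic step s: d(i) = min_j (i-j)^2 s^2 + f(j)
static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& vtx, std::vector<double>& zpt) {
  int q0 = 0;
  while (q0 < n && f[q0] == DBL_MAX) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = DBL_MAX; return; }
  int k = 0;
  vtx[0] = q0; zpt[0] = -DBL_MAX; zpt[1] = DBL_MAX;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == DBL_MAX) continue;
    double sval = 0;
    while (k >= 0) {
      const int p = vtx[k];
      sval = ((f[q] + (double)q * q * s2) - (f[p] + (double)p * p * s2)) /
             (2.0 * s2 * (q - p));
      if (sval <= zpt[k]) --k; else break;
    }
    if (k < 0) { k = 0; vtx[0] = q; zpt[0] = -DBL_MAX; zpt[1] = DBL_MAX; }
    else { ++k; vtx[k] = q; zpt[k] = sval; zpt[k + 1] = DBL_MAX; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zpt[k + 1] < q) ++k;
    const int p = vtx[k];
    d[q] = (double)(q - p) * (q - p) * s2 + f[p];
  }
}

// exact squared Euclidean distance (mm^2) to the nearest nonzero voxel
// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  double* d = out.begin();
  for (size_t i = 0; i < N; ++i) d[i] = mask[i] ? 0.0 : DBL_MAX;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> vtx(nmax);
  std::vector<double> zpt(nmax + 1), f(nmax), dd(nmax);
  // x pass
  double s2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* row = d + (size_t)nx * (y + (size_t)ny * z);
      dt1d(row, dd.data(), nx, s2, vtx, zpt);
      std::copy(dd.begin(), dd.begin() + nx, row);
    }
  // y pass
  s2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x0 = 0; x0 < nx; ++x0) {
      double* base = d + x0 + (size_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = base[(size_t)y * nx];
      dt1d(f.data(), dd.data(), ny, s2, vtx, zpt);
      for (int y = 0; y < ny; ++y) base[(size_t)y * nx] = dd[y];
    }
  // z pass
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x0 = 0; x0 < nx; ++x0) {
      double* base = d + x0 + (size_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = base[(size_t)z * nx * ny];
      dt1d(f.data(), dd.data(), nz, s2, vtx, zpt);
      for (int z = 0; z < nz; ++z) base[(size_t)z * nx * ny] = dd[z];
    }
  return out;
}

// 26-connected component labelling of a binary mask (labels 1..k by
// discovery order; component sizes returned alongside)
// [[Rcpp::export]]
List cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N);
  std::vector<size_t> stack;
  std::vector<int> sizes;
  int next = 0;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    int size = 0;
    stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xi = x + dx, yi = y + dy, zi = z + dz;
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) continue;
            const size_t u = xi + (size_t)nx * (yi + (size_t)ny * zi);
            if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
          }
    }
    sizes.push_back(size);
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}
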