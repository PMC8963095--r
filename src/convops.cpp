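// Low-level 3D tensor kernels backing the inception U-Net and the
// connected-component postprocessing.  Arrays arrive from R in column-major
// order with dimensions (X, Y, Z, C); weights as (k, k, k, Cin, Cout).
// Convolutions use "same" zero padding and are evaluated as chunked
// im2col + GEMM so the patch matrix never exceeds a few tens of MB.

#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long long idx4(int x, int y, int z, int c,
                             int X, int Y, int Z) {
  return x + (long long)X * (y + (long long)Y * (z + (long long)Z * c));
}

// Fill the im2col patch matrix for z-slab [z0, z1).  Row order is
// x + X*y + X*Y*(z - z0); column order is dx + k*dy + k*k*dz + k^3*ci,
// matching the column-major layout of a (k,k,k,Cin,Cout) weight array
// flattened to (k^3*Cin) x Cout.
static void im2col_slab(const double* x, int X, int Y, int Z, int Cin,
                        int k, int pad, int z0, int z1, arma::mat& P) {
  const int rows = X * Y * (z1 - z0);
  P.zeros(rows, (long long)k * k * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const int col = dx + k * (dy + k * (dz + k * ci));
          double* pcol = P.colptr(col);
          for (int z = z0; z < z1; ++z) {
            const int sz = z + dz - pad;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy - pad;
              if (sy < 0 || sy >= Y) continue;
              // x-run: valid sx are [max(0,pad-dx), min(X, X+pad-dx))
              int xlo = pad - dx; if (xlo < 0) xlo = 0;
              int xhi = X + pad - dx; if (xhi > X) xhi = X;
              if (xlo >= xhi) continue;
              const long long src0 = idx4(xlo + dx - pad, sy, sz, ci, X, Y, Z);
              const long long row0 = xlo + (long long)X * (y + (long long)Y * (z - z0));
              std::memcpy(pcol + row0, x + src0, sizeof(double) * (xhi - xlo));
            }
          }
        }
      }
    }
  }
}

static int slab_height(int X, int Y, long long cols) {
  // cap the patch matrix at ~48 MB of doubles
  long long zb = 6000000LL / ((long long)X * Y * cols);
  if (zb < 1) zb = 1;
  return (int)zb;
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector dims,
                            NumericVector w, int k, int cout,
                            NumericVector bias) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int pad = (k - 1) / 2;
  const long long cols = (long long)k * k * k * Cin;
  NumericVector y((long long)X * Y * Z * cout);
  arma::mat W(w.begin(), cols, cout, false, true);
  arma::mat P;
  const int zb = slab_height(X, Y, cols);
  for (int z0 = 0; z0 < Z; z0 += zb) {
    const int z1 = std::min(Z, z0 + zb);
    im2col_slab(x.begin(), X, Y, Z, Cin, k, pad, z0, z1, P);
    arma::mat Yc = P * W;
    const int rows = X * Y * (z1 - z0);
    for (int co = 0; co < cout; ++co) {
      const double b = bias[co];
      const double* src = Yc.colptr(co);
      double* dst = y.begin() + idx4(0, 0, z0, co, X, Y, Z);
      for (int r = 0; r < rows; ++r) dst[r] = src[r] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector dims,
                   NumericVector w, int k, int cout,
                   NumericVector gy) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int pad = (k - 1) / 2;
  const long long cols = (long long)k * k * k * Cin;
  arma::mat W(w.begin(), cols, cout, false, true);
  arma::mat GW(cols, cout, arma::fill::zeros);
  arma::vec GB(cout, arma::fill::zeros);
  NumericVector gx(x.size());
  arma::mat P, Gc;
  const int zb = slab_height(X, Y, cols);
  for (int z0 = 0; z0 < Z; z0 += zb) {
    const int z1 = std::min(Z, z0 + zb);
    const int rows = X * Y * (z1 - z0);
    im2col_slab(x.begin(), X, Y, Z, Cin, k, pad, z0, z1, P);
    Gc.set_size(rows, cout);
    for (int co = 0; co < cout; ++co) {
      const double* src = gy.begin() + idx4(0, 0, z0, co, X, Y, Z);
      std::memcpy(Gc.colptr(co), src, sizeof(double) * rows);
    }
    GW += P.t() * Gc;
    GB += arma::sum(Gc, 0).t();
    arma::mat GP = Gc * W.t();  // rows x cols
    // col2im scatter-add into gx
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dz = 0; dz < k; ++dz) {
        for (int dy = 0; dy < k; ++dy) {
          for (int dx = 0; dx < k; ++dx) {
            const int col = dx + k * (dy + k * (dz + k * ci));
            const double* pcol = GP.colptr(col);
            for (int z = z0; z < z1; ++z) {
              const int sz = z + dz - pad;
              if (sz < 0 || sz >= Z) continue;
              for (int y = 0; y < Y; ++y) {
                const int sy = y + dy - pad;
                if (sy < 0 || sy >= Y) continue;
                int xlo = pad - dx; if (xlo < 0) xlo = 0;
                int xhi = X + pad - dx; if (xhi > X) xhi = X;
                if (xlo >= xhi) continue;
                double* dst = gx.begin() + idx4(xlo + dx - pad, sy, sz, ci, X, Y, Z);
                const double* src = pcol + xlo +
                  (long long)X * (y + (long long)Y * (z - z0));
                for (int i = 0; i < xhi - xlo; ++i) dst[i] += src[i];
              }
            }
          }
        }
      }
    }
  }
  NumericVector gwv(w.size()), gbv(cout);
  std::memcpy(gwv.begin(), GW.memptr(), sizeof(double) * GW.n_elem);
  std::memcpy(gbv.begin(), GB.memptr(), sizeof(double) * cout);
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Max pooling over cubic windows; returns pooled values and 0-based argmax
// linear indices into the input for the backward pass.
// [[Rcpp::export]]
List maxpool3d_fw_cpp(NumericVector x, IntegerVector dims,
                      int size, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X + 2 * pad - size) / stride + 1;
  const int Yo = (Y + 2 * pad - size) / stride + 1;
  const int Zo = (Z + 2 * pad - size) / stride + 1;
  NumericVector y((long long)Xo * Yo * Zo * C);
  NumericVector idx(y.size());
  long long o = 0;
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          long long bi = -1;
          for (int dz = 0; dz < size; ++dz) {
            const int sz = zo * stride + dz - pad;
            if (sz < 0 || sz >= Z) continue;
            for (int dy = 0; dy < size; ++dy) {
              const int sy = yo * stride + dy - pad;
              if (sy < 0 || sy >= Y) continue;
              for (int dx = 0; dx < size; ++dx) {
                const int sx = xo * stride + dx - pad;
                if (sx < 0 || sx >= X) continue;
                const long long ii = idx4(sx, sy, sz, c, X, Y, Z);
                if (x[ii] > best) { best = x[ii]; bi = ii; }
              }
            }
          }
          y[o] = best;
          idx[o] = (double)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["ydim"] = IntegerVector::create(Xo, Yo, Zo, C));
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw_cpp(NumericVector idx, NumericVector gy,
                               double xlen) {
  NumericVector gx((long long)xlen);
  for (long long i = 0; i < gy.size(); ++i)
    gx[(long long)idx[i]] += gy[i];
  return gx;
}

// Transposed convolution, kernel 2, stride 2 (windows do not overlap).
// [[Rcpp::export]]
NumericVector tconv3d_fw_cpp(NumericVector x, IntegerVector dims,
                             NumericVector w, int cout, NumericVector bias) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((long long)Xo * Yo * Zo * cout);
  for (int co = 0; co < cout; ++co) {
    double* yc = y.begin() + (long long)Xo * Yo * Zo * co;
    const double b = bias[co];
    for (long long i = 0; i < (long long)Xo * Yo * Zo; ++i) yc[i] = b;
  }
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv = w[dx + 2 * (dy + 2 * (dz + 2 * (ci + Cin * co)))];
            for (int z = 0; z < Z; ++z)
              for (int yy = 0; yy < Y; ++yy) {
                const double* xr = x.begin() + idx4(0, yy, z, ci, X, Y, Z);
                double* yr = y.begin() +
                  idx4(dx, 2 * yy + dy, 2 * z + dz, co, Xo, Yo, Zo);
                for (int xx = 0; xx < X; ++xx) yr[2 * xx] += wv * xr[xx];
              }
          }
  return y;
}

// [[Rcpp::export]]
List tconv3d_bw_cpp(NumericVector x, IntegerVector dims,
                    NumericVector w, int cout, NumericVector gy) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector gx(x.size()), gw(w.size()), gb(cout);
  for (int co = 0; co < cout; ++co) {
    const double* gc = gy.begin() + (long long)Xo * Yo * Zo * co;
    double s = 0;
    for (long long i = 0; i < (long long)Xo * Yo * Zo; ++i) s += gc[i];
    gb[co] = s;
  }
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const int wi = dx + 2 * (dy + 2 * (dz + 2 * (ci + Cin * co)));
            const double wv = w[wi];
            double acc = 0;
            for (int z = 0; z < Z; ++z)
              for (int yy = 0; yy < Y; ++yy) {
                const double* xr = x.begin() + idx4(0, yy, z, ci, X, Y, Z);
                const double* gr = gy.begin() +
                  idx4(dx, 2 * yy + dy, 2 * z + dz, co, Xo, Yo, Zo);
                double* gxr = gx.begin() + idx4(0, yy, z, ci, X, Y, Z);
                for (int xx = 0; xx < X; ++xx) {
                  const double g = gr[2 * xx];
                  acc += g * xr[xx];
                  gxr[xx] += wv * g;
                }
              }
            gw[wi] = acc;
          }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Connected-component labeling of a binary volume (6/18/26-connectivity),
// labels assigned in voxel scan order starting at 1.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims,
                           int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector lab((long long)X * Y * Z);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < lab.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const long long v = stack.back();
      stack.pop_back();
      const int x = v % X, y = (v / X) % Y, z = v / ((long long)X * Y);
      for (const auto& d : nb) {
        const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
          continue;
        const long long u = nx + (long long)X * (ny + (long long)Y * nz);
        if (mask[u] && !lab[u]) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}
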