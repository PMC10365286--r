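// Neural-network primitives for desk-scale CPU training.
//
// Tensor layout: a feature map is an R numeric array with dim = (nz, ny, nx, C),
// column-major, so the flat index is  z + nz*(y + ny*(x + nx*c)).
// Convolutions are cubic (k x k x k), zero-padded, implemented as
// im2col + GEMM chunked over x-planes so the column matrix stays small.
// Column ordering within a patch: kk = dz + k*(dy + k*(dx + k*cin)); the
// weight matrix is (Cout x Cin*k^3) with matching column order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// gather one chunk of output x-planes into a column matrix (K x ncols)
static void im2col_chunk(const double* x, int nz, int ny, int nx, int C,
                         int k, int s, int p,
                         int nzo, int nyo, int x0, int x1, arma::mat& col) {
  const int K = C * k * k * k;
  const long V = (long)nz * ny * nx;
  long j = 0;
  for (int xo = x0; xo < x1; ++xo) {
    for (int yo = 0; yo < nyo; ++yo) {
      for (int zo = 0; zo < nzo; ++zo, ++j) {
        double* cj = col.colptr(j);
        int zi0 = zo * s - p, yi0 = yo * s - p, xi0 = xo * s - p;
        int kk = 0;
        for (int cin = 0; cin < C; ++cin) {
          const double* xc = x + (long)cin * V;
          for (int dx = 0; dx < k; ++dx) {
            int xi = xi0 + dx;
            bool xok = xi >= 0 && xi < nx;
            for (int dy = 0; dy < k; ++dy) {
              int yi = yi0 + dy;
              bool yok = yi >= 0 && yi < ny;
              const double* base = xc + ((long)xi * ny + yi) * nz;
              for (int dz = 0; dz < k; ++dz, ++kk) {
                int zi = zi0 + dz;
                cj[kk] = (xok && yok && zi >= 0 && zi < nz) ? base[zi] : 0.0;
              }
            }
          }
        }
        (void)K;
      }
    }
  }
}

static int planes_per_chunk(int K, int nzo, int nyo) {
  double per_plane = (double)K * nzo * nyo;       // doubles per x-plane
  int np = (int)std::max(1.0, std::floor(8.0e6 / std::max(per_plane, 1.0)));
  return np;
}

// [[Rcpp::export]]
List cpp_conv3d_fwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector b, int k, int s, int p) {
  int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3];
  int nzo = out_dim(nz, k, s, p), nyo = out_dim(ny, k, s, p),
      nxo = out_dim(nx, k, s, p);
  int Cout = Wm.nrow();
  int K = C * k * k * k;
  if (Wm.ncol() != K) stop("weight shape mismatch");
  arma::mat W(Wm.begin(), Cout, K, false);
  long Vo = (long)nzo * nyo * nxo;
  NumericVector y(Vo * Cout);
  double* yp = y.begin();
  int np = planes_per_chunk(K, nzo, nyo);
  arma::mat col;
  for (int x0 = 0; x0 < nxo; x0 += np) {
    int x1 = std::min(nxo, x0 + np);
    long ncols = (long)(x1 - x0) * nyo * nzo;
    col.set_size(K, ncols);
    im2col_chunk(x.begin(), nz, ny, nx, C, k, s, p, nzo, nyo, x0, x1, col);
    arma::mat out = W * col;                       // Cout x ncols
    long off = (long)x0 * nyo * nzo;
    for (int co = 0; co < Cout; ++co) {
      double* dst = yp + (long)co * Vo + off;
      const double bco = b[co];
      for (long j = 0; j < ncols; ++j) dst[j] = out(co, j) + bco;
    }
  }
  y.attr("dim") = IntegerVector::create(nzo, nyo, nxo, Cout);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector gy, int k, int s, int p) {
  int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3];
  int nzo = out_dim(nz, k, s, p), nyo = out_dim(ny, k, s, p),
      nxo = out_dim(nx, k, s, p);
  int Cout = Wm.nrow();
  int K = C * k * k * k;
  arma::mat W(Wm.begin(), Cout, K, false);
  long Vo = (long)nzo * nyo * nxo;
  long V = (long)nz * ny * nx;
  NumericVector gx(V * C);
  NumericMatrix gWm(Cout, K);
  arma::mat gW(gWm.begin(), Cout, K, false);
  NumericVector gb(Cout);
  const double* gyp = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    const double* g = gyp + (long)co * Vo;
    for (long j = 0; j < Vo; ++j) acc += g[j];
    gb[co] = acc;
  }
  int np = planes_per_chunk(K, nzo, nyo);
  arma::mat col, gchunk;
  for (int x0 = 0; x0 < nxo; x0 += np) {
    int x1 = std::min(nxo, x0 + np);
    long ncols = (long)(x1 - x0) * nyo * nzo;
    col.set_size(K, ncols);
    im2col_chunk(x.begin(), nz, ny, nx, C, k, s, p, nzo, nyo, x0, x1, col);
    gchunk.set_size(Cout, ncols);
    long off = (long)x0 * nyo * nzo;
    for (int co = 0; co < Cout; ++co) {
      const double* g = gyp + (long)co * Vo + off;
      for (long j = 0; j < ncols; ++j) gchunk(co, j) = g[j];
    }
    gW += gchunk * col.t();
    arma::mat gcol = W.t() * gchunk;               // K x ncols, scatter-add
    long j = 0;
    for (int xo = x0; xo < x1; ++xo) {
      for (int yo = 0; yo < nyo; ++yo) {
        for (int zo = 0; zo < nzo; ++zo, ++j) {
          const double* cj = gcol.colptr(j);
          int zi0 = zo * s - p, yi0 = yo * s - p, xi0 = xo * s - p;
          int kk = 0;
          for (int cin = 0; cin < C; ++cin) {
            double* xc = gx.begin() + (long)cin * V;
            for (int dx = 0; dx < k; ++dx) {
              int xi = xi0 + dx;
              bool xok = xi >= 0 && xi < nx;
              for (int dy = 0; dy < k; ++dy) {
                int yi = yi0 + dy;
                bool yok = yi >= 0 && yi < ny;
                double* base = xc + ((long)xi * ny + yi) * nz;
                for (int dz = 0; dz < k; ++dz, ++kk) {
                  int zi = zi0 + dz;
                  if (xok && yok && zi >= 0 && zi < nz) base[zi] += cj[kk];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nz, ny, nx, C);
  return List::create(_["gx"] = gx, _["gW"] = gWm, _["gb"] = gb);
}

// Transposed convolution restricted to kernel 2, stride 2 (exact 2x upsample).
// Weight matrix layout: (Cout*8 x Cin), row index = cout + Cout*(dz + 2*(dy + 2*dx)).
// [[Rcpp::export]]
List cpp_convt3d_fwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                     NumericVector b) {
  int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3];
  int Cout = Wm.nrow() / 8;
  arma::mat W(Wm.begin(), Cout * 8, C, false);
  long V = (long)nz * ny * nx;
  arma::mat X(x.begin(), V, C, false);             // V x Cin (channel-major cols)
  arma::mat out = X * W.t();                       // V x Cout*8
  int nzo = nz * 2, nyo = ny * 2, nxo = nx * 2;
  long Vo = (long)nzo * nyo * nxo;
  NumericVector y(Vo * Cout);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + (long)co * Vo;
    double bco = b[co];
    for (long j = 0; j < Vo; ++j) yc[j] = bco;
  }
  long j = 0;
  for (int xi = 0; xi < nx; ++xi)
    for (int yi = 0; yi < ny; ++yi)
      for (int zi = 0; zi < nz; ++zi, ++j) {
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              long o = (long)(2 * zi + dz) +
                       (long)nzo * ((2 * yi + dy) + (long)nyo * (2 * xi + dx));
              int rbase = dz + 2 * (dy + 2 * dx);
              for (int co = 0; co < Cout; ++co)
                yp[(long)co * Vo + o] += out(j, co + Cout * rbase);
            }
      }
  y.attr("dim") = IntegerVector::create(nzo, nyo, nxo, Cout);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                     NumericVector gy) {
  int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3];
  int Cout = Wm.nrow() / 8;
  arma::mat W(Wm.begin(), Cout * 8, C, false);
  int nzo = nz * 2, nyo = ny * 2, nxo = nx * 2;
  long V = (long)nz * ny * nx;
  long Vo = (long)nzo * nyo * nxo;
  // gather gy into (V x Cout*8)
  arma::mat G(V, Cout * 8);
  const double* gyp = gy.begin();
  long j = 0;
  for (int xi = 0; xi < nx; ++xi)
    for (int yi = 0; yi < ny; ++yi)
      for (int zi = 0; zi < nz; ++zi, ++j) {
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              long o = (long)(2 * zi + dz) +
                       (long)nzo * ((2 * yi + dy) + (long)nyo * (2 * xi + dx));
              int rbase = dz + 2 * (dy + 2 * dx);
              for (int co = 0; co < Cout; ++co)
                G(j, co + Cout * rbase) = gyp[(long)co * Vo + o];
            }
      }
  arma::mat X(x.begin(), V, C, false);
  arma::mat gWa = G.t() * X;                       // (Cout*8) x Cin
  arma::mat gXa = G * W;                           // V x Cin
  NumericVector gx(V * C);
  std::copy(gXa.begin(), gXa.end(), gx.begin());
  gx.attr("dim") = IntegerVector::create(nz, ny, nx, C);
  NumericMatrix gWm(Cout * 8, C);
  std::copy(gWa.begin(), gWa.end(), gWm.begin());
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    const double* g = gyp + (long)co * Vo;
    for (long o = 0; o < Vo; ++o) acc += g[o];
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gW"] = gWm, _["gb"] = gb);
}

// Non-overlapping max pooling with per-axis window (kz,ky,kx) == stride.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector dims,
                       int kz, int ky, int kx) {
  int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3];
  int nzo = nz / kz, nyo = ny / ky, nxo = nx / kx;
  long V = (long)nz * ny * nx;
  long Vo = (long)nzo * nyo * nxo;
  NumericVector y(Vo * C);
  IntegerVector arg(Vo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * V;
    long o = (long)c * Vo;
    for (int xo = 0; xo < nxo; ++xo)
      for (int yo = 0; yo < nyo; ++yo)
        for (int zo = 0; zo < nzo; ++zo, ++o) {
          double best = -1e300; long bi = -1;
          for (int dx = 0; dx < kx; ++dx)
            for (int dy = 0; dy < ky; ++dy)
              for (int dz = 0; dz < kz; ++dz) {
                long i = (long)(zo * kz + dz) +
                         (long)nz * ((yo * ky + dy) + (long)ny * (xo * kx + dx));
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          y[o] = best;
          arg[o] = (int)((long)c * V + bi);
        }
  }
  y.attr("dim") = IntegerVector::create(nzo, nyo, nxo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector arg,
                                IntegerVector dims) {
  long V = (long)dims[0] * dims[1] * dims[2] * dims[3];
  NumericVector gx(V);
  for (long j = 0; j < (long)gy.size(); ++j) gx[arg[j]] += gy[j];
  gx.attr("dim") = dims;
  return gx;
}
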