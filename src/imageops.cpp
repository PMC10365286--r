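// Volume utilities: separable Gaussian smoothing, 3D connected components,
// box morphology, trilinear resampling, bilinear 2D resize.
// Volumes are R arrays with dim = (nz, ny, nx), column-major (z fastest).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, IntegerVector dims,
                          NumericVector sigma) {
  int n[3] = {dims[0], dims[1], dims[2]};
  long V = (long)n[0] * n[1] * n[2];
  std::vector<double> a(x.begin(), x.end()), b(V);
  long stride[3] = {1, n[0], (long)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      ker[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += ker[i + r];
    }
    for (double& k : ker) k /= sum;
    long st = stride[ax];
    int len = n[ax];
    // iterate over all lines along axis ax
    long outer1 = (ax == 0) ? n[1] : n[0];
    long outer2 = (ax == 2) ? n[1] : n[2];
    long so1 = (ax == 0) ? stride[1] : stride[0];
    long so2 = (ax == 2) ? stride[1] : stride[2];
    for (long i1 = 0; i1 < outer1; ++i1)
      for (long i2 = 0; i2 < outer2; ++i2) {
        long base = i1 * so1 + i2 * so2;
        for (int j = 0; j < len; ++j) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int jj = j + t;
            if (jj < 0) jj = 0;                 // replicate border
            if (jj >= len) jj = len - 1;
            acc += ker[t + r] * a[base + (long)jj * st];
          }
          b[base + (long)j * st] = acc;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// 6-connected component labelling; returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long V = (long)nz * ny * nx;
  IntegerVector lab(V);
  std::vector<long> stack;
  int cur = 0;
  for (long seed = 0; seed < V; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++cur;
    lab[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      long i = stack.back();
      stack.pop_back();
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((long)nz * ny));
      const int dz[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int z2 = z + dz[d], y2 = y + dy[d], x2 = x + dx[d];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        long j = z2 + (long)nz * (y2 + (long)ny * x2);
        if (mask[j] && !lab[j]) {
          lab[j] = cur;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// box dilation (op=1) / erosion (op=0) with radius r (cube of side 2r+1)
// [[Rcpp::export]]
IntegerVector cpp_morph3d(IntegerVector mask, IntegerVector dims, int r,
                          int op) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long V = (long)nz * ny * nx;
  IntegerVector out(V);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int hit = op ? 0 : 1;
        for (int dx = -r; dx <= r && (op ? !hit : hit); ++dx) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) { if (!op) hit = 0; continue; }
          for (int dy = -r; dy <= r && (op ? !hit : hit); ++dy) {
            int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) { if (!op) hit = 0; continue; }
            for (int dz = -r; dz <= r && (op ? !hit : hit); ++dz) {
              int z2 = z + dz;
              if (z2 < 0 || z2 >= nz) { if (!op) hit = 0; continue; }
              int v = mask[z2 + (long)nz * (y2 + (long)ny * x2)];
              if (op && v) hit = 1;
              if (!op && !v) hit = 0;
            }
          }
        }
        out[z + (long)nz * (y + (long)ny * x)] = hit;
      }
  out.attr("dim") = dims;
  return out;
}

// trilinear resampling: output voxel i maps to input coordinate i*ratio,
// clamped to the grid (border replication beyond the last voxel centre)
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector dims,
                             IntegerVector odims, NumericVector ratio,
                             int nearest) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int mz = odims[0], my = odims[1], mx = odims[2];
  NumericVector out((long)mz * my * mx);
  const double* xp = x.begin();
  long o = 0;
  for (int xo = 0; xo < mx; ++xo) {
    double fx = std::min(std::max(xo * ratio[2], 0.0), (double)(nx - 1));
    int x0 = (int)fx, x1 = std::min(x0 + 1, nx - 1);
    double wx = fx - x0;
    for (int yo = 0; yo < my; ++yo) {
      double fy = std::min(std::max(yo * ratio[1], 0.0), (double)(ny - 1));
      int y0 = (int)fy, y1 = std::min(y0 + 1, ny - 1);
      double wy = fy - y0;
      for (int zo = 0; zo < mz; ++zo, ++o) {
        double fz = std::min(std::max(zo * ratio[0], 0.0), (double)(nz - 1));
        int z0 = (int)fz, z1 = std::min(z0 + 1, nz - 1);
        double wz = fz - z0;
        if (nearest) {
          int zi = (int)std::lround(fz), yi = (int)std::lround(fy),
              xi = (int)std::lround(fx);
          out[o] = xp[zi + (long)nz * (yi + (long)ny * xi)];
          continue;
        }
        double v = 0.0;
        for (int dx = 0; dx < 2; ++dx) {
          int xi = dx ? x1 : x0;
          double ax = dx ? wx : 1 - wx;
          if (ax == 0) continue;
          for (int dy = 0; dy < 2; ++dy) {
            int yi = dy ? y1 : y0;
            double ay = dy ? wy : 1 - wy;
            if (ay == 0) continue;
            for (int dz = 0; dz < 2; ++dz) {
              int zi = dz ? z1 : z0;
              double az = dz ? wz : 1 - wz;
              if (az == 0) continue;
              v += ax * ay * az * xp[zi + (long)nz * (yi + (long)ny * xi)];
            }
          }
        }
        out[o] = v;
      }
    }
  }
  out.attr("dim") = odims;
  return out;
}

// bilinear resize of a 2D image (rows x cols), align-corners mapping
// [[Rcpp::export]]
NumericMatrix cpp_resize2d(NumericMatrix img, int oh, int ow) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(oh, ow);
  double ry = (oh > 1) ? (double)(h - 1) / (oh - 1) : 0.0;
  double rx = (ow > 1) ? (double)(w - 1) / (ow - 1) : 0.0;
  for (int j = 0; j < ow; ++j) {
    double fx = j * rx;
    int x0 = (int)fx, x1 = std::min(x0 + 1, w - 1);
    double wx = fx - x0;
    for (int i = 0; i < oh; ++i) {
      double fy = i * ry;
      int y0 = (int)fy, y1 = std::min(y0 + 1, h - 1);
      double wy = fy - y0;
      out(i, j) = (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x1)) +
                  wy * ((1 - wx) * img(y1, x0) + wx * img(y1, x1));
    }
  }
  return out;
}
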