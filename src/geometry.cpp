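// Geometry kernels: anisotropic Euclidean distance transform (squared,
// separable lower-envelope algorithm), 3D connected-component labelling
// (6-connectivity), and affine grid resampling (trilinear / nearest).
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const double INF = 1e30;

// 1D squared distance transform on a sampled line with sample spacing s.
static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    double fq = f[q];
    while (true) {
      double pp = (double)v[k] * s;
      double sep = (fq + qq * qq - f[v[k]] - pp * pp) / (2 * qq - 2 * pp);
      if (sep <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sep;
      z[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (z[k + 1] < qq) ++k;
    double pp = (double)v[k] * s;
    d[q] = (qq - pp) * (qq - pp) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every foreground voxel to the
// nearest background voxel; background voxels get 0. Voxels outside the
// grid are treated as background (distance measured to the grid edge).
// [[Rcpp::export(rng = false)]]
NumericVector edt3d_sq(LogicalVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  int X = dm[0], Y = dm[1], Z = dm[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out((size_t)X * Y * Z);
  out.attr("dim") = dm;
  double* o = out.begin();
  // init: 0 at background, INF at foreground, then pass along x
  std::vector<double> f(std::max(std::max(X, Y), Z)),
      d(std::max(std::max(X, Y), Z));
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      size_t base = (size_t)z * X * Y + (size_t)y * X;
      for (int x = 0; x < X; ++x) f[x] = mask[base + x] ? INF : 0.0;
      dt1d(f.data(), d.data(), X, sx);
      for (int x = 0; x < X; ++x) {
        // outside-grid background: cap by distance to x edges
        double edge = std::min((x + 1) * sx, (X - x) * sx);
        o[base + x] = mask[base + x] ? std::min(d[x], edge * edge) : 0.0;
      }
    }
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      size_t base = (size_t)z * X * Y + x;
      for (int y = 0; y < Y; ++y) f[y] = o[base + (size_t)y * X];
      dt1d(f.data(), d.data(), Y, sy);
      for (int y = 0; y < Y; ++y) {
        double edge = std::min((y + 1) * sy, (Y - y) * sy);
        o[base + (size_t)y * X] = std::min(d[y], edge * edge);
      }
    }
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      size_t base = (size_t)y * X + x;
      for (int z = 0; z < Z; ++z) f[z] = o[base + (size_t)z * X * Y];
      dt1d(f.data(), d.data(), Z, sz);
      for (int z = 0; z < Z; ++z) {
        double edge = std::min((z + 1) * sz, (Z - z) * sz);
        o[base + (size_t)z * X * Y] = std::min(d[z], edge * edge);
      }
    }
  return out;
}

// Label connected components of a logical 3D array (6-connectivity).
// Returns an integer array with labels 1..K in first-encounter order.
// [[Rcpp::export(rng = false)]]
IntegerVector label_components(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  int X = dm[0], Y = dm[1], Z = dm[2];
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = dm;
  int next = 0;
  std::queue<size_t> q;
  const size_t XY = (size_t)X * Y;
  for (size_t i = 0, n = mask.size(); i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      size_t v = q.front();
      q.pop();
      int x = v % X, y = (v / X) % Y, z = v / XY;
      const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (auto& o : nb) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
          continue;
        size_t w = (size_t)nz * XY + (size_t)ny * X + nx;
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// Resample x onto an output grid: input voxel coords of output voxel
// (i,j,k) (0-based) are A %*% c(i,j,k,1) with A a 3x4 matrix. mode 0 =
// trilinear (constant 0 outside), mode 1 = nearest neighbour. With
// clamp = 1 coordinates are clamped to the grid (edge replication) —
// the right behaviour for spacing changes, while rigid-motion copies
// want the zero border.
// [[Rcpp::export(rng = false)]]
NumericVector resample_affine(NumericVector x, IntegerVector out_dim,
                              NumericMatrix A, int mode, int clamp = 0) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("x must be a 3D array");
  int X = dm[0], Y = dm[1], Z = dm[2];
  int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector out((size_t)Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  const double* xp = x.begin();
  const size_t XY = (size_t)X * Y;
  size_t o = 0;
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i, ++o) {
        double u = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double v = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double w = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        if (clamp) {
          u = std::min(std::max(u, 0.0), (double)(X - 1));
          v = std::min(std::max(v, 0.0), (double)(Y - 1));
          w = std::min(std::max(w, 0.0), (double)(Z - 1));
        }
        if (mode == 1) {
          long xi = std::lround(u), yi = std::lround(v), zi = std::lround(w);
          if (xi < 0 || xi >= X || yi < 0 || yi >= Y || zi < 0 || zi >= Z)
            out[o] = 0;
          else
            out[o] = xp[(size_t)zi * XY + (size_t)yi * X + xi];
        } else {
          int x0 = (int)std::floor(u), y0 = (int)std::floor(v),
              z0 = (int)std::floor(w);
          double tx = u - x0, ty = v - y0, tz = w - z0;
          double acc = 0;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = z0 + dz;
            double wz = dz ? tz : 1 - tz;
            if (zi < 0 || zi >= Z || wz == 0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = y0 + dy;
              double wy = dy ? ty : 1 - ty;
              if (yi < 0 || yi >= Y || wy == 0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                int xi = x0 + dx;
                double wx = dx ? tx : 1 - tx;
                if (xi < 0 || xi >= X || wx == 0) continue;
                acc += wz * wy * wx * xp[(size_t)zi * XY + (size_t)yi * X + xi];
              }
            }
          }
          out[o] = acc;
        }
      }
  return out;
}
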