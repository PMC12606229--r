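#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Run length of a ray: number of consecutive steps k = 1..cap for which
// start + k*gen stays inside the grid AND on foreground. 0-based start.
static inline int run_length(const int *mask, int nx, int ny, int nz,
                             int x, int y, int z,
                             int gx, int gy, int gz, int cap) {
  int r = 0;
  for (int k = 1; k <= cap; ++k) {
    x += gx; y += gy; z += gz;
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) break;
    if (!mask[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)]) break;
    ++r;
  }
  return r;
}

// [[Rcpp::export]]
int ray_run_length_cpp(IntegerVector mask, IntegerVector dims,
                       IntegerVector start, IntegerVector gen, int cap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *m = mask.begin();
  int x = start[0], y = start[1], z = start[2];
  if (!m[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)])
    stop("ray_run_length: start voxel is background");
  return run_length(m, nx, ny, nz, x, y, z, gen[0], gen[1], gen[2], cap);
}

// Minimum chord thickness per foreground voxel. axes: m x 3 integer matrix
// of antipodal-reduced generators. chord = (r+ + r- + 1) * |g| * s.
// [[Rcpp::export]]
NumericVector thickness_field_cpp(IntegerVector mask, IntegerVector dims,
                                  IntegerMatrix axes, int cap, double s) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int na = axes.nrow();
  const int *m = mask.begin();
  std::vector<int> gx(na), gy(na), gz(na);
  std::vector<double> gn(na);
  for (int a = 0; a < na; ++a) {
    gx[a] = axes(a, 0); gy[a] = axes(a, 1); gz[a] = axes(a, 2);
    gn[a] = std::sqrt((double)(gx[a] * gx[a] + gy[a] * gy[a] + gz[a] * gz[a]));
  }
  // axes sorted by norm ascending allows early exit once the current minimum
  // cannot be undercut by any remaining axis (whose chord is >= |g| * s)
  std::vector<int> ord(na);
  for (int a = 0; a < na; ++a) ord[a] = a;
  std::sort(ord.begin(), ord.end(),
            [&gn](int i, int j) { return gn[i] < gn[j]; });
  NumericVector out((R_xlen_t)nx * ny * nz);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (!m[idx]) { out[idx] = 0.0; continue; }
        double best = R_PosInf;
        for (int ai = 0; ai < na; ++ai) {
          int a = ord[ai];
          if (gn[a] * s >= best) break;  // minimal possible chord on this axis
          int rp = run_length(m, nx, ny, nz, x, y, z, gx[a], gy[a], gz[a], cap);
          int rm = run_length(m, nx, ny, nz, x, y, z, -gx[a], -gy[a], -gz[a], cap);
          double chord = (rp + rm + 1) * gn[a] * s;
          if (chord < best) best = chord;
        }
        out[idx] = best;
      }
  return out;
}

// Per-voxel orientation tensors from run-length-weighted scan rays.
// dirs: m x 3 unreduced generators. For direction i with unit vector d_i,
// r_i = 1 + run_length (the centre voxel counted once per ray) and
// A = sum_i r_i^2 d_i d_i^T. Output: 6 components per voxel in NIFTI
// lower-triangle order (a11, a21, a22, a31, a32, a33); background -> 0.
// [[Rcpp::export]]
NumericVector tensor_field_cpp(IntegerVector mask, IntegerVector dims,
                               IntegerMatrix dirs, int cap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = dirs.nrow();
  const int *m = mask.begin();
  std::vector<int> gx(nd), gy(nd), gz(nd);
  std::vector<double> ux(nd), uy(nd), uz(nd);
  for (int i = 0; i < nd; ++i) {
    gx[i] = dirs(i, 0); gy[i] = dirs(i, 1); gz[i] = dirs(i, 2);
    double n = std::sqrt((double)(gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i]));
    ux[i] = gx[i] / n; uy[i] = gy[i] / n; uz[i] = gz[i] / n;
  }
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)(nvox * 6));
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (!m[idx]) continue;
        double a11 = 0, a21 = 0, a22 = 0, a31 = 0, a32 = 0, a33 = 0;
        for (int i = 0; i < nd; ++i) {
          double r = 1.0 + run_length(m, nx, ny, nz, x, y, z,
                                      gx[i], gy[i], gz[i], cap);
          double w = r * r;
          a11 += w * ux[i] * ux[i];
          a21 += w * uy[i] * ux[i];
          a22 += w * uy[i] * uy[i];
          a31 += w * uz[i] * ux[i];
          a32 += w * uz[i] * uy[i];
          a33 += w * uz[i] * uz[i];
        }
        out[idx] = a11;
        out[idx + nvox] = a21;
        out[idx + 2 * nvox] = a22;
        out[idx + 3 * nvox] = a31;
        out[idx + 4 * nvox] = a32;
        out[idx + 5 * nvox] = a33;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 6);
  return out;
}

// 26-connected component labelling of a binary grid (iterative flood fill).
// [[Rcpp::export]]
IntegerVector connected_components_26(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  const int *m = mask.begin();
  IntegerVector lab((R_xlen_t)nvox);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t seed = 0; seed < nvox; ++seed) {
    if (!m[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            size_t w = (size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * zz);
            if (m[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
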