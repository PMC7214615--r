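#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Column-major linear index for a (nx, ny, nz) array, 0-based coordinates.
static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Gray-level co-occurrence counts restricted to in-mask voxel pairs.
// levels: integer gray levels in [1, nbins] (values outside the mask are
// ignored); offsets: ndir x 3 integer matrix of voxel displacements.
// Returns an nbins x nbins x ndir array of symmetric pair counts: each
// ordered pair (v, v+d) with both ends in the mask adds one count at
// (i, j) and one at (j, i).
// [[Rcpp::export]]
IntegerVector cpp_glcm_counts(IntegerVector levels, LogicalVector mask,
                              IntegerVector dims, int nbins,
                              IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ndir = offsets.nrow();
  IntegerVector out(nbins * nbins * ndir);
  for (int d = 0; d < ndir; ++d) {
    const int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    int *slab = INTEGER(out) + (R_xlen_t)d * nbins * nbins;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = lin(x, y, z, nx, ny);
          if (!mask[a]) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          const int b = lin(x2, y2, z2, nx, ny);
          if (!mask[b]) continue;
          const int i = levels[a] - 1, j = levels[b] - 1;
          slab[i + nbins * j] += 1;
          slab[j + nbins * i] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(nbins, nbins, ndir);
  return out;
}

// Gray-level run-length counts. A run is a maximal streak of consecutive
// in-mask voxels with equal level along one direction; leaving the mask or
// the volume terminates the run. Returns nbins x maxlen x ndir counts
// (runs longer than maxlen are tallied at maxlen, callers size maxlen to
// the volume diagonal so this never triggers in practice).
// [[Rcpp::export]]
IntegerVector cpp_glrlm_counts(IntegerVector levels, LogicalVector mask,
                               IntegerVector dims, int nbins, int maxlen,
                               IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ndir = offsets.nrow();
  IntegerVector out(nbins * maxlen * ndir);
  for (int d = 0; d < ndir; ++d) {
    const int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    int *slab = INTEGER(out) + (R_xlen_t)d * nbins * maxlen;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = lin(x, y, z, nx, ny);
          if (!mask[a]) continue;
          const int lev = levels[a];
          // run start: predecessor out of volume, out of mask, or different
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, nx, ny, nz)) {
            const int p = lin(xp, yp, zp, nx, ny);
            if (mask[p] && levels[p] == lev) continue;
          }
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (inside(xc, yc, zc, nx, ny, nz)) {
            const int c = lin(xc, yc, zc, nx, ny);
            if (!mask[c] || levels[c] != lev) break;
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          if (len > maxlen) len = maxlen;
          slab[(lev - 1) + nbins * (len - 1)] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(nbins, maxlen, ndir);
  return out;
}

// Connected-component labels of a binary volume under 26-connectivity.
// Labels are 1..k in discovery order (raster scan), 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        const int s = lin(x0, y0, z0, nx, ny);
        if (!mask[s] || lab[s] != 0) continue;
        lab[s] = ++next;
        q.push(s);
        while (!q.empty()) {
          const int v = q.front(); q.pop();
          const int z = v / (nx * ny), r = v % (nx * ny);
          const int y = r / nx, x = r % nx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                const int w = lin(x2, y2, z2, nx, ny);
                if (mask[w] && lab[w] == 0) {
                  lab[w] = next;
                  q.push(w);
                }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Maximum pairwise Euclidean distance between rows of a coordinate matrix
// (points in mm). Used for the maximum 3D diameter on surface voxels.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double d = coords(i, k) - coords(j, k);
        s += d * d;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
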