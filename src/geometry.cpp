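#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Trilinear interpolation of a 3D field at arbitrary physical points.
// values: column-major array of dim (nx, ny, nz); node i sits at
// origin + (i-1) * spacing. Points outside the node hull return NA.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector values, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  NumericVector out(np);
  const double *v = values.begin();
  for (int p = 0; p < np; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[p] = NA_REAL;
      continue;
    }
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i >= nx - 1) i = nx - 2; if (i < 0) i = 0;
    if (j >= ny - 1) j = ny - 2; if (j < 0) j = 0;
    if (k >= nz - 1) k = nz - 2; if (k < 0) k = 0;
    double tx = fx - i, ty = fy - j, tz = fz - k;
    // degenerate single-slab axes
    if (nx == 1) { i = 0; tx = 0; }
    if (ny == 1) { j = 0; ty = 0; }
    if (nz == 1) { k = 0; tz = 0; }
    const R_xlen_t sI = 1, sJ = nx, sK = (R_xlen_t)nx * ny;
    const R_xlen_t b = i * sI + j * sJ + k * sK;
    const int di = (nx > 1), dj = (ny > 1), dk = (nz > 1);
    double c000 = v[b];
    double c100 = v[b + di * sI];
    double c010 = v[b + dj * sJ];
    double c110 = v[b + di * sI + dj * sJ];
    double c001 = v[b + dk * sK];
    double c101 = v[b + di * sI + dk * sK];
    double c011 = v[b + dj * sJ + dk * sK];
    double c111 = v[b + di * sI + dj * sJ + dk * sK];
    double c00 = c000 * (1 - tx) + c100 * tx;
    double c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx;
    double c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[p] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

static inline int64_t hash_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices
  return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
         (int64_t)(iz + 1048576);
}

// Global minimum Euclidean distance between two point clouds (n x 3 each).
// Exact: queries run from the smaller cloud against a uniform hash grid over
// the larger one, with the cell size set from a cheap upper bound on the
// minimum so each query touches O(1) shells; a shell is skipped only when no
// cell in it can beat the current global best. `cell` <= 0 picks the cell
// size automatically (recommended).
// [[Rcpp::export]]
double min_pointset_distance_cpp(NumericMatrix a, NumericMatrix b, double cell) {
  if (a.nrow() == 0 || b.nrow() == 0) return NA_REAL;
  // query from the smaller set
  const NumericMatrix &qs = (a.nrow() <= b.nrow()) ? a : b;
  const NumericMatrix &ts = (a.nrow() <= b.nrow()) ? b : a;
  const int nq = qs.nrow(), nt = ts.nrow();
  if (cell <= 0) {
    // upper bound: distance from the first query point to the whole target
    double u = R_PosInf;
    for (int q = 0; q < nt; ++q) {
      double dx = qs(0, 0) - ts(q, 0), dy = qs(0, 1) - ts(q, 1),
             dz = qs(0, 2) - ts(q, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < u) u = d2;
    }
    cell = std::max(std::sqrt(u), 1e-9);
  }
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve((size_t)nt * 2);
  for (int q = 0; q < nt; ++q) {
    int ix = (int)std::floor(ts(q, 0) / cell);
    int iy = (int)std::floor(ts(q, 1) / cell);
    int iz = (int)std::floor(ts(q, 2) / cell);
    grid[hash_key(ix, iy, iz)].push_back(q);
  }
  double best = R_PosInf;
  for (int p = 0; p < nq; ++p) {
    const double px = qs(p, 0), py = qs(p, 1), pz = qs(p, 2);
    const int cx = (int)std::floor(px / cell);
    const int cy = (int)std::floor(py / cell);
    const int cz = (int)std::floor(pz / cell);
    for (int r = 0;; ++r) {
      // a cell on Chebyshev shell r is at least (r-1)*cell away from p
      if (r > 0 && (double)(r - 1) * cell > best) break;
      for (int dx = -r; dx <= r; ++dx) {
        for (int dy = -r; dy <= r; ++dy) {
          for (int dz = -r; dz <= r; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            auto it = grid.find(hash_key(cx + dx, cy + dy, cz + dz));
            if (it == grid.end()) continue;
            for (int q : it->second) {
              double ddx = px - ts(q, 0), ddy = py - ts(q, 1), ddz = pz - ts(q, 2);
              double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              if (d < best) best = d;
            }
          }
        }
      }
    }
    if (best == 0) return 0;
  }
  return best;
}

// 6-connectivity connected-component labelling of a 3D logical mask.
// Returns integer labels (0 = background), component ids ordered by first voxel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = mask.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sI = 1, sJ = nx, sK = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / sK);
      int j = (int)((cur - (R_xlen_t)k * sK) / sJ);
      int i = (int)(cur - (R_xlen_t)k * sK - (R_xlen_t)j * sJ);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t nb = ii * sI + jj * sJ + kk * sK;
        if (m[nb] && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
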