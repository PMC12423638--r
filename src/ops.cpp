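#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Column-major linear index for a (nx, ny, nz) array, 0-based.
static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Sample a 3D volume at continuous 0-based voxel coordinates.
// interp: 0 = nearest, 1 = trilinear. Out-of-grid samples return `background`.
// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector src, IntegerVector dim,
                         NumericVector xi, NumericVector yi, NumericVector zi,
                         int interp, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = xi[i], y = yi[i], z = zi[i];
    if (interp == 0) {
      const int ix = (int)std::lround(x), iy = (int)std::lround(y), iz = (int)std::lround(z);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        out[i] = background;
      } else {
        out[i] = src[lin(ix, iy, iz, nx, ny)];
      }
    } else {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[i] = background;
        continue;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
      if (x0 == nx - 1) x0--;
      if (y0 == ny - 1) y0--;
      if (z0 == nz - 1) z0--;
      const double fx = x - x0, fy = y - y0, fz = z - z0;
      double acc = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
            if (w > 0) acc += w * src[lin(x0 + dx, y0 + dy, z0 + dz, nx, ny)];
          }
      out[i] = acc;
    }
  }
  return out;
}

// Separable Gaussian smoothing with replicated (clamped) boundaries.
// sigma is in voxels per axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector src, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(src.begin(), src.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int j = -r; j <= r; ++j) { k[j + r] = std::exp(-0.5 * j * j / (s * s)); ksum += k[j + r]; }
    for (double &kv : k) kv /= ksum;
    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    const int u = (ax == 0) ? ny : nx;
    const int v = (ax == 2) ? ny : nz;
    const R_xlen_t stu = (ax == 0) ? stride[1] : stride[0];
    const R_xlen_t stv = (ax == 2) ? stride[1] : stride[2];
    for (int jv = 0; jv < v; ++jv)
      for (int ju = 0; ju < u; ++ju) {
        const R_xlen_t base = ju * stu + jv * stv;
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int j = -r; j <= r; ++j) {
            int q = p + j;
            if (q < 0) q = 0; else if (q >= len) q = len - 1;
            acc += k[j + r] * a[base + q * st];
          }
          b[base + p * st] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

static void neighbour_offsets(int conn, std::vector<std::array<int,3> > &off) {
  off.clear();
  if (conn == 6) {
    off.push_back({{1,0,0}}); off.push_back({{-1,0,0}});
    off.push_back({{0,1,0}}); off.push_back({{0,-1,0}});
    off.push_back({{0,0,1}}); off.push_back({{0,0,-1}});
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (conn == 18 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 2) continue;
          off.push_back({{dx,dy,dz}});
        }
  }
}

// Connected-component labelling of a binary mask (conn = 6 or 26).
// Components are numbered 1..k in order of their lowest linear voxel index.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<std::array<int,3> > off;
  neighbour_offsets(conn, off);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      const R_xlen_t c = stack.back(); stack.pop_back();
      const int cz = (int)(c / ((R_xlen_t)nx * ny));
      const int cy = (int)((c / nx) % ny);
      const int cx = (int)(c % nx);
      for (size_t j = 0; j < off.size(); ++j) {
        const int x = cx + off[j][0], y = cy + off[j][1], z = cz + off[j][2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        const R_xlen_t q = lin(x, y, z, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// One round of binary dilation (op = 1) or erosion (op = 0), conn = 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_morph(IntegerVector mask, IntegerVector dim, int conn, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  std::vector<std::array<int,3> > off;
  neighbour_offsets(conn, off);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = lin(x, y, z, nx, ny);
        int v = mask[i] ? 1 : 0;
        if (op == 1 && !v) {           // dilation: on if any neighbour on
          for (size_t j = 0; j < off.size() && !v; ++j) {
            const int qx = x + off[j][0], qy = y + off[j][1], qz = z + off[j][2];
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
            if (mask[lin(qx, qy, qz, nx, ny)]) v = 1;
          }
        } else if (op == 0 && v) {     // erosion: off if any neighbour off (grid edge counts as off)
          for (size_t j = 0; j < off.size() && v; ++j) {
            const int qx = x + off[j][0], qy = y + off[j][1], qz = z + off[j][2];
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) { v = 0; break; }
            if (!mask[lin(qx, qy, qz, nx, ny)]) v = 0;
          }
        }
        out[i] = v;
      }
  out.attr("dim") = dim;
  return out;
}

// Iterative nearest-label propagation (6-connected breadth-first rounds).
// Brain voxels whose label is in `fill_codes` (or 0) receive the code of the
// nearest propagating voxel; codes in `frozen_codes` keep their value and do
// not propagate. Propagation respects `hemi` (voxels only receive codes from
// voxels with the same hemisphere id). Ties within a round are broken by the
// lowest candidate code. Remaining unreached fill voxels are returned as-is.
// [[Rcpp::export]]
IntegerVector cpp_label_fill(IntegerVector labels, IntegerVector brain, IntegerVector hemi,
                             IntegerVector dim, IntegerVector fill_codes,
                             IntegerVector frozen_codes) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);
  std::vector<char> is_fill(n, 0);
  std::vector<char> frozen_set(4096, 0), fill_set(4096, 0);
  for (int i = 0; i < frozen_codes.size(); ++i)
    if (frozen_codes[i] >= 0 && frozen_codes[i] < 4096) frozen_set[frozen_codes[i]] = 1;
  for (int i = 0; i < fill_codes.size(); ++i)
    if (fill_codes[i] >= 0 && fill_codes[i] < 4096) fill_set[fill_codes[i]] = 1;
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!brain[i]) continue;
    const int c = out[i];
    if (c == 0 || fill_set[c]) { is_fill[i] = 1; }
    else if (!frozen_set[c]) frontier.push_back(i);
  }
  std::vector<std::array<int,3> > off;
  neighbour_offsets(6, off);
  std::vector<R_xlen_t> next_frontier;
  std::vector<int> cand(n, 0);
  std::vector<R_xlen_t> touched;
  while (!frontier.empty()) {
    next_frontier.clear();
    touched.clear();
    for (size_t fi = 0; fi < frontier.size(); ++fi) {
      const R_xlen_t c = frontier[fi];
      const int cz = (int)(c / ((R_xlen_t)nx * ny));
      const int cy = (int)((c / nx) % ny);
      const int cx = (int)(c % nx);
      const int code = out[c];
      for (size_t j = 0; j < off.size(); ++j) {
        const int x = cx + off[j][0], y = cy + off[j][1], z = cz + off[j][2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        const R_xlen_t q = lin(x, y, z, nx, ny);
        if (!brain[q] || !is_fill[q]) continue;
        if (hemi[q] != hemi[c]) continue;
        if (cand[q] == 0) { cand[q] = code; touched.push_back(q); }
        else if (code < cand[q]) cand[q] = code;
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      const R_xlen_t q = touched[t];
      out[q] = cand[q];
      cand[q] = 0;
      is_fill[q] = 0;
      next_frontier.push_back(q);
    }
    std::sort(next_frontier.begin(), next_frontier.end());
    frontier.swap(next_frontier);
  }
  out.attr("dim") = dim;
  return out;
}

// Directional boundary dilation: for each boundary voxel of `mask`, locate the
// nearest CSF voxel outside the mask within `maxdist` (Chebyshev metric if
// chebyshev != 0, else Euclidean) and add the voxels strictly between the two
// along the discrete 3D line segment. Returns the augmented mask.
// [[Rcpp::export]]
IntegerVector cpp_boundary_dilation(IntegerVector mask, IntegerVector csf, IntegerVector dim,
                                    int maxdist, int chebyshev) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(mask);
  // offsets sorted by (metric distance, squared euclidean, lexicographic)
  struct Off { int dx, dy, dz; double d; int e2; };
  std::vector<Off> offs;
  for (int dz = -maxdist; dz <= maxdist; ++dz)
    for (int dy = -maxdist; dy <= maxdist; ++dy)
      for (int dx = -maxdist; dx <= maxdist; ++dx) {
        if (!dx && !dy && !dz) continue;
        const int e2 = dx * dx + dy * dy + dz * dz;
        double d;
        if (chebyshev) d = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
        else d = std::sqrt((double)e2);
        if (d > maxdist + 1e-9) continue;
        offs.push_back({dx, dy, dz, d, e2});
      }
  std::stable_sort(offs.begin(), offs.end(), [](const Off &a, const Off &b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.e2 != b.e2) return a.e2 < b.e2;
    if (a.dz != b.dz) return a.dz < b.dz;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  std::vector<std::array<int,3> > face;
  neighbour_offsets(6, face);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int z = (int)(i / ((R_xlen_t)nx * ny));
    const int y = (int)((i / nx) % ny);
    const int x = (int)(i % nx);
    bool boundary = false;
    for (size_t j = 0; j < face.size() && !boundary; ++j) {
      const int qx = x + face[j][0], qy = y + face[j][1], qz = z + face[j][2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) { boundary = true; break; }
      if (!mask[lin(qx, qy, qz, nx, ny)]) boundary = true;
    }
    if (!boundary) continue;
    for (size_t j = 0; j < offs.size(); ++j) {
      const int cx = x + offs[j].dx, cy = y + offs[j].dy, cz = z + offs[j].dz;
      if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz) continue;
      const R_xlen_t q = lin(cx, cy, cz, nx, ny);
      if (!csf[q] || mask[q]) continue;
      // discrete segment from (x,y,z) to (cx,cy,cz), endpoints excluded
      const int steps = std::max(std::abs(offs[j].dx),
                        std::max(std::abs(offs[j].dy), std::abs(offs[j].dz)));
      for (int s = 1; s < steps; ++s) {
        const double t = (double)s / steps;
        const int px = (int)std::lround(x + t * offs[j].dx);
        const int py = (int)std::lround(y + t * offs[j].dy);
        const int pz = (int)std::lround(z + t * offs[j].dz);
        out[lin(px, py, pz, nx, ny)] = 1;
      }
      break;  // nearest CSF voxel only
    }
  }
  out.attr("dim") = dim;
  return out;
}
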