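// Low-level 3-D grid primitives shared by the segmentation pipeline.
// Volumes are column-major [x, y, z]; linear index = x + nx*(y + ny*z).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long long)ny * z);
}

// 6-connected neighbour offsets generated on the fly to respect bounds.

// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, rem = v / nx, y = rem % ny, z = rem / ny;
      const int nb[6][3] = {{x-1,y,z},{x+1,y,z},{x,y-1,z},{x,y+1,z},{x,y,z-1},{x,y,z+1}};
      for (int k = 0; k < 6; ++k) {
        int xx = nb[k][0], yy = nb[k][1], zz = nb[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static std::vector<std::array<int,3>> ball_offsets(double rx, double ry, double rz) {
  std::vector<std::array<int,3>> off;
  int mx = (int)std::floor(rx), my = (int)std::floor(ry), mz = (int)std::floor(rz);
  for (int dz = -mz; dz <= mz; ++dz)
    for (int dy = -my; dy <= my; ++dy)
      for (int dx = -mx; dx <= mx; ++dx) {
        double q = 0.0;
        if (rx > 0) q += (double)dx*dx/(rx*rx); else if (dx) continue;
        if (ry > 0) q += (double)dy*dy/(ry*ry); else if (dy) continue;
        if (rz > 0) q += (double)dz*dz/(rz*rz); else if (dz) continue;
        if (q <= 1.0 + 1e-9) off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export(name = ".morph_ball")]]
LogicalVector morph_ball(LogicalVector mask, IntegerVector dim,
                         NumericVector radius, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto off = ball_offsets(radius[0], radius[1], radius[2]);
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = lin(x, y, z, nx, ny);
        bool hit = dilate ? false : true;
        if (dilate) {
          // true if any neighbour in the ball is set
          for (auto &o : off) {
            int xx = x + o[0], yy = y + o[1], zz = z + o[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            if (mask[lin(xx, yy, zz, nx, ny)]) { hit = true; break; }
          }
        } else {
          // erosion: all in-bounds neighbours must be set
          for (auto &o : off) {
            int xx = x + o[0], yy = y + o[1], zz = z + o[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            if (!mask[lin(xx, yy, zz, nx, ny)]) { hit = false; break; }
          }
        }
        out[v] = hit;
      }
  return out;
}

// Separable Gaussian blur; kernel truncated at 3.5 sigma and renormalised at
// the borders so constants (and additive calibration shifts) are preserved
// exactly.
static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), outl(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      for (int i = 0; i < len; ++i) {
        int x = axis == 0 ? i : j1, y = axis == 1 ? i : (axis == 0 ? j1 : j2),
            z = axis == 2 ? i : j2;
        line[i] = v[lin(x, y, z, nx, ny)];
      }
      for (int i = 0; i < len; ++i) {
        double s = 0, w = 0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) { double kk = k[j - i + r]; s += kk * line[j]; w += kk; }
        outl[i] = s / w;
      }
      for (int i = 0; i < len; ++i) {
        int x = axis == 0 ? i : j1, y = axis == 1 ? i : (axis == 0 ? j1 : j2),
            z = axis == 2 ? i : j2;
        v[lin(x, y, z, nx, ny)] = outl[i];
      }
    }
}

// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(v.begin(), v.end());
}

// Sliding-window rank percentile of masked voxels, quantised to 1 HU bins.
// For every masked voxel, the p-th percentile (nearest-rank) of masked
// voxels within the box window of half-widths hw (voxels) centred on it.
// Windows holding fewer than min_count masked voxels fall back to
// `fallback`. The 1-HU quantisation makes the field exactly equivariant
// under integer-HU calibration shifts.
// [[Rcpp::export(name = ".local_percentile")]]
NumericVector local_percentile(NumericVector vol, LogicalVector mask,
                               IntegerVector dim, IntegerVector hw,
                               double p, int min_count, double fallback) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int OFFSET = 1500, NBIN = 5000; // HU in [-1500, 3499]
  const int NC = (NBIN + 63) / 64;      // coarse bins of 64
  const int hx = hw[0], hy = hw[1], hz = hw[2];
  NumericVector out(n, NA_REAL);

  std::vector<int> bin(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    long b = std::lround(vol[i]) + OFFSET;
    if (b < 0) b = 0; if (b >= NBIN) b = NBIN - 1;
    bin[i] = (int)b;
  }

  std::vector<int> fine(NBIN), coarse(NC);
  // does column (y,z band) contain any masked voxel? quick row skip
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      bool any = false;
      for (int x = 0; x < nx && !any; ++x) any = mask[lin(x, y, z, nx, ny)];
      if (!any) continue;
      std::fill(fine.begin(), fine.end(), 0);
      std::fill(coarse.begin(), coarse.end(), 0);
      int count = 0;
      const int ylo = std::max(0, y - hy), yhi = std::min(ny - 1, y + hy);
      const int zlo = std::max(0, z - hz), zhi = std::min(nz - 1, z + hz);
      auto add_plane = [&](int xp, int sgn) {
        if (xp < 0 || xp >= nx) return;
        for (int zz = zlo; zz <= zhi; ++zz)
          for (int yy = ylo; yy <= yhi; ++yy) {
            R_xlen_t w = lin(xp, yy, zz, nx, ny);
            if (!mask[w]) continue;
            fine[bin[w]] += sgn; coarse[bin[w] >> 6] += sgn; count += sgn;
          }
      };
      for (int xp = 0; xp <= std::min(nx - 1, hx); ++xp) add_plane(xp, +1);
      for (int x = 0; x < nx; ++x) {
        if (x > 0) { add_plane(x + hx, +1); add_plane(x - hx - 1, -1); }
        R_xlen_t v = lin(x, y, z, nx, ny);
        if (!mask[v]) continue;
        if (count < min_count) { out[v] = fallback; continue; }
        int k = (int)std::ceil(p / 100.0 * count);
        if (k < 1) k = 1;
        int cum = 0, cb = 0;
        while (cb < NC && cum + coarse[cb] < k) { cum += coarse[cb]; ++cb; }
        int fb = cb << 6;
        while (fb < NBIN && cum + fine[fb] < k) { cum += fine[fb]; ++fb; }
        out[v] = (double)(fb - OFFSET);
      }
    }
  }
  return out;
}

// Layered (breadth-first) region growing from a seed with an inclusion
// criterion vol < thr. Growth is abandoned (leaked = true) when a single
// layer multiplies the accumulated volume by more than leak_factor once the
// region already holds min_check voxels.
// [[Rcpp::export(name = ".region_grow")]]
List region_grow(NumericVector vol, IntegerVector dim, int seed, double thr,
                 double leak_factor, int min_check) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n, false);
  bool leaked = false;
  int size = 0;
  if (seed >= 0 && seed < n && vol[seed] < thr) {
    std::vector<int> frontier{seed}, next;
    mask[seed] = true; size = 1;
    while (!frontier.empty()) {
      next.clear();
      for (int v : frontier) {
        int x = v % nx, rem = v / nx, y = rem % ny, z = rem / ny;
        const int nb[6][3] = {{x-1,y,z},{x+1,y,z},{x,y-1,z},{x,y+1,z},{x,y,z-1},{x,y,z+1}};
        for (int k = 0; k < 6; ++k) {
          int xx = nb[k][0], yy = nb[k][1], zz = nb[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int w = lin(xx, yy, zz, nx, ny);
          if (!mask[w] && vol[w] < thr) { mask[w] = true; next.push_back(w); }
        }
      }
      int grown = size + (int)next.size();
      if (size >= min_check && grown > leak_factor * size) {
        leaked = true;
        break;
      }
      size = grown;
      frontier.swap(next);
    }
  }
  return List::create(_["mask"] = mask, _["leaked"] = leaked, _["size"] = size);
}
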