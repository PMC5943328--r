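#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// --- separable Gaussian smoothing --------------------------------------

// Edge handling replicates the boundary sample so structures spanning the
// domain keep full value at the faces (a spanning plate stays a plate).
static void blur_axis(std::vector<double> &a, int nx, int ny, int nz,
                      int axis, const std::vector<double> &kern) {
  const int rad = static_cast<int>(kern.size()) / 2;
  const int64_t sx = 1, sy = nx, sz = static_cast<int64_t>(nx) * ny;
  const int64_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(len);
  const int nlines_a = (axis == 0) ? ny : nx;
  const int nlines_b = (axis == 2) ? ny : nz;
  for (int b = 0; b < nlines_b; ++b) {
    for (int aidx = 0; aidx < nlines_a; ++aidx) {
      int64_t base;
      if (axis == 0) base = static_cast<int64_t>(aidx) * sy + static_cast<int64_t>(b) * sz;
      else if (axis == 1) base = static_cast<int64_t>(aidx) * sx + static_cast<int64_t>(b) * sz;
      else base = static_cast<int64_t>(aidx) * sx + static_cast<int64_t>(b) * sy;
      for (int t = 0; t < len; ++t) line[t] = a[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int q = -rad; q <= rad; ++q) {
          int s = t + q;
          if (s < 0) s = 0;
          if (s >= len) s = len - 1;
          acc += kern[q + rad] * line[s];
        }
        a[base + t * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  if (sigma > 0) {
    const int rad = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
    std::vector<double> kern(2 * rad + 1);
    double s = 0;
    for (int q = -rad; q <= rad; ++q) {
      kern[q + rad] = std::exp(-0.5 * q * q / (sigma * sigma));
      s += kern[q + rad];
    }
    for (double &w : kern) w /= s;
    for (int axis = 0; axis < 3; ++axis) blur_axis(a, nx, ny, nz, axis, kern);
  }
  NumericVector out(vol.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// --- exact squared Euclidean distance transform -------------------------

// Felzenszwalb & Huttenlocher lower-envelope scan, one axis at a time.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vtx, std::vector<double> &zbuf, int n) {
  int k = 0;
  vtx[0] = 0;
  zbuf[0] = -1e30;
  zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    int p = vtx[k];
    d[q] = (q - p) * (double)(q - p) + f[p];
  }
}

// Squared distance (voxel units) from every voxel to the nearest voxel
// where mask is FALSE (background). Mask TRUE everywhere -> +inf capped.
// [[Rcpp::export(name = ".cpp_sqedt")]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t ntot = static_cast<int64_t>(nx) * ny * nz;
  const double BIG = 1e30;
  std::vector<double> a(ntot);
  for (int64_t i = 0; i < ntot; ++i) a[i] = mask[i] ? BIG : 0.0;

  const int64_t sx = 1, sy = nx, sz = static_cast<int64_t>(nx) * ny;
  const int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxlen), d(maxlen), zbuf(maxlen + 1);
  std::vector<int> vtx(maxlen);

  struct AxisDef { int len; int64_t stride; int na; int64_t stra; int nb; int64_t strb; };
  AxisDef axes[3] = {
    {nx, sx, ny, sy, nz, sz},
    {ny, sy, nx, sx, nz, sz},
    {nz, sz, nx, sx, ny, sy}
  };
  for (const AxisDef &ax : axes) {
    for (int b = 0; b < ax.nb; ++b) {
      for (int q = 0; q < ax.na; ++q) {
        const int64_t base = q * ax.stra + b * ax.strb;
        for (int t = 0; t < ax.len; ++t) f[t] = a[base + t * ax.stride];
        dt1d(f, d, vtx, zbuf, ax.len);
        for (int t = 0; t < ax.len; ++t) a[base + t * ax.stride] = std::min(d[t], BIG);
      }
    }
  }
  NumericVector out(ntot);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// --- local thickness (largest covering sphere) --------------------------

// Hildebrand-Rueegsegger local thickness: lt(v) = diameter of the largest
// sphere fully inside the phase that covers v. Sphere radii come from the
// EDT (center-to-background distance minus half a voxel, i.e. distance to
// the phase boundary); redundant centers whose sphere lies inside a
// neighbour's sphere are pruned before painting.
// [[Rcpp::export(name = ".cpp_local_thickness")]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  double r_offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t ntot = static_cast<int64_t>(nx) * ny * nz;
  NumericVector sq = cpp_sqedt(mask, dim);
  std::vector<double> r(ntot, 0.0);
  for (int64_t i = 0; i < ntot; ++i) {
    if (mask[i]) r[i] = std::max(0.5, std::sqrt(sq[i]) - r_offset);
  }

  auto lin = [&](int x, int y, int z) {
    return static_cast<int64_t>(x) + static_cast<int64_t>(y) * nx +
           static_cast<int64_t>(z) * nx * (int64_t)ny;
  };

  // Distance-ridge filter: drop centers contained in a neighbour's sphere.
  struct Center { double r; int x, y, z; };
  std::vector<Center> centers;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int64_t i = lin(x, y, z);
    if (!mask[i]) continue;
    bool redundant = false;
    for (int dz = -1; dz <= 1 && !redundant; ++dz)
      for (int dy = -1; dy <= 1 && !redundant; ++dy)
        for (int dx = -1; dx <= 1 && !redundant; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (r[lin(xx, yy, zz)] >= r[i] + dist - 1e-9) redundant = true;
        }
    if (!redundant) centers.push_back({r[i], x, y, z});
  }
  std::sort(centers.begin(), centers.end(),
            [](const Center &a, const Center &b) { return a.r > b.r; });

  NumericVector lt(ntot);
  std::fill(lt.begin(), lt.end(), 0.0);
  for (const Center &c : centers) {
    const double rad = c.r, r2 = rad * rad, diam = 2.0 * rad;
    const int ir = static_cast<int>(std::floor(rad));
    for (int dz = -ir; dz <= ir; ++dz) {
      int zz = c.z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        int yy = c.y + dy;
        if (yy < 0 || yy >= ny) continue;
        const double dd = (double)dz * dz + (double)dy * dy;
        if (dd > r2) continue;
        const int mx = static_cast<int>(std::floor(std::sqrt(r2 - dd)));
        int x0 = std::max(0, c.x - mx), x1 = std::min(nx - 1, c.x + mx);
        int64_t row = lin(x0, yy, zz);
        for (int xx = x0; xx <= x1; ++xx, ++row) {
          if (mask[row] && lt[row] < diam) lt[row] = diam;
        }
      }
    }
  }
  lt.attr("dim") = dim;
  return lt;
}

// --- connected components (26-connectivity), largest component ----------

// [[Rcpp::export(name = ".cpp_largest_component")]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t ntot = static_cast<int64_t>(nx) * ny * nz;
  std::vector<int> label(ntot, 0);
  std::vector<int64_t> stack;
  int best_label = 0;
  int64_t best_size = 0;
  int cur = 0;
  auto lin = [&](int x, int y, int z) {
    return static_cast<int64_t>(x) + static_cast<int64_t>(y) * nx +
           static_cast<int64_t>(z) * nx * (int64_t)ny;
  };
  for (int64_t seed = 0; seed < ntot; ++seed) {
    if (!mask[seed] || label[seed]) continue;
    ++cur;
    int64_t size = 0;
    stack.push_back(seed);
    label[seed] = cur;
    while (!stack.empty()) {
      int64_t i = stack.back();
      stack.pop_back();
      ++size;
      int x = static_cast<int>(i % nx), y = static_cast<int>((i / nx) % ny),
          z = static_cast<int>(i / (static_cast<int64_t>(nx) * ny));
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          int64_t j = lin(xx, yy, zz);
          if (mask[j] && !label[j]) { label[j] = cur; stack.push_back(j); }
        }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(ntot);
  for (int64_t i = 0; i < ntot; ++i) out[i] = (label[i] == best_label);
  out.attr("dim") = dim;
  return out;
}
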