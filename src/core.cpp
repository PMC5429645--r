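#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>

using namespace Rcpp;

// One-dimensional squared Euclidean distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher) on a line with grid step `h` mm.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * h, xv = v[k] * h;
    double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
    while (s <= z[k]) {
      --k;
      xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest mask voxel.
// mask: integer volume (non-zero = feature), column-major x-fastest.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  NumericVector out(mask.size());
  // initialise: 0 at features, INF elsewhere
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] != 0 ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int z = 0; z < nz; ++z) f[z] = out[base + stride * z];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + stride * z] = d[z];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// 6-connected components of a binary mask; returns component ids (1-based,
// 0 = background) in deterministic scan order.
// [[Rcpp::export(name = ".flood_components")]]
IntegerVector flood_components(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector comp(mask.size(), 0);
  int next_id = 0;
  std::queue<R_xlen_t> q;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (mask[s] == 0 || comp[s] != 0) continue;
    comp[s] = ++next_id;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int n6 = 0; n6 < 6; ++n6) {
        int xx = x + dx[n6], yy = y + dy[n6], zz = z + dz[n6];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t ni = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[ni] != 0 && comp[ni] == 0) {
          comp[ni] = next_id;
          q.push(ni);
        }
      }
    }
  }
  return comp;
}

static inline int nearest(double w, double origin, double sp) {
  return (int)std::lround((w - origin) / sp);
}

// Trace the label sequence along the segment p0 -> p1 (world mm) with the
// given step; returns the nearest-voxel label at each step position.
// [[Rcpp::export(name = ".trace_ray")]]
IntegerVector trace_ray(IntegerVector labels, IntegerVector dims,
                        NumericVector spacing, NumericVector origin,
                        NumericVector p0, NumericVector p1, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  int nsteps = len > 0 ? (int)std::ceil(len / step) : 0;
  IntegerVector out(nsteps + 1);
  for (int i = 0; i <= nsteps; ++i) {
    double t = nsteps > 0 ? (double)i / nsteps : 0.0;
    int vx = nearest(p0[0] + t * dx, origin[0], spacing[0]);
    int vy = nearest(p0[1] + t * dy, origin[1], spacing[1]);
    int vz = nearest(p0[2] + t * dz, origin[2], spacing[2]);
    if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = labels[vx + (R_xlen_t)nx * (vy + (R_xlen_t)ny * vz)];
    }
  }
  return out;
}

// Batch candidate measurement for the path planner: for every pair of skin
// voxel and target voxel, walk the straight segment between the voxel
// centres at sub-voxel steps and record what the scoring criteria need.
// Returns a matrix with one row per (skin, target) pair (skin-major order)
// and columns: blocked (0/1: risk tissue crossed before the target was
// reached), length_mm, min_risk_dist_mm (minimum of the risk-mask distance
// transform over the walk), n_target_voxels (distinct target voxels
// visited).
// [[Rcpp::export(name = ".measure_candidates")]]
NumericMatrix measure_candidates(IntegerVector labels, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 IntegerMatrix skin, IntegerMatrix targets,
                                 LogicalVector risk_lut, int target_code,
                                 NumericVector risk_dist, double step,
                                 double max_length) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = skin.nrow(), nt = targets.nrow();
  NumericMatrix out((R_xlen_t)ns * nt, 4);
  for (int i = 0; i < ns; ++i) {
    double sx = origin[0] + skin(i, 0) * spacing[0];
    double sy = origin[1] + skin(i, 1) * spacing[1];
    double sz = origin[2] + skin(i, 2) * spacing[2];
    for (int j = 0; j < nt; ++j) {
      double tx = origin[0] + targets(j, 0) * spacing[0];
      double ty = origin[1] + targets(j, 1) * spacing[1];
      double tz = origin[2] + targets(j, 2) * spacing[2];
      double dx = tx - sx, dy = ty - sy, dz = tz - sz;
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      R_xlen_t row = (R_xlen_t)i * nt + j;
      out(row, 1) = len;
      if (len > max_length) {
        // over-length candidates fail the hard length constraint outright;
        // skip the walk
        out(row, 0) = 0;
        out(row, 2) = NA_REAL;
        out(row, 3) = 0;
        continue;
      }
      int nsteps = len > 0 ? (int)std::ceil(len / step) : 0;
      bool blocked = false, reached = false;
      double min_dist = std::numeric_limits<double>::infinity();
      int n_target = 0;
      R_xlen_t prev_idx = -1;
      for (int sdx = 0; sdx <= nsteps; ++sdx) {
        double t = nsteps > 0 ? (double)sdx / nsteps : 0.0;
        int vx = nearest(sx + t * dx, origin[0], spacing[0]);
        int vy = nearest(sy + t * dy, origin[1], spacing[1]);
        int vz = nearest(sz + t * dz, origin[2], spacing[2]);
        if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz)
          continue;
        R_xlen_t idx = vx + (R_xlen_t)nx * (vy + (R_xlen_t)ny * vz);
        int lab = labels[idx];
        if (risk_dist[idx] < min_dist) min_dist = risk_dist[idx];
        if (lab == target_code) {
          reached = true;
          if (idx != prev_idx) ++n_target;
        } else if (!reached && lab >= 0 && lab < risk_lut.size() &&
                   risk_lut[lab]) {
          blocked = true;
          break;
        }
        prev_idx = idx;
      }
      out(row, 0) = blocked ? 1.0 : 0.0;
      out(row, 2) = min_dist;
      out(row, 3) = n_target;
    }
  }
  return out;
}
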