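// Low-level 3D image primitives.
//
// All volumes are R arrays with dim = c(nz, ny, nx), i.e. voxel (z, y, x)
// sits at linear index z + nz*(y + ny*x) (0-based here, 1-based in R).
// The z axis is the fastest-varying one, matching TIFF page stacking on
// the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// half-sample reflection: ... c b a | a b c ... | c b a ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export(name = ".cpp_conv1d")]]
NumericVector cpp_conv1d(NumericVector vol, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dim;

  // stride along the convolution axis and extent of that axis
  int n_axis, stride;
  if (axis == 0)      { n_axis = nz; stride = 1; }
  else if (axis == 1) { n_axis = ny; stride = nz; }
  else                { n_axis = nx; stride = nz * ny; }

  // iterate over all lines along `axis`
  int d1, d2, s1, s2;
  if (axis == 0)      { d1 = ny; d2 = nx; s1 = nz; s2 = nz * ny; }
  else if (axis == 1) { d1 = nz; d2 = nx; s1 = 1;  s2 = nz * ny; }
  else                { d1 = nz; d2 = ny; s1 = 1;  s2 = nz;      }

  std::vector<double> line(n_axis);
  for (int i2 = 0; i2 < d2; ++i2) {
    for (int i1 = 0; i1 < d1; ++i1) {
      const int base = i1 * s1 + i2 * s2;
      for (int t = 0; t < n_axis; ++t) line[t] = vol[base + t * stride];
      for (int t = 0; t < n_axis; ++t) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int src = reflect_idx(t + k - r, n_axis);
          acc += kernel[k] * line[src];
        }
        out[base + t * stride] = acc;
      }
    }
  }
  return out;
}

// Neighbourhood offsets for a min/max filter.
// shape: 0 = ellipsoid (per-axis radii, (dz/rz)^2+(dy/ry)^2+(dx/rx)^2 <= 1,
// a zero radius collapses that axis), 1 = box (Chebyshev).
static std::vector<std::array<int, 3>> se_offsets(const IntegerVector &radii,
                                                  int shape) {
  const int rz = radii[0], ry = radii[1], rx = radii[2];
  std::vector<std::array<int, 3>> off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        if (shape == 0) {
          double v = 0.0;
          v += rz ? (double)dz * dz / ((double)rz * rz) : 0.0;
          v += ry ? (double)dy * dy / ((double)ry * ry) : 0.0;
          v += rx ? (double)dx * dx / ((double)rx * rx) : 0.0;
          if (v > 1.0 + 1e-9) continue;
        }
        off.push_back({dz, dy, dx});
      }
  return off;
}

// Binary max (dilate = true) / min (dilate = false) filter.
// Out-of-bounds voxels count as background for the max filter and as
// foreground for the min filter, so closing is extensive at the border.
// [[Rcpp::export(name = ".cpp_minmax")]]
LogicalVector cpp_minmax(LogicalVector mask, IntegerVector dim,
                         IntegerVector radii, bool dilate, int shape) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  auto off = se_offsets(radii, shape);
  LogicalVector out(mask.size());
  out.attr("dim") = dim;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool acc = dilate ? false : true;
        for (const auto &o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          bool v;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            v = dilate ? false : true;
          else
            v = mask[lin(zz, yy, xx, nz, ny)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[lin(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// Connected-component labelling, connectivity 6 or 26 (3D).
// Returns integer labels 1..k, 0 = background.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;

  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        off.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur % nz, rest = cur / nz;
      int y = rest % ny, x = rest / ny;
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = lin(zz, yy, xx, nz, ny);
        if (mask[j] && !labels[j]) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Count of foreground 26-neighbours per voxel.
// [[Rcpp::export(name = ".cpp_neighbor_count")]]
IntegerVector cpp_neighbor_count(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out(mask.size(), 0);
  out.attr("dim") = dim;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (!mask[lin(z, y, x, nz, ny)]) continue;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) continue;
              if (mask[lin(zz, yy, xx, nz, ny)]) ++cnt;
            }
        out[lin(z, y, x, nz, ny)] = cnt;
      }
  return out;
}

// ---- medial-axis thinning ------------------------------------------------
//
// Simple-point test via topological numbers (Malandain & Bertrand):
// a foreground voxel is simple iff
//   (a) the foreground restricted to its 26-neighbourhood has exactly one
//       26-connected component, and
//   (b) the background restricted to its 18-neighbourhood has exactly one
//       6-connected component that touches a face neighbour.
// Deleting simple points one at a time provably preserves the number of
// connected components, tunnels and cavities of the object.

namespace {

struct CubeTables {
  // 26 neighbour offsets (excluding center), their cube positions 0..26
  int noff[26][3];
  // 26-adjacency among the 26 neighbour slots
  std::vector<int> adj26[26];
  // 18-neighbourhood slots (subset of 0..25) and 6-adjacency among them
  bool in18[26];
  bool isface[26];
  std::vector<int> adj6[26];
  CubeTables() {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          noff[k][0] = dz; noff[k][1] = dy; noff[k][2] = dx;
          ++k;
        }
    for (int a = 0; a < 26; ++a) {
      int s = std::abs(noff[a][0]) + std::abs(noff[a][1]) + std::abs(noff[a][2]);
      in18[a] = (s <= 2);
      isface[a] = (s == 1);
    }
    for (int a = 0; a < 26; ++a) {
      for (int b = 0; b < 26; ++b) {
        if (a == b) continue;
        int dz = noff[a][0] - noff[b][0];
        int dy = noff[a][1] - noff[b][1];
        int dx = noff[a][2] - noff[b][2];
        int cheb = std::max(std::abs(dz), std::max(std::abs(dy), std::abs(dx)));
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (cheb <= 1) adj26[a].push_back(b);
        if (manh == 1 && in18[a] && in18[b]) adj6[a].push_back(b);
      }
    }
  }
};

const CubeTables &tables() {
  static CubeTables t;
  return t;
}

// nb[k]: foreground state of neighbour slot k (k = 0..25)
bool is_simple(const bool nb[26]) {
  const CubeTables &t = tables();
  // (a) one 26-component of foreground among the 26 neighbours
  int seen[26]; int nseen = 0;
  bool visited[26] = {false};
  int ncomp_fg = 0;
  for (int s = 0; s < 26; ++s) if (nb[s]) { seen[nseen++] = s; }
  if (nseen == 0) return false;  // isolated point: not simple
  for (int idx = 0; idx < nseen; ++idx) {
    int s = seen[idx];
    if (visited[s]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    // BFS
    std::vector<int> stack{s};
    visited[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      for (int nb2 : t.adj26[cur])
        if (nb[nb2] && !visited[nb2]) { visited[nb2] = true; stack.push_back(nb2); }
    }
  }
  // (b) one 6-component of background in the 18-neighbourhood touching a face
  bool bvis[26] = {false};
  int ncomp_bg = 0;
  for (int s = 0; s < 26; ++s) {
    if (!t.in18[s] || nb[s] || bvis[s]) continue;
    // component; does it contain a face neighbour?
    bool face = false;
    std::vector<int> stack{s};
    bvis[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      if (t.isface[cur]) face = true;
      for (int nb2 : t.adj6[cur])
        if (!nb[nb2] && !bvis[nb2]) { bvis[nb2] = true; stack.push_back(nb2); }
    }
    if (face) {
      ++ncomp_bg;
      if (ncomp_bg > 1) return false;
    }
  }
  return ncomp_bg == 1;
}

inline void fill_neighbourhood(const std::vector<uint8_t> &m, int z, int y,
                               int x, int nz, int ny, int nx, bool nb[26]) {
  const CubeTables &t = tables();
  for (int s = 0; s < 26; ++s) {
    int zz = z + t.noff[s][0], yy = y + t.noff[s][1], xx = x + t.noff[s][2];
    nb[s] = !(zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) &&
            m[lin(zz, yy, xx, nz, ny)];
  }
}

inline int count_nb(const bool nb[26]) {
  int c = 0;
  for (int s = 0; s < 26; ++s) c += nb[s];
  return c;
}

} // namespace

// Topology-preserving 3D thinning: six directional subiterations
// (border peeling) per cycle; candidates are non-endpoint simple border
// points, deleted sequentially with a re-check so topology is preserved
// exactly. Deterministic (z, y, x) scan order.
// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<uint8_t> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  // direction order: -z, +z, -y, +y, -x, +x (border direction = background
  // face neighbour on that side)
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool nb[26];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            int i = lin(z, y, x, nz, ny);
            if (!m[i]) continue;
            int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            bool border =
                (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                 xx >= nx) || !m[lin(zz, yy, xx, nz, ny)];
            if (!border) continue;
            fill_neighbourhood(m, z, y, x, nz, ny, nx, nb);
            if (count_nb(nb) < 2) continue;  // endpoint or isolated: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check (parallel safety)
      for (int i : cand) {
        int z = i % nz, rest = i / nz;
        int y = rest % ny, x = rest / ny;
        fill_neighbourhood(m, z, y, x, nz, ny, nx, nb);
        if (count_nb(nb) < 2) continue;
        if (is_simple(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  out.attr("dim") = dim;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// Grayscale rolling-ball background of one 2D slice: morphological opening
// with a non-flat hemispherical structuring function of the given radius
// (in pixels). Returns the background estimate.
// [[Rcpp::export(name = ".cpp_rolling_ball_slice")]]
NumericMatrix cpp_rolling_ball_slice(NumericMatrix img, double radius) {
  const int ny = img.nrow(), nx = img.ncol();
  const int r = (int)std::floor(radius);
  // ball height profile
  std::vector<std::array<int, 2>> off;
  std::vector<double> h;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 > radius * radius) continue;
      off.push_back({dy, dx});
      h.push_back(std::sqrt(radius * radius - d2));
    }
  const int m = (int)off.size();
  NumericMatrix ero(ny, nx), bg(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int yy = y + off[k][0], xx = x + off[k][1];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double c = img(yy, xx) - h[k];
        if (c < v) v = c;
      }
      ero(y, x) = v;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int yy = y + off[k][0], xx = x + off[k][1];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double c = ero(yy, xx) + h[k];
        if (c > v) v = c;
      }
      bg(y, x) = v;
    }
  return bg;
}
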