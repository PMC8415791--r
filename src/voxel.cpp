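// Low-level voxel-grid primitives: connected-component labelling,
// exact Euclidean distance transform, topology-preserving 3D thinning,
// and batched symmetric 3x3 eigenvalue decomposition.
//
// Grids are passed as flat vectors in R's column-major order with an
// explicit dims attribute-equivalent argument; out-of-grid voxels are
// treated as background throughout.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int idx3(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// offsets of the 26-neighbourhood
struct Neigh {
  int dx[26], dy[26], dz[26], n;
  Neigh() : n(0) {
    for (int dz_ = -1; dz_ <= 1; ++dz_)
      for (int dy_ = -1; dy_ <= 1; ++dy_)
        for (int dx_ = -1; dx_ <= 1; ++dx_) {
          if (dx_ == 0 && dy_ == 0 && dz_ == 0) continue;
          dx[n] = dx_; dy[n] = dy_; dz[n] = dz_; ++n;
        }
  }
};
static const Neigh N26;

} // namespace

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur % d[0], y = (cur / d[0]) % d[1], z = cur / (d[0] * d[1]);
      for (int k = 0; k < 26; ++k) {
        int man = std::abs(N26.dx[k]) + std::abs(N26.dy[k]) + std::abs(N26.dz[k]);
        if (connectivity == 6 && man != 1) continue;
        int nx = x + N26.dx[k], ny = y + N26.dy[k], nz = z + N26.dz[k];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d[0] || ny >= d[1] || nz >= d[2])
          continue;
        int q = idx3(nx, ny, nz, d);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared-distance transform on a sampled
// line with physical sample spacing s.
void dt1d(const double* f, double* out, int n, double s,
          std::vector<int>& v, std::vector<double>& z) {
  if (n == 1) { out[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sep;
    for (;;) {
      double vs = v[k] * s;
      sep = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (sep <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sep; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * s;
    out[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

} // namespace

// Squared Euclidean distance from every voxel to the nearest background
// (FALSE) voxel, with anisotropic spacing in mm. Background voxels get 0.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3) stop("need 3D dims and spacing");
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (mask.size() != n) stop("mask length does not match dims");
  const double BIG = 1e20;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zc = 0; zc < d[2]; ++zc)
    for (int yc = 0; yc < d[1]; ++yc) {
      for (int x = 0; x < d[0]; ++x) f[x] = g[idx3(x, yc, zc, d)];
      dt1d(f.data(), out.data(), d[0], spacing[0], v, z);
      for (int x = 0; x < d[0]; ++x) g[idx3(x, yc, zc, d)] = out[x];
    }
  // pass along y
  for (int zc = 0; zc < d[2]; ++zc)
    for (int xc = 0; xc < d[0]; ++xc) {
      for (int y = 0; y < d[1]; ++y) f[y] = g[idx3(xc, y, zc, d)];
      dt1d(f.data(), out.data(), d[1], spacing[1], v, z);
      for (int y = 0; y < d[1]; ++y) g[idx3(xc, y, zc, d)] = out[y];
    }
  // pass along z
  for (int yc = 0; yc < d[1]; ++yc)
    for (int xc = 0; xc < d[0]; ++xc) {
      for (int zz = 0; zz < d[2]; ++zz) f[zz] = g[idx3(xc, yc, zz, d)];
      dt1d(f.data(), out.data(), d[2], spacing[2], v, z);
      for (int zz = 0; zz < d[2]; ++zz) g[idx3(xc, yc, zz, d)] = out[zz];
    }
  return g;
}

namespace {

// Simple-point test for (26, 6) digital topology on the 3x3x3 neighbourhood
// occupancy nb[27] (center at index 13; nb ordering x fastest).
// A border voxel is simple iff (a) its foreground 26-neighbours form exactly
// one 26-connected component, and (b) the background voxels of its
// 18-neighbourhood form exactly one 6-connected component that is 6-adjacent
// to the center.
inline int cube_idx(int x, int y, int z) { return (x + 1) + 3 * ((y + 1) + 3 * (z + 1)); }

bool is_simple(const bool nb[27]) {
  // (a) one 26-component of foreground in N26
  int fg[26], nfg = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) fg[nfg++] = i;
  if (nfg == 0) return false;
  bool seen[27] = {false};
  int stack[26], sp = 0;
  stack[sp++] = fg[0]; seen[fg[0]] = true;
  int cnt = 1;
  while (sp) {
    int c = stack[--sp];
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    for (int i = 0; i < nfg; ++i) {
      int o = fg[i];
      if (seen[o]) continue;
      int ox = o % 3 - 1, oy = (o / 3) % 3 - 1, oz = o / 9 - 1;
      if (std::abs(ox - cx) <= 1 && std::abs(oy - cy) <= 1 && std::abs(oz - cz) <= 1) {
        seen[o] = true; stack[sp++] = o; ++cnt;
      }
    }
  }
  if (cnt != nfg) return false;

  // (b) one 6-component of background in N18, 6-adjacent to center
  // N18 = neighbours with manhattan distance 1 or 2 (no corners)
  bool bseen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || nb[i] || bseen[i]) continue;
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int man = std::abs(ix) + std::abs(iy) + std::abs(iz);
    if (man != 1) continue; // grow components only from face-neighbours of center
    // BFS within background N18 cells using 6-connectivity
    ++ncomp;
    int st[18], sp2 = 0;
    st[sp2++] = i; bseen[i] = true;
    while (sp2) {
      int c = st[--sp2];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int ox = cx + F[k][0], oy = cy + F[k][1], oz = cz + F[k][2];
        if (ox < -1 || ox > 1 || oy < -1 || oy > 1 || oz < -1 || oz > 1) continue;
        if (std::abs(ox) + std::abs(oy) + std::abs(oz) > 2) continue; // stay in N18
        int o = cube_idx(ox, oy, oz);
        if (o == 13 || nb[o] || bseen[o]) continue;
        bseen[o] = true; st[sp2++] = o;
      }
    }
  }
  return ncomp == 1;
}

inline void fill_nb(const LogicalVector& m, const int* d, int x, int y, int z,
                    bool nb[27]) {
  int k = 0;
  for (int dz_ = -1; dz_ <= 1; ++dz_)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_, ++k) {
        int nx = x + dx_, ny = y + dy_, nz = z + dz_;
        nb[k] = !(nx < 0 || ny < 0 || nz < 0 ||
                  nx >= d[0] || ny >= d[1] || nz >= d[2]) &&
                m[idx3(nx, ny, nz, d)];
      }
}

inline int count_fg_neighbours(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

} // namespace

// Topology-preserving thinning of a 3D mask to a 1-voxel curve skeleton.
// Sequential deletion of simple border points in 6 directional sub-iterations;
// endpoints (exactly one foreground neighbour), isolated voxels and
// explicitly protected voxels (geodesic tube tips, root attachments) are
// kept. Protection is what stops open tube ends from eroding axially.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims,
                       Nullable<LogicalVector> protect_ = R_NilValue) {
  if (dims.size() != 3) stop("dims must have length 3");
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector m = clone(mask);
  LogicalVector protect(n, false);
  if (protect_.isNotNull()) {
    LogicalVector p(protect_);
    if (p.size() != n) stop("protect length does not match dims");
    protect = p;
  }

  static const int DIR[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (R_xlen_t s = 0; s < n; ++s) {
        if (!m[s] || protect[s]) continue;
        int x = s % d[0], y = (s / d[0]) % d[1], z = s / ((R_xlen_t)d[0] * d[1]);
        int bx = x + DIR[dir][0], by = y + DIR[dir][1], bz = z + DIR[dir][2];
        bool border = (bx < 0 || by < 0 || bz < 0 ||
                       bx >= d[0] || by >= d[1] || bz >= d[2]) ||
                      !m[idx3(bx, by, bz, d)];
        if (!border) continue;
        fill_nb(m, d, x, y, z, nb);
        int nf = count_fg_neighbours(nb);
        if (nf <= 1) continue;       // endpoint or isolated: preserve
        if (is_simple(nb)) cand.push_back((int)s);
      }
      // sequential re-checked deletion preserves topology exactly
      for (size_t i = 0; i < cand.size(); ++i) {
        int s = cand[i];
        if (!m[s]) continue;
        int x = s % d[0], y = (s / d[0]) % d[1], z = s / (d[0] * d[1]);
        fill_nb(m, d, x, y, z, nb);
        int nf = count_fg_neighbours(nb);
        if (nf <= 1) continue;
        if (is_simple(nb)) { m[s] = false; changed = true; }
      }
    }
  }
  return m;
}

// Eigenvalues of many symmetric 3x3 matrices, returned sorted by increasing
// absolute value (|l1| <= |l2| <= |l3|), via the trigonometric closed form.
// [[Rcpp::export(name = ".cpp_eigen_sym3")]]
NumericMatrix cpp_eigen_sym3(NumericVector xx, NumericVector yy, NumericVector zz,
                             NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t n = xx.size();
  if (yy.size() != n || zz.size() != n || xy.size() != n ||
      xz.size() != n || yz.size() != n)
    stop("all six component vectors must have equal length");
  NumericMatrix out(n, 3);
  const double TWO_PI_3 = 2.0943951023931953;
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = xx[i], b = yy[i], c = zz[i], de = xy[i], e = xz[i], f = yz[i];
    double l1, l2, l3;
    double p1 = de * de + e * e + f * f;
    if (p1 == 0.0) {
      l1 = a; l2 = b; l3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double ba = (a - q) / p, bb = (b - q) / p, bc = (c - q) / p;
      double bd = de / p, be = e / p, bf = f / p;
      double detB = ba * (bb * bc - bf * bf) - bd * (bd * bc - bf * be) +
                    be * (bd * bf - bb * be);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * TWO_PI_3);
      l2 = 3.0 * q - l1 - l3;
    }
    // sort by |lambda| ascending
    double v[3] = {l1, l2, l3};
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(v[t]) > std::fabs(v[t + 1])) std::swap(v[t], v[t + 1]);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}
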