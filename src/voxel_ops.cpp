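// Low-level voxel geometry primitives shared by the vascular and morphometry
// modules. Arrays arrive from R in (z, y, x) dimension order, column-major,
// so linear index = z + nz*(y + ny*x), all 0-based on this side.
#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int64_t lin(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * (int64_t)x);
}

// ---------------------------------------------------------------------------
// Connected-component labeling, 6- or 26-connectivity, BFS flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  // neighbor offset table
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  int next = 0;
  std::vector<int64_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = lin(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int64_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((int64_t)nz * ny));
          for (int k = 0; k < nn; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int64_t j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope 1D passes along each axis, with per-axis sample spacing).
// Returns, for every foreground voxel, the distance in physical units to the
// nearest background voxel center; 0 on background.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double w) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      double qq = q * w, vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (zb[k + 1] < qq) ++k;
    double vv = v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  const double INF = 1e30;
  NumericVector g(n);
  for (int64_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (spacing[0])
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) g[lin(z, y, x, nz, ny)] = d[z];
    }
  // pass along y (spacing[1])
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x (spacing[2])
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = d[x];
    }
  for (int64_t i = 0; i < n; ++i) g[i] = std::sqrt(g[i]);
  g.attr("dim") = dim;
  return g;
}

// ---------------------------------------------------------------------------
// Homotopic thinning skeletonization.
//
// A voxel is "simple" (removable without changing local topology) when the
// foreground of its 26-neighborhood forms exactly one 26-connected component
// and the background of its 18-neighborhood forms exactly one 6-connected
// component containing a face neighbor (Bertrand & Malandain criterion).
// Voxels are removed in increasing distance-transform order so the skeleton
// stays centered; curve endpoints (<= 1 foreground neighbor) are preserved.
// ---------------------------------------------------------------------------

static const int N26Z[26] = {-1,-1,-1,-1,-1,-1,-1,-1,-1, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1};
static const int N26Y[26] = {-1,-1,-1, 0, 0, 0, 1, 1, 1,-1,-1,-1, 0, 0, 1, 1, 1,-1,-1,-1, 0, 0, 0, 1, 1, 1};
static const int N26X[26] = {-1, 0, 1,-1, 0, 1,-1, 0, 1,-1, 0, 1,-1, 1,-1, 0, 1,-1, 0, 1,-1, 0, 1,-1, 0, 1};

// neighborhood cube index: (dz+1) + 3*(dy+1) + 9*(dx+1), center = 13
static inline int nbidx(int dz, int dy, int dx) { return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1); }

static bool is_simple(const bool nb[27]) {
  // condition 1: foreground in N26 \ {center} is one 26-connected component
  bool fg[27];
  int nfg = 0;
  for (int i = 0; i < 27; ++i) { fg[i] = (i != 13) && nb[i]; if (fg[i]) ++nfg; }
  if (nfg == 0) return false;  // isolated voxel: not simple
  {
    int seen[27] = {0};
    std::vector<int> st;
    int start = -1;
    for (int i = 0; i < 27; ++i) if (fg[i]) { start = i; break; }
    st.push_back(start); seen[start] = 1;
    int cnt = 1;
    while (!st.empty()) {
      int cur = st.back(); st.pop_back();
      int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int zz = cz + a, yy = cy + b, xx = cx + c;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
            int j = zz + 3 * yy + 9 * xx;
            if (fg[j] && !seen[j]) { seen[j] = 1; st.push_back(j); ++cnt; }
          }
    }
    if (cnt != nfg) return false;
  }
  // condition 2: background in N18 is one 6-connected component touching a
  // face neighbor of the center (6-connectivity paths confined to N18)
  {
    bool in18[27], bg[27];
    for (int i = 0; i < 27; ++i) {
      int cz = i % 3 - 1, cy = (i / 3) % 3 - 1, cx = i / 9 - 1;
      int manh = std::abs(cz) + std::abs(cy) + std::abs(cx);
      in18[i] = (manh == 1 || manh == 2);
      bg[i] = in18[i] && !nb[i];
    }
    // seeds: background face neighbors
    static const int faces[6] = { nbidx(-1,0,0), nbidx(1,0,0), nbidx(0,-1,0),
                                  nbidx(0,1,0), nbidx(0,0,-1), nbidx(0,0,1) };
    int ncomp = 0;
    int seen[27] = {0};
    for (int s = 0; s < 6; ++s) {
      int f0 = faces[s];
      if (!bg[f0] || seen[f0]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::vector<int> st;
      st.push_back(f0); seen[f0] = 1;
      while (!st.empty()) {
        int cur = st.back(); st.pop_back();
        int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
        const int dzs[6] = {-1,1,0,0,0,0}, dys[6] = {0,0,-1,1,0,0}, dxs[6] = {0,0,0,0,-1,1};
        for (int k = 0; k < 6; ++k) {
          int zz = cz + dzs[k], yy = cy + dys[k], xx = cx + dxs[k];
          if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
          int j = zz + 3 * yy + 9 * xx;
          if (bg[j] && !seen[j]) { seen[j] = 1; st.push_back(j); }
        }
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".skeletonize_3d")]]
LogicalVector skeletonize_3d(LogicalVector mask, IntegerVector dim, NumericVector priority,
                             NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  std::vector<char> m(n);
  for (int64_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> char {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return m[lin(z, y, x, nz, ny)];
  };
  auto fill_nb = [&](int z, int y, int x, bool nb[27]) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          nb[nbidx(a, b, c)] = at(z + a, y + b, x + c) != 0;
  };
  auto n26count = [&](int z, int y, int x) {
    int cnt = 0;
    for (int k = 0; k < 26; ++k) cnt += at(z + N26Z[k], y + N26Y[k], x + N26X[k]) != 0;
    return cnt;
  };

  // directional subiterations: per pass, each of the 6 face directions only
  // deletes voxels whose face neighbor in that direction is background at
  // subiteration start. This peels one layer per direction per pass and
  // prevents thin structures from unraveling end-to-end within one pass,
  // which would erase short side branches before they become endpoints.
  // With anisotropic voxels a direction fires only at a rate inversely
  // proportional to its physical spacing, so erosion speed is isotropic in
  // physical units and arms along the coarse axis are not eaten first.
  static const int DZ[6] = {-1, 1, 0, 0, 0, 0};
  static const int DY[6] = {0, 0, -1, 1, 0, 0};
  static const int DX[6] = {0, 0, 0, 0, -1, 1};
  const double sp[6] = {spacing[0], spacing[0], spacing[1], spacing[1],
                        spacing[2], spacing[2]};
  double spmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  std::vector<std::pair<double, int64_t> > cand;
  // run until a whole period (all directions have fired at least once)
  // passes without any deletion
  double spmax = std::max(spacing[0], std::max(spacing[1], spacing[2]));
  const long period = (long)std::ceil(spmax / spmin);
  long stall = 0;
  long pass = 0;
  while (stall <= period) {
    bool changed = false;
    ++pass;
    for (int dir = 0; dir < 6; ++dir) {
      double rate = spmin / sp[dir];   // fires on floor crossings of pass*rate
      if ((long)std::floor(pass * rate) == (long)std::floor((pass - 1) * rate))
        continue;
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            int64_t i = lin(z, y, x, nz, ny);
            if (m[i] && !at(z + DZ[dir], y + DY[dir], x + DX[dir]))
              cand.push_back(std::make_pair(priority[i], i));
          }
      std::sort(cand.begin(), cand.end());
      for (size_t k = 0; k < cand.size(); ++k) {
        int64_t i = cand[k].second;
        if (!m[i]) continue;
        int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((int64_t)nz * ny));
        if (n26count(z, y, x) <= 1) continue;  // endpoint: keep
        bool nb[27];
        fill_nb(z, y, x, nb);
        if (is_simple(nb)) { m[i] = 0; changed = true; }
      }
    }
    stall = changed ? 0 : stall + 1;
  }
  LogicalVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction: marching tetrahedra on the Kuhn 6-tetrahedron cube
// decomposition. The decomposition is conforming across cube faces, so the
// mesh of a closed component is watertight by construction. Vertices are
// returned in physical (x, y, z) micrometre coordinates; triangle winding is
// oriented so normals point toward decreasing field values (outward for a
// bright-inside field).
// ---------------------------------------------------------------------------

struct Key64Hash {
  size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// [[Rcpp::export(name = ".marching_tetra")]]
List marching_tetra(NumericVector field, IntegerVector dim, double iso, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  // 6 tets per cube: one per permutation of the axis step order (z=0,y=1,x=2)
  static const int perms[6][3] = { {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0} };

  std::unordered_map<uint64_t, int, Key64Hash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto val = [&](int z, int y, int x) { return field[lin(z, y, x, nz, ny)]; };

  // corner: lattice (z,y,x); returns packed id
  auto pid = [&](int z, int y, int x) -> uint64_t {
    return (uint64_t)lin(z, y, x, nz, ny);
  };
  const uint64_t NTOT = (uint64_t)nz * ny * nx;

  // interpolated vertex on lattice edge (a -> b); caches by canonical key
  struct Corner { int z, y, x; double v; uint64_t id; };
  auto edge_vertex = [&](const Corner& a, const Corner& b) -> int {
    uint64_t lo = std::min(a.id, b.id), hi = std::max(a.id, b.id);
    uint64_t key = lo * NTOT + hi;
    std::unordered_map<uint64_t, int, Key64Hash>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - a.v) / (b.v - a.v);
    double px = (a.x + t * (b.x - a.x)) * sx;
    double py = (a.y + t * (b.y - a.y)) * sy;
    double pz = (a.z + t * (b.z - a.z)) * sz;
    int idx = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    vmap[key] = idx;
    return idx;
  };

  auto emit = [&](int a, int b, int c, const double g[3]) {
    // g = field gradient (physical units, order x,y,z); flip so normal . g < 0
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double dot = nxv * g[0] + nyv * g[1] + nzv * g[2];
    if (dot > 0) { int t = b; b = c; c = t; }
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        // quick reject: all 8 corners on one side
        double mn = 1e300, mx = -1e300;
        for (int a = 0; a <= 1; ++a)
          for (int b = 0; b <= 1; ++b)
            for (int c = 0; c <= 1; ++c) {
              double v = val(z + a, y + b, x + c);
              if (v < mn) mn = v;
              if (v > mx) mx = v;
            }
        if (mn > iso || mx <= iso) continue;

        for (int p = 0; p < 6; ++p) {
          Corner cor[4];
          int off[3] = {0, 0, 0};  // (z, y, x) offsets
          for (int k = 0; k < 4; ++k) {
            if (k > 0) off[perms[p][k - 1]] = 1;
            int cz = z + off[0], cy = y + off[1], cx = x + off[2];
            cor[k].z = cz; cor[k].y = cy; cor[k].x = cx;
            cor[k].v = val(cz, cy, cx);
            cor[k].id = pid(cz, cy, cx);
          }
          int mask = 0;
          for (int k = 0; k < 4; ++k) if (cor[k].v > iso) mask |= (1 << k);
          if (mask == 0 || mask == 15) continue;

          // linear-field gradient inside the tet, physical (x,y,z) order
          double g[3] = {0, 0, 0};
          const double sax[3] = {sz, sy, sx};  // spacing by axis index z,y,x
          for (int k = 0; k < 3; ++k) {
            int axis = perms[p][k];            // 0=z, 1=y, 2=x
            double dv = (cor[k + 1].v - cor[k].v) / sax[axis];
            if (axis == 0) g[2] = dv;
            else if (axis == 1) g[1] = dv;
            else g[0] = dv;
          }

          int inside[4], outside[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (mask & (1 << k)) inside[ni++] = k; else outside[no++] = k;
          }
          if (ni == 1) {
            int i0 = inside[0];
            int e0 = edge_vertex(cor[i0], cor[outside[0]]);
            int e1 = edge_vertex(cor[i0], cor[outside[1]]);
            int e2 = edge_vertex(cor[i0], cor[outside[2]]);
            emit(e0, e1, e2, g);
          } else if (ni == 3) {
            int o0 = outside[0];
            int e0 = edge_vertex(cor[inside[0]], cor[o0]);
            int e1 = edge_vertex(cor[inside[1]], cor[o0]);
            int e2 = edge_vertex(cor[inside[2]], cor[o0]);
            emit(e0, e1, e2, g);
          } else {  // ni == 2: quad, cyclic (i0,o0)-(i0,o1)-(i1,o1)-(i1,o0)
            int i0 = inside[0], i1 = inside[1], o0 = outside[0], o1 = outside[1];
            int q0 = edge_vertex(cor[i0], cor[o0]);
            int q1 = edge_vertex(cor[i0], cor[o1]);
            int q2 = edge_vertex(cor[i1], cor[o1]);
            int q3 = edge_vertex(cor[i1], cor[o0]);
            emit(q0, q1, q2, g);
            emit(q0, q2, q3, g);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; ++i) {
    T(i, 0) = tri[3 * i] + 1; T(i, 1) = tri[3 * i + 1] + 1; T(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("triangles") = T);
}
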