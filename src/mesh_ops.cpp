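// Mesh rendering and geometry kernels: z-buffer rasterization of
// per-vertex attributes, grid-accelerated ray-triangle queries for
// occlusion tests, and quadric edge-collapse decimation.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
#include <algorithm>
#include <set>
#include <array>
#include <functional>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rasterization
// ---------------------------------------------------------------------------

// Rasterize a triangle mesh whose vertices are already projected to pixel
// coordinates (u right, v down, pixel centres at integers, 0-based).
// Perspective-correct interpolation of one scalar attribute via 1/z.
// Returns attribute image, depth buffer and 1-based face index per pixel
// (0 = background).
// [[Rcpp::export]]
List rasterize_mesh_cpp(NumericMatrix px, NumericVector depth,
                        IntegerMatrix faces, NumericVector attr,
                        int width, int height, double background) {
  NumericMatrix img(height, width);
  NumericMatrix zbuf(height, width);
  IntegerMatrix fbuf(height, width);
  std::fill(img.begin(), img.end(), background);
  std::fill(zbuf.begin(), zbuf.end(), std::numeric_limits<double>::infinity());

  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    const double z0 = depth[i0], z1 = depth[i1], z2 = depth[i2];
    if (z0 <= 0 || z1 <= 0 || z2 <= 0) continue;  // clip: any vertex behind
    const double x0 = px(i0, 0), y0 = px(i0, 1);
    const double x1 = px(i1, 0), y1 = px(i1, 1);
    const double x2 = px(i2, 0), y2 = px(i2, 1);
    if (!R_finite(x0) || !R_finite(x1) || !R_finite(x2) ||
        !R_finite(y0) || !R_finite(y1) || !R_finite(y2)) continue;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    int xmin = std::max(0, (int)std::ceil(std::min({x0, x1, x2})));
    int xmax = std::min(width - 1, (int)std::floor(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::ceil(std::min({y0, y1, y2})));
    int ymax = std::min(height - 1, (int)std::floor(std::max({y0, y1, y2})));
    if (xmin > xmax || ymin > ymax) continue;
    const double inv_area = 1.0 / area;
    const double iz0 = 1.0 / z0, iz1 = 1.0 / z1, iz2 = 1.0 / z2;
    const double a0 = attr[i0] * iz0, a1 = attr[i1] * iz1, a2 = attr[i2] * iz2;
    for (int y = ymin; y <= ymax; ++y) {
      for (int x = xmin; x <= xmax; ++x) {
        const double w0 = ((x1 - (double)x) * (y2 - (double)y) -
                           (x2 - (double)x) * (y1 - (double)y)) * inv_area;
        const double w1 = ((x2 - (double)x) * (y0 - (double)y) -
                           (x0 - (double)x) * (y2 - (double)y)) * inv_area;
        const double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        const double iz = w0 * iz0 + w1 * iz1 + w2 * iz2;
        const double z = 1.0 / iz;
        if (z < zbuf(y, x)) {
          zbuf(y, x) = z;
          img(y, x) = (w0 * a0 + w1 * a1 + w2 * a2) * z;
          fbuf(y, x) = f + 1;
        }
      }
    }
  }
  return List::create(_["image"] = img, _["depth"] = zbuf,
                      _["face"] = fbuf);
}

// ---------------------------------------------------------------------------
// Ray-triangle queries (uniform-grid acceleration)
// ---------------------------------------------------------------------------

struct TriGrid {
  int nx, ny, nz;
  double ox, oy, oz, cell;
  std::vector<std::vector<int>> cells;
  int idx(int ix, int iy, int iz) const {
    return (iz * ny + iy) * nx + ix;
  }
};

static TriGrid build_grid(const NumericMatrix &V, const IntegerMatrix &F) {
  TriGrid g;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(i, d));
      hi[d] = std::max(hi[d], V(i, d));
    }
  const double pad = 1e-6;
  for (int d = 0; d < 3; ++d) { lo[d] -= pad; hi[d] += pad; }
  // aim for ~2 triangles per occupied cell
  const double vol = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  double cell = std::cbrt(std::max(vol, 1e-30) / std::max(F.nrow(), 1));
  cell = std::max(cell, 1e-9);
  g.nx = std::min(256, std::max(1, (int)std::ceil((hi[0] - lo[0]) / cell)));
  g.ny = std::min(256, std::max(1, (int)std::ceil((hi[1] - lo[1]) / cell)));
  g.nz = std::min(256, std::max(1, (int)std::ceil((hi[2] - lo[2]) / cell)));
  g.cell = std::max({(hi[0] - lo[0]) / g.nx, (hi[1] - lo[1]) / g.ny,
                     (hi[2] - lo[2]) / g.nz, 1e-9});
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.cells.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int f = 0; f < F.nrow(); ++f) {
    double tlo[3], thi[3];
    for (int d = 0; d < 3; ++d) {
      tlo[d] = std::min({V(F(f, 0) - 1, d), V(F(f, 1) - 1, d), V(F(f, 2) - 1, d)});
      thi[d] = std::max({V(F(f, 0) - 1, d), V(F(f, 1) - 1, d), V(F(f, 2) - 1, d)});
    }
    int c0[3], c1[3];
    c0[0] = std::max(0, std::min(g.nx - 1, (int)((tlo[0] - g.ox) / g.cell)));
    c0[1] = std::max(0, std::min(g.ny - 1, (int)((tlo[1] - g.oy) / g.cell)));
    c0[2] = std::max(0, std::min(g.nz - 1, (int)((tlo[2] - g.oz) / g.cell)));
    c1[0] = std::max(0, std::min(g.nx - 1, (int)((thi[0] - g.ox) / g.cell)));
    c1[1] = std::max(0, std::min(g.ny - 1, (int)((thi[1] - g.oy) / g.cell)));
    c1[2] = std::max(0, std::min(g.nz - 1, (int)((thi[2] - g.oz) / g.cell)));
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          g.cells[g.idx(ix, iy, iz)].push_back(f);
  }
  return g;
}

// Moller-Trumbore; returns t or -1
static inline double tri_intersect(const double *o, const double *d,
                                   const NumericMatrix &V,
                                   const IntegerMatrix &F, int f,
                                   double &u_out, double &v_out) {
  const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int d2 = 0; d2 < 3; ++d2) {
    e1[d2] = V(i1, d2) - V(i0, d2);
    e2[d2] = V(i2, d2) - V(i0, d2);
  }
  pv[0] = d[1] * e2[2] - d[2] * e2[1];
  pv[1] = d[2] * e2[0] - d[0] * e2[2];
  pv[2] = d[0] * e2[1] - d[1] * e2[0];
  const double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < 1e-14) return -1.0;
  const double inv = 1.0 / det;
  for (int d2 = 0; d2 < 3; ++d2) tv[d2] = o[d2] - V(i0, d2);
  const double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < 0 || u > 1) return -1.0;
  qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
  qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
  qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
  const double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < 0 || u + v > 1) return -1.0;
  const double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  u_out = u; v_out = v;
  return t;
}

// Walk the grid along a ray (3D-DDA), calling triangle tests per cell.
template <typename Fn>
static void grid_walk(const TriGrid &g, const double *o, const double *d,
                      double tmax, Fn &&visit) {
  // entry point: clamp origin into grid bounds along the ray if outside
  double t0 = 0.0;
  double pos[3] = {o[0], o[1], o[2]};
  const double glo[3] = {g.ox, g.oy, g.oz};
  const double ghi[3] = {g.ox + g.nx * g.cell, g.oy + g.ny * g.cell,
                         g.oz + g.nz * g.cell};
  for (int dd = 0; dd < 3; ++dd) {
    if (std::fabs(d[dd]) < 1e-30) {
      if (pos[dd] < glo[dd] || pos[dd] > ghi[dd]) return;
    } else {
      const double t1 = (glo[dd] - o[dd]) / d[dd];
      const double t2 = (ghi[dd] - o[dd]) / d[dd];
      t0 = std::max(t0, std::min(t1, t2));
    }
  }
  if (t0 > tmax) return;
  if (t0 > 0) {
    t0 += 1e-12;
    for (int dd = 0; dd < 3; ++dd) pos[dd] = o[dd] + t0 * d[dd];
  }
  int ix = std::max(0, std::min(g.nx - 1, (int)((pos[0] - g.ox) / g.cell)));
  int iy = std::max(0, std::min(g.ny - 1, (int)((pos[1] - g.oy) / g.cell)));
  int iz = std::max(0, std::min(g.nz - 1, (int)((pos[2] - g.oz) / g.cell)));
  const int sx = d[0] > 0 ? 1 : -1, sy = d[1] > 0 ? 1 : -1,
            sz = d[2] > 0 ? 1 : -1;
  const double inf = std::numeric_limits<double>::infinity();
  double tdx = std::fabs(d[0]) > 1e-30 ? g.cell / std::fabs(d[0]) : inf;
  double tdy = std::fabs(d[1]) > 1e-30 ? g.cell / std::fabs(d[1]) : inf;
  double tdz = std::fabs(d[2]) > 1e-30 ? g.cell / std::fabs(d[2]) : inf;
  double nbx = std::fabs(d[0]) > 1e-30
                   ? (g.ox + (ix + (sx > 0)) * g.cell - o[0]) / d[0] : inf;
  double nby = std::fabs(d[1]) > 1e-30
                   ? (g.oy + (iy + (sy > 0)) * g.cell - o[1]) / d[1] : inf;
  double nbz = std::fabs(d[2]) > 1e-30
                   ? (g.oz + (iz + (sz > 0)) * g.cell - o[2]) / d[2] : inf;
  while (true) {
    if (!visit(g.cells[g.idx(ix, iy, iz)])) return;
    const double tnext = std::min({nbx, nby, nbz});
    if (tnext > tmax) return;
    if (nbx <= nby && nbx <= nbz) {
      ix += sx; nbx += tdx;
      if (ix < 0 || ix >= g.nx) return;
    } else if (nby <= nbz) {
      iy += sy; nby += tdy;
      if (iy < 0 || iy >= g.ny) return;
    } else {
      iz += sz; nbz += tdz;
      if (iz < 0 || iz >= g.nz) return;
    }
  }
}

// Closest hit of each ray against the mesh. Returns t (-1 if miss),
// 1-based face index, and barycentric (u, v) wrt the face's 2nd/3rd vertex.
// [[Rcpp::export]]
List ray_mesh_intersect_cpp(NumericMatrix origins, NumericMatrix dirs,
                            NumericMatrix V, IntegerMatrix F,
                            double tmin = 0.0) {
  TriGrid g = build_grid(V, F);
  const int n = origins.nrow();
  NumericVector tout(n, -1.0);
  IntegerVector fout(n, 0);
  NumericMatrix bout(n, 2);
  for (int i = 0; i < n; ++i) {
    const double o[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    const double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    double tbest = std::numeric_limits<double>::infinity();
    int fbest = -1; double ub = 0, vb = 0;
    grid_walk(g, o, d, tbest, [&](const std::vector<int> &tris) {
      for (int f : tris) {
        double u, v;
        const double t = tri_intersect(o, d, V, F, f, u, v);
        if (t > tmin && t < tbest) { tbest = t; fbest = f; ub = u; vb = v; }
      }
      return true;  // keep walking: closest hit may be in a later cell
    });
    if (fbest >= 0) {
      tout[i] = tbest; fout[i] = fbest + 1;
      bout(i, 0) = ub; bout(i, 1) = vb;
    }
  }
  return List::create(_["t"] = tout, _["face"] = fout, _["bary"] = bout);
}

// Occlusion query: is any triangle hit strictly between eps and tmax-eps
// along each ray? Used for per-vertex visibility (ray from vertex towards
// the camera).
// [[Rcpp::export]]
LogicalVector ray_occluded_cpp(NumericMatrix origins, NumericMatrix dirs,
                               NumericVector tmax, NumericMatrix V,
                               IntegerMatrix F, double eps = 1e-5) {
  TriGrid g = build_grid(V, F);
  const int n = origins.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const double o[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    const double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    const double lim = tmax[i] - eps;
    bool hit = false;
    grid_walk(g, o, d, lim, [&](const std::vector<int> &tris) {
      for (int f : tris) {
        double u, v;
        const double t = tri_intersect(o, d, V, F, f, u, v);
        if (t > eps && t < lim) { hit = true; return false; }
      }
      return true;
    });
    out[i] = hit;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Quadric edge-collapse decimation
// ---------------------------------------------------------------------------

struct Quadric {
  // symmetric 4x4 stored as upper triangle
  double q[10] = {0};
  void add_plane(double a, double b, double c, double d, double w) {
    const double v[4] = {a, b, c, d};
    int k = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) q[k++] += w * v[i] * v[j];
  }
  void add(const Quadric &o) { for (int k = 0; k < 10; ++k) q[k] += o.q[k]; }
  double eval(double x, double y, double z) const {
    const double v[4] = {x, y, z, 1};
    double s = 0; int k = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) {
        s += (i == j ? 1.0 : 2.0) * q[k++] * v[i] * v[j];
      }
    return s;
  }
};

struct HeapEdge {
  double cost; int a, b; int stamp_a, stamp_b;
  bool operator<(const HeapEdge &o) const { return cost > o.cost; }
};

// Decimate to a target vertex count by greedy quadric edge collapse with a
// link-condition check (preserves topology). Collapse position is the
// cheaper endpoint or midpoint (subset placement keeps the implementation
// robust without a 4x4 solve).
// [[Rcpp::export]]
List decimate_mesh_cpp(NumericMatrix Vin, IntegerMatrix Fin,
                       int target_vertices) {
  const int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i] = Vin(i, 0); Y[i] = Vin(i, 1); Z[i] = Vin(i, 2); }
  std::vector<std::array<int, 3>> F(nf);
  for (int f = 0; f < nf; ++f)
    F[f] = {Fin(f, 0) - 1, Fin(f, 1) - 1, Fin(f, 2) - 1};

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    const int a = F[f][0], b = F[f][1], c = F[f][2];
    const double ux = X[b] - X[a], uy = Y[b] - Y[a], uz = Z[b] - Z[a];
    const double vx = X[c] - X[a], vy = Y[c] - Y[a], vz = Z[c] - Z[a];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
           nz = ux * vy - uy * vx;
    const double len = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (len < 1e-20) continue;
    const double area = 0.5 * len;
    nx /= len; ny /= len; nz /= len;
    const double d = -(nx * X[a] + ny * Y[a] + nz * Z[a]);
    Q[a].add_plane(nx, ny, nz, d, area);
    Q[b].add_plane(nx, ny, nz, d, area);
    Q[c].add_plane(nx, ny, nz, d, area);
  }

  // adjacency: vertex -> set of neighbour vertices
  std::vector<std::set<int>> nbr(nv);
  for (auto &f : F)
    for (int e = 0; e < 3; ++e) {
      nbr[f[e]].insert(f[(e + 1) % 3]);
      nbr[f[e]].insert(f[(e + 2) % 3]);
    }
  std::vector<int> stamp(nv, 0);
  std::vector<bool> alive(nv, true);
  // collapse map (union-find with path compression): find() resolves any
  // original vertex to its surviving representative
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  auto edge_cost = [&](int a, int b, double &px, double &py, double &pz) {
    Quadric q = Q[a]; q.add(Q[b]);
    const double ca = q.eval(X[a], Y[a], Z[a]);
    const double cb = q.eval(X[b], Y[b], Z[b]);
    const double mx = 0.5 * (X[a] + X[b]), my = 0.5 * (Y[a] + Y[b]),
                 mz = 0.5 * (Z[a] + Z[b]);
    const double cm = q.eval(mx, my, mz);
    if (cm <= ca && cm <= cb) { px = mx; py = my; pz = mz; return cm; }
    if (ca <= cb) { px = X[a]; py = Y[a]; pz = Z[a]; return ca; }
    px = X[b]; py = Y[b]; pz = Z[b]; return cb;
  };

  std::priority_queue<HeapEdge> heap;
  auto push_edge = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    double px, py, pz;
    const double c = edge_cost(a, b, px, py, pz);
    heap.push({c, a, b, stamp[a], stamp[b]});
  };
  for (int a = 0; a < nv; ++a)
    for (int b : nbr[a]) if (b > a) push_edge(a, b);

  int alive_count = nv;
  while (alive_count > target_vertices && !heap.empty()) {
    HeapEdge e = heap.top(); heap.pop();
    const int a = e.a, b = e.b;
    if (!alive[a] || !alive[b]) continue;
    if (e.stamp_a != stamp[a] || e.stamp_b != stamp[b]) continue;
    if (!nbr[a].count(b)) continue;
    // link condition: common neighbours of a and b must be exactly the two
    // triangle apices, otherwise the collapse pinches the surface
    int common = 0;
    for (int x : nbr[a]) if (nbr[b].count(x)) ++common;
    if (common != 2) continue;
    // collapse b into a at the optimal subset position
    double px, py, pz;
    edge_cost(a, b, px, py, pz);
    X[a] = px; Y[a] = py; Z[a] = pz;
    Q[a].add(Q[b]);
    alive[b] = false; --alive_count;
    parent[b] = a;
    nbr[a].erase(b);
    for (int x : nbr[b]) {
      if (x == a) continue;
      nbr[x].erase(b);
      nbr[x].insert(a);
      nbr[a].insert(x);
    }
    nbr[b].clear();
    ++stamp[a];
    for (int x : nbr[a]) push_edge(a, x);
  }

  // rebuild: remap original faces through the collapse map, drop
  // degenerate and duplicate faces, compact vertex indices
  std::vector<int> newid(nv, 0);
  int nv_out = 0;
  for (int i = 0; i < nv; ++i) if (alive[i]) newid[i] = ++nv_out;  // 1-based
  std::set<std::array<int, 3>> seen;
  std::vector<std::array<int, 3>> Fout;
  for (auto &f : F) {
    int a = find(f[0]), b = find(f[1]), c = find(f[2]);
    if (a == b || b == c || a == c) continue;
    std::array<int, 3> key = {a, b, c};
    std::array<int, 3> sorted = key;
    std::sort(sorted.begin(), sorted.end());
    if (!seen.insert(sorted).second) continue;
    Fout.push_back({newid[a], newid[b], newid[c]});
  }
  NumericMatrix Vout(nv_out, 3);
  for (int i = 0; i < nv; ++i)
    if (alive[i]) {
      Vout(newid[i] - 1, 0) = X[i];
      Vout(newid[i] - 1, 1) = Y[i];
      Vout(newid[i] - 1, 2) = Z[i];
    }
  IntegerMatrix Fm(Fout.size(), 3);
  for (size_t f = 0; f < Fout.size(); ++f)
    for (int e = 0; e < 3; ++e) Fm(f, e) = Fout[f][e];
  return List::create(_["vertices"] = Vout, _["faces"] = Fm);
}
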