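#include <Rcpp.h>
#include <queue>
#include <vector>
#include <set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major, so
// linear index = z + y*nz + x*nz*ny (0-based here, 1-based in R).

static const double BIG = 1e20;

// ---------------------------------------------------------------- watershed

struct WsEntry {
  double v;
  int lab;
  long long age;
  int idx;
};
struct WsCmp {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.v != b.v) return a.v > b.v;
    // FIFO within a flood level: equal-intensity plateaus are apportioned
    // by arrival order, i.e. split at their geometric middle
    return a.age > b.age;
  }
};

// Seeded watershed by priority flooding on the intensity relief.
// Markers > 0 keep their label; every voxel ends up labelled.
// 6-connectivity; ties broken by flood level, then marker id, then age.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector markers) {
  IntegerVector dim = relief.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector out(n);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long age = 0;
  for (int i = 0; i < n; i++) {
    out[i] = markers[i] > 0 ? markers[i] : 0;
  }
  for (int i = 0; i < n; i++) {
    if (out[i] > 0) pq.push(WsEntry{relief[i], out[i], age++, i});
  }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    int i = e.idx;
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int d = 0; d < 6; d++) {
      int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = zz + yy * nz + xx * nz * ny;
      if (out[j] == 0) {
        out[j] = e.lab;
        pq.push(WsEntry{relief[j], e.lab, age++, j});
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------ fast marching

struct FmEntry {
  double t;
  int idx;
};
struct FmCmp {
  bool operator()(const FmEntry &a, const FmEntry &b) const {
    return a.t > b.t;
  }
};

// Solve the first-order upwind quadratic sum_i ((T - T_i)/h_i)^2 = slow^2
// greedily over the sorted upwind neighbour times.
static double eikonal_update(std::vector<std::pair<double, double> > &nb,
                             double slow) {
  std::sort(nb.begin(), nb.end());
  double T = BIG;
  double a = 0, b = 0, c = -slow * slow;
  for (size_t k = 0; k < nb.size(); k++) {
    if (nb[k].first >= T) break;
    double w = 1.0 / (nb[k].second * nb[k].second);
    a += w;
    b += 2.0 * w * nb[k].first;
    c += w * nb[k].first * nb[k].first;
    double disc = b * b - 4.0 * a * c;
    if (disc < 0) break;
    T = (b + std::sqrt(disc)) / (2.0 * a);
  }
  return T;
}

// First-order Fast Marching arrival times from a single source voxel.
// speed: positive where traversable (<= 0 is an obstacle, arrival stays Inf).
// source: 0-based (z, y, x). spacing: grid step (hz, hy, hx).
// [[Rcpp::export]]
NumericVector cpp_fast_marching(NumericVector speed, IntegerVector source,
                                NumericVector spacing) {
  IntegerVector dim = speed.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  NumericVector T(n, R_PosInf);
  std::vector<char> frozen(n, 0);
  std::priority_queue<FmEntry, std::vector<FmEntry>, FmCmp> pq;
  int src = source[0] + source[1] * nz + source[2] * nz * ny;
  T[src] = 0.0;
  pq.push(FmEntry{0.0, src});
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  const double hax[6] = {0, 0, 1, 1, 2, 2}; // axis per direction: z,z,y,y,x,x
  while (!pq.empty()) {
    FmEntry e = pq.top();
    pq.pop();
    if (frozen[e.idx]) continue;
    frozen[e.idx] = 1;
    int z = e.idx % nz, y = (e.idx / nz) % ny, x = e.idx / (nz * ny);
    for (int d = 0; d < 6; d++) {
      int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = zz + yy * nz + xx * nz * ny;
      if (frozen[j] || speed[j] <= 0) continue;
      // collect best frozen upwind neighbour per axis
      std::vector<std::pair<double, double> > nb;
      int zj = zz, yj = yy, xj = xx;
      for (int ax = 0; ax < 3; ax++) {
        double best = BIG;
        for (int s = -1; s <= 1; s += 2) {
          int z2 = zj + (ax == 0 ? s : 0);
          int y2 = yj + (ax == 1 ? s : 0);
          int x2 = xj + (ax == 2 ? s : 0);
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          int k = z2 + y2 * nz + x2 * nz * ny;
          if (frozen[k] && T[k] < best) best = T[k];
        }
        if (best < BIG)
          nb.push_back(std::make_pair(best, spacing[ax]));
      }
      (void)hax;
      if (nb.empty()) continue;
      double newT = eikonal_update(nb, 1.0 / speed[j]);
      if (newT < T[j]) {
        T[j] = newT;
        pq.push(FmEntry{newT, j});
      }
    }
  }
  T.attr("dim") = dim;
  return T;
}

// ------------------------------------------------- exact distance transform

// Felzenszwalb & Huttenlocher 1-D squared distance transform with spacing h.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * h, s = 0;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0)
        k--;
      else
        break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance of every TRUE voxel to the nearest
// FALSE voxel. spacing: (hz, hy, hx). All-TRUE input returns Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<double> g(n);
  for (int i = 0; i < n; i++) g[i] = mask[i] ? BIG : 0.0;
  std::vector<double> f(std::max(nz, std::max(ny, nx)));
  std::vector<double> d(f.size());
  // z axis (stride 1)
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      int base = y * nz + x * nz * ny;
      for (int z = 0; z < nz; z++) f[z] = g[base + z];
      dt1d(f, d, nz, spacing[0]);
      for (int z = 0; z < nz; z++) g[base + z] = d[z];
    }
  // y axis
  for (int x = 0; x < nx; x++)
    for (int z = 0; z < nz; z++) {
      int base = z + x * nz * ny;
      for (int y = 0; y < ny; y++) f[y] = g[base + y * nz];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; y++) g[base + y * nz] = d[y];
    }
  // x axis
  for (int y = 0; y < ny; y++)
    for (int z = 0; z < nz; z++) {
      int base = z + y * nz;
      for (int x = 0; x < nx; x++) f[x] = g[base + x * nz * ny];
      dt1d(f, d, nx, spacing[2]);
      for (int x = 0; x < nx; x++) g[base + x * nz * ny] = d[x];
    }
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = g[i] >= BIG ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------ connected components

// Label connected components of TRUE voxels; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (int i0 = 0; i0 < n; i0++) {
    if (!mask[i0] || lab[i0] != 0) continue;
    next++;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int ord = std::abs(dz) + std::abs(dy) + std::abs(dx);
            if (ord == 0) continue;
            if (connectivity == 6 && ord > 1) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                xx >= nx)
              continue;
            int j = zz + yy * nz + xx * nz * ny;
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// -------------------------------------------------------- steepest descent

// Discrete steepest descent on a scalar field from a start voxel: step to the
// strictly smallest 26-neighbour until no neighbour is lower. Returns the
// 0-based (z,y,x) path including both endpoints.
// [[Rcpp::export]]
IntegerMatrix cpp_descent_path(NumericVector field, IntegerVector start) {
  IntegerVector dim = field.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> path;
  int z = start[0], y = start[1], x = start[2];
  int guard = nz * ny * nx + 1;
  while (guard-- > 0) {
    path.push_back(z);
    path.push_back(y);
    path.push_back(x);
    double cur = field[z + y * nz + x * nz * ny];
    double best = cur;
    int bz = z, by = y, bx = x;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          double v = field[zz + yy * nz + xx * nz * ny];
          if (v < best) {
            best = v;
            bz = zz;
            by = yy;
            bx = xx;
          }
        }
    if (best >= cur) break;
    z = bz;
    y = by;
    x = bx;
  }
  int m = (int)path.size() / 3;
  IntegerMatrix out(m, 3);
  for (int i = 0; i < m; i++) {
    out(i, 0) = path[3 * i];
    out(i, 1) = path[3 * i + 1];
    out(i, 2) = path[3 * i + 2];
  }
  return out;
}

// ---------------------------------------------------------- 3-D convex hull

struct HFace {
  int a, b, c;
  double nx, ny, nz, off;
  bool alive;
};

static HFace make_face(const NumericMatrix &P, int a, int b, int c) {
  HFace f;
  f.a = a;
  f.b = b;
  f.c = c;
  double ux = P(b, 0) - P(a, 0), uy = P(b, 1) - P(a, 1), uz = P(b, 2) - P(a, 2);
  double vx = P(c, 0) - P(a, 0), vy = P(c, 1) - P(a, 1), vz = P(c, 2) - P(a, 2);
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * P(a, 0) + f.ny * P(a, 1) + f.nz * P(a, 2);
  f.alive = true;
  return f;
}

// Volume of the convex hull of a 3-D point set (incremental hull).
// Degenerate (coplanar/collinear) input returns 0.
// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  // scale for tolerance
  double lo[3], hi[3];
  for (int k = 0; k < 3; k++) {
    lo[k] = hi[k] = pts(0, k);
    for (int i = 1; i < n; i++) {
      lo[k] = std::min(lo[k], pts(i, k));
      hi[k] = std::max(hi[k], pts(i, k));
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) return 0.0;
  double eps = 1e-9 * diag * diag; // compared against un-normalised plane dot
  // initial extreme pair
  int i0 = 0, i1 = 0;
  double dmax = -1;
  for (int k = 0; k < 3; k++) {
    int a = 0, b = 0;
    for (int i = 1; i < n; i++) {
      if (pts(i, k) < pts(a, k)) a = i;
      if (pts(i, k) > pts(b, k)) b = i;
    }
    double dd = 0;
    for (int j = 0; j < 3; j++)
      dd += (pts(a, j) - pts(b, j)) * (pts(a, j) - pts(b, j));
    if (dd > dmax) {
      dmax = dd;
      i0 = a;
      i1 = b;
    }
  }
  if (dmax <= 0) return 0.0;
  // furthest from line i0-i1
  int i2 = -1;
  dmax = 1e-12 * diag * diag;
  double ax = pts(i1, 0) - pts(i0, 0), ay = pts(i1, 1) - pts(i0, 1),
         az = pts(i1, 2) - pts(i0, 2);
  for (int i = 0; i < n; i++) {
    double bx = pts(i, 0) - pts(i0, 0), by = pts(i, 1) - pts(i0, 1),
           bz = pts(i, 2) - pts(i0, 2);
    double cx = ay * bz - az * by, cy = az * bx - ax * bz,
           cz = ax * by - ay * bx;
    double dd = cx * cx + cy * cy + cz * cz;
    if (dd > dmax) {
      dmax = dd;
      i2 = i;
    }
  }
  if (i2 < 0) return 0.0;
  // furthest from plane (i0,i1,i2)
  HFace base = make_face(pts, i0, i1, i2);
  int i3 = -1;
  dmax = eps;
  for (int i = 0; i < n; i++) {
    double dd = std::fabs(base.nx * pts(i, 0) + base.ny * pts(i, 1) +
                          base.nz * pts(i, 2) - base.off);
    if (dd > dmax) {
      dmax = dd;
      i3 = i;
    }
  }
  if (i3 < 0) return 0.0;
  // interior reference point
  double ox = (pts(i0, 0) + pts(i1, 0) + pts(i2, 0) + pts(i3, 0)) / 4.0;
  double oy = (pts(i0, 1) + pts(i1, 1) + pts(i2, 1) + pts(i3, 1)) / 4.0;
  double oz = (pts(i0, 2) + pts(i1, 2) + pts(i2, 2) + pts(i3, 2)) / 4.0;
  std::vector<HFace> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int t = 0; t < 4; t++) {
    HFace f = make_face(pts, tet[t][0], tet[t][1], tet[t][2]);
    if (f.nx * ox + f.ny * oy + f.nz * oz - f.off > 0) {
      std::swap(f.b, f.c);
      f = make_face(pts, f.a, f.b, f.c);
    }
    faces.push_back(f);
  }
  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t fi = 0; fi < faces.size(); fi++) {
      if (!faces[fi].alive) continue;
      double d = faces[fi].nx * pts(i, 0) + faces[fi].ny * pts(i, 1) +
                 faces[fi].nz * pts(i, 2) - faces[fi].off;
      if (d > eps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue;
    std::set<std::pair<int, int> > vedges;
    for (size_t vi = 0; vi < visible.size(); vi++) {
      HFace &f = faces[visible[vi]];
      vedges.insert(std::make_pair(f.a, f.b));
      vedges.insert(std::make_pair(f.b, f.c));
      vedges.insert(std::make_pair(f.c, f.a));
      f.alive = false;
    }
    for (std::set<std::pair<int, int> >::iterator it = vedges.begin();
         it != vedges.end(); ++it) {
      if (vedges.count(std::make_pair(it->second, it->first))) continue;
      HFace f = make_face(pts, it->first, it->second, i);
      if (f.nx * ox + f.ny * oy + f.nz * oz - f.off > 0) {
        std::swap(f.b, f.c);
        f = make_face(pts, f.a, f.b, f.c);
      }
      faces.push_back(f);
    }
  }
  double vol = 0.0;
  for (size_t fi = 0; fi < faces.size(); fi++) {
    if (!faces[fi].alive) continue;
    const HFace &f = faces[fi];
    double a1 = pts(f.a, 0) - ox, a2 = pts(f.a, 1) - oy, a3 = pts(f.a, 2) - oz;
    double b1 = pts(f.b, 0) - ox, b2 = pts(f.b, 1) - oy, b3 = pts(f.b, 2) - oz;
    double c1 = pts(f.c, 0) - ox, c2 = pts(f.c, 1) - oy, c3 = pts(f.c, 2) - oz;
    vol += std::fabs(a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
                     a3 * (b1 * c2 - b2 * c1)) /
           6.0;
  }
  return vol;
}
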