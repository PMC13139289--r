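#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Column-major linear index for an (nx, ny, nz) array, 0-based.
static inline int64_t lin(int i, int j, int k, int nx, int ny) {
  return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * (int64_t)k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian filter with zero (constant) boundary.  sigma is in
// voxels; the kernel is truncated at ceil(3.5 * sigma) and renormalised.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".gaussian_filter3d")]]
NumericVector gaussian_filter3d(NumericVector arr, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(arr);
  const int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (auto &v : ker) v /= s;

  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(nx - 1, i + r);
        for (int t = lo; t <= hi; ++t) acc += ker[t - i + r] * a[lin(t, j, k, nx, ny)];
        b[lin(i, j, k, nx, ny)] = acc;
      }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double acc = 0.0;
        const int lo = std::max(0, j - r), hi = std::min(ny - 1, j + r);
        for (int t = lo; t <= hi; ++t) acc += ker[t - j + r] * b[lin(i, t, k, nx, ny)];
        a[lin(i, j, k, nx, ny)] = acc;
      }
  // z axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double acc = 0.0;
        const int lo = std::max(0, k - r), hi = std::min(nz - 1, k + r);
        for (int t = lo; t <= hi; ++t) acc += ker[t - k + r] * a[lin(i, j, t, nx, ny)];
        b[lin(i, j, k, nx, ny)] = acc;
      }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching tetrahedra on the Kuhn (6-tetrahedron)
// decomposition of each grid cell.  The decomposition is translation
// invariant, so triangulated diagonals agree between neighbouring cells and
// the extracted surface is watertight by construction.  Vertices are placed
// by linear interpolation along tetrahedron edges and shared through a
// global edge table.  Triangles are wound so that face normals point from
// the "inside" (field > level) to the "outside".
// ---------------------------------------------------------------------------
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector field, IntegerVector dim,
                         double level, NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double eps = 1e-9 * std::max(1.0, std::abs(level));

  // Node values with exact-level ties nudged to the outside so that no
  // surface vertex coincides with a grid node (prevents zero-area faces).
  std::vector<double> f(field.begin(), field.end());
  for (auto &v : f) if (std::abs(v - level) < eps) v = level - eps;

  std::unordered_map<int64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto node_world = [&](int64_t id, double *p) {
    const int i = (int)(id % nx);
    const int j = (int)((id / nx) % ny);
    const int k = (int)(id / ((int64_t)nx * ny));
    p[0] = ox + i * sx; p[1] = oy + j * sy; p[2] = oz + k * sz;
  };

  auto vertex_on_edge = [&](int64_t a, int64_t b) -> int {
    if (a > b) std::swap(a, b);
    const int64_t key = a * (int64_t)nx * ny * nz + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    node_world(a, pa); node_world(b, pb);
    const double fa = f[a], fb = f[b];
    const double t = (level - fa) / (fb - fa);
    const int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex[key] = id;
    return id;
  };

  // Emit one triangle given its three edge-vertices plus inside/outside
  // reference points for orientation.
  auto emit = [&](int va, int vb, int vc,
                  const double *cin, const double *cout) {
    const double ux = vx[vb] - vx[va], uy = vy[vb] - vy[va], uz = vz[vb] - vz[va];
    const double wx_ = vx[vc] - vx[va], wy_ = vy[vc] - vy[va], wz_ = vz[vc] - vz[va];
    const double nxv = uy * wz_ - uz * wy_;
    const double nyv = uz * wx_ - ux * wz_;
    const double nzv = ux * wy_ - uy * wx_;
    const double dx = cout[0] - cin[0], dy = cout[1] - cin[1], dz = cout[2] - cin[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(vb, vc);
    f0.push_back(va); f1.push_back(vb); f2.push_back(vc);
  };

  int64_t cid[8]; bool cin[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          cid[c] = lin(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2], nx, ny);
          cin[c] = f[cid[c]] > level;
          n_in += cin[c];
        }
        if (n_in == 0 || n_in == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t tid[4]; bool tin[4]; int ti = 0;
          for (int c = 0; c < 4; ++c) {
            tid[c] = cid[TETS[t][c]];
            tin[c] = cin[TETS[t][c]];
            ti += tin[c];
          }
          if (ti == 0 || ti == 4) continue;
          // inside / outside reference centroids
          double pin[3] = {0, 0, 0}, pout[3] = {0, 0, 0}, p[3];
          for (int c = 0; c < 4; ++c) {
            node_world(tid[c], p);
            double *dst = tin[c] ? pin : pout;
            dst[0] += p[0]; dst[1] += p[1]; dst[2] += p[2];
          }
          for (int d = 0; d < 3; ++d) { pin[d] /= ti; pout[d] /= (4 - ti); }
          if (ti == 1 || ti == 3) {
            int apex = -1;
            for (int c = 0; c < 4; ++c)
              if (tin[c] == (ti == 1)) apex = c;
            int tri[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) tri[m++] = vertex_on_edge(tid[apex], tid[c]);
            emit(tri[0], tri[1], tri[2], pin, pout);
          } else { // 2 in, 2 out -> quad split into two triangles
            int ain = -1, bin_ = -1, aout = -1, bout = -1;
            for (int c = 0; c < 4; ++c) {
              if (tin[c]) { if (ain < 0) ain = c; else bin_ = c; }
              else        { if (aout < 0) aout = c; else bout = c; }
            }
            const int vac = vertex_on_edge(tid[ain], tid[aout]);
            const int vad = vertex_on_edge(tid[ain], tid[bout]);
            const int vbc = vertex_on_edge(tid[bin_], tid[aout]);
            const int vbd = vertex_on_edge(tid[bin_], tid[bout]);
            emit(vac, vad, vbd, pin, pout);
            emit(vac, vbd, vbc, pin, pout);
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix Fm(nf, 3);
  for (int q = 0; q < nf; ++q) { Fm(q, 0) = f0[q] + 1; Fm(q, 1) = f1[q] + 1; Fm(q, 2) = f2[q] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary volume under 6- or
// 26-adjacency (iterative flood fill).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const int64_t cur = stack.back(); stack.pop_back();
      const int ci = (int)(cur % nx);
      const int cj = (int)((cur / nx) % ny);
      const int ck = (int)(cur / ((int64_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1) continue;
            const int i2 = ci + di, j2 = cj + dj, k2 = ck + dk;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
            const int64_t t = lin(i2, j2, k2, nx, ny);
            if (mask[t] != 0 && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Opposing-face thickness.  For every face i, T(i) is the minimum
// centroid-to-centroid distance over faces j with dot(N_i, N_j) < 0
// (strictly).  Ties in distance are broken by the lowest face index.
// Faces without candidates get NA.  Brute force is the reference O(F^2)
// definition; the grid version returns the identical result using a
// uniform spatial hash with a provable stopping radius: after all cells
// within Chebyshev radius R of the query cell have been visited, every
// unvisited point lies at Euclidean distance >= R * cell_size.
// ---------------------------------------------------------------------------

struct FlatPoints {
  std::vector<double> x, y, z;
  explicit FlatPoints(const NumericMatrix &m)
    : x(m.nrow()), y(m.nrow()), z(m.nrow()) {
    for (int i = 0; i < m.nrow(); ++i) { x[i] = m(i,0); y[i] = m(i,1); z[i] = m(i,2); }
  }
  int n() const { return (int)x.size(); }
};

static inline double d2(const FlatPoints &a, int i, const FlatPoints &b, int j) {
  const double dx = a.x[i] - b.x[j], dy = a.y[i] - b.y[j], dz = a.z[i] - b.z[j];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(name = ".thickness_brute")]]
List thickness_brute(NumericMatrix cen, NumericMatrix nrm) {
  const int F = cen.nrow();
  FlatPoints C(cen), N(nrm);
  NumericVector T(F, NA_REAL);
  IntegerVector P(F, NA_INTEGER);
  for (int i = 0; i < F; ++i) {
    double best = R_PosInf; int bj = -1;
    for (int j = 0; j < F; ++j) {
      if (j == i) continue;
      if (N.x[i] * N.x[j] + N.y[i] * N.y[j] + N.z[i] * N.z[j] >= 0) continue;
      const double dd = d2(C, i, C, j);
      if (dd < best) { best = dd; bj = j; }
    }
    if (bj >= 0) { T[i] = std::sqrt(best); P[i] = bj + 1; }
  }
  return List::create(_["thickness"] = T, _["pair"] = P);
}

// Uniform grid over points with contiguous (CSR) cell storage.
struct CellGrid {
  double h, x0, y0, z0;
  int gx, gy, gz;
  std::vector<int> start, items;
  CellGrid(const FlatPoints &P, double cell) {
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int i = 0; i < P.n(); ++i) {
      xmin = std::min(xmin, P.x[i]); xmax = std::max(xmax, P.x[i]);
      ymin = std::min(ymin, P.y[i]); ymax = std::max(ymax, P.y[i]);
      zmin = std::min(zmin, P.z[i]); zmax = std::max(zmax, P.z[i]);
    }
    h = cell; x0 = xmin; y0 = ymin; z0 = zmin;
    gx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    gy = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    gz = std::max(1, (int)std::floor((zmax - zmin) / h) + 1);
    const size_t nc = (size_t)gx * gy * gz;
    std::vector<int> count(nc, 0);
    std::vector<int> cell_of(P.n());
    for (int i = 0; i < P.n(); ++i) {
      cell_of[i] = (int)cell_index(P.x[i], P.y[i], P.z[i]);
      ++count[cell_of[i]];
    }
    start.assign(nc + 1, 0);
    for (size_t c = 0; c < nc; ++c) start[c + 1] = start[c] + count[c];
    items.resize(P.n());
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < P.n(); ++i) items[fill[cell_of[i]]++] = i;
  }
  size_t cell_index(double x, double y, double z) const {
    const int cx = std::min(gx - 1, std::max(0, (int)std::floor((x - x0) / h)));
    const int cy = std::min(gy - 1, std::max(0, (int)std::floor((y - y0) / h)));
    const int cz = std::min(gz - 1, std::max(0, (int)std::floor((z - z0) / h)));
    return (size_t)cx + (size_t)gx * ((size_t)cy + (size_t)gy * (size_t)cz);
  }
  void coords(double x, double y, double z, int *c) const {
    c[0] = std::min(gx - 1, std::max(0, (int)std::floor((x - x0) / h)));
    c[1] = std::min(gy - 1, std::max(0, (int)std::floor((y - y0) / h)));
    c[2] = std::min(gz - 1, std::max(0, (int)std::floor((z - z0) / h)));
  }
  // visit every in-range cell of the Chebyshev shell at radius R
  template <typename Fn>
  void shell(const int *c0, int R, Fn fn) const {
    const int xlo = std::max(0, c0[0] - R), xhi = std::min(gx - 1, c0[0] + R);
    const int ylo = std::max(0, c0[1] - R), yhi = std::min(gy - 1, c0[1] + R);
    const int zlo = std::max(0, c0[2] - R), zhi = std::min(gz - 1, c0[2] + R);
    if (R == 0) { visit(c0[0], c0[1], c0[2], fn); return; }
    for (int cz = zlo; cz <= zhi; ++cz) {
      const bool zface = (cz == c0[2] - R || cz == c0[2] + R);
      for (int cy = ylo; cy <= yhi; ++cy) {
        const bool yface = (cy == c0[1] - R || cy == c0[1] + R);
        if (zface || yface) {
          for (int cx = xlo; cx <= xhi; ++cx) visit(cx, cy, cz, fn);
        } else {
          if (c0[0] - R >= 0) visit(c0[0] - R, cy, cz, fn);
          if (c0[0] + R <= gx - 1) visit(c0[0] + R, cy, cz, fn);
        }
      }
    }
  }
  template <typename Fn>
  void visit(int cx, int cy, int cz, Fn fn) const {
    const size_t c = (size_t)cx + (size_t)gx * ((size_t)cy + (size_t)gy * (size_t)cz);
    for (int t = start[c]; t < start[c + 1]; ++t) fn(items[t]);
  }
  int rmax() const { return gx + gy + gz + 2; }
};

static double heuristic_cell(const FlatPoints &P, double mult) {
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int i = 0; i < P.n(); ++i) {
    xmin = std::min(xmin, P.x[i]); xmax = std::max(xmax, P.x[i]);
    ymin = std::min(ymin, P.y[i]); ymax = std::max(ymax, P.y[i]);
    zmin = std::min(zmin, P.z[i]); zmax = std::max(zmax, P.z[i]);
  }
  const double vol = std::max(1e-9, (xmax - xmin) * (ymax - ymin) * (zmax - zmin));
  return std::max(1e-6, mult * std::cbrt(vol / std::max(1, P.n())));
}

// [[Rcpp::export(name = ".thickness_grid")]]
List thickness_grid(NumericMatrix cen, NumericMatrix nrm) {
  const int F = cen.nrow();
  FlatPoints C(cen), N(nrm);
  NumericVector T(F, NA_REAL);
  IntegerVector P(F, NA_INTEGER);
  const double h = heuristic_cell(C, 4.0);
  CellGrid G(C, h);
  const int Rmax = G.rmax();
  for (int i = 0; i < F; ++i) {
    int c0[3];
    G.coords(C.x[i], C.y[i], C.z[i], c0);
    double best = R_PosInf; int bj = -1;
    const double nix = N.x[i], niy = N.y[i], niz = N.z[i];
    for (int R = 0; R <= Rmax; ++R) {
      G.shell(c0, R, [&](int j) {
        if (j == i) return;
        if (nix * N.x[j] + niy * N.y[j] + niz * N.z[j] >= 0) return;
        const double dd = d2(C, i, C, j);
        if (dd < best || (dd == best && j < bj)) { best = dd; bj = j; }
      });
      if (bj >= 0 && best <= (double)R * h * (double)R * h) break;
    }
    if (bj >= 0) { T[i] = std::sqrt(best); P[i] = bj + 1; }
  }
  return List::create(_["thickness"] = T, _["pair"] = P);
}

// ---------------------------------------------------------------------------
// k nearest target faces (by centroid distance) for each query point.
// Ties broken by lowest target index after the distance sort.  Brute and
// grid versions return identical index matrices.
// ---------------------------------------------------------------------------

static void sort_take_k(std::vector<std::pair<double, int>> &cand, int k,
                        IntegerMatrix &out, int row) {
  std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
  for (int m = 0; m < k; ++m) out(row, m) = cand[m].second + 1;
}

// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix query, NumericMatrix target, int k) {
  FlatPoints Q(query), Tg(target);
  const int nq = Q.n(), nt = Tg.n();
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int>> cand(nt);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nt; ++j) cand[j] = {d2(Q, i, Tg, j), j};
    std::vector<std::pair<double, int>> c2(cand);
    sort_take_k(c2, k, out, i);
  }
  return out;
}

// [[Rcpp::export(name = ".knn_grid")]]
IntegerMatrix knn_grid(NumericMatrix query, NumericMatrix target, int k) {
  FlatPoints Q(query), Tg(target);
  const int nq = Q.n();
  IntegerMatrix out(nq, k);
  const double h = heuristic_cell(Tg, 6.0);
  CellGrid G(Tg, h);
  const int Rmax = G.rmax();
  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < nq; ++i) {
    cand.clear();
    int c0[3];
    G.coords(Q.x[i], Q.y[i], Q.z[i], c0);
    for (int R = 0; R <= Rmax; ++R) {
      G.shell(c0, R, [&](int j) { cand.push_back({d2(Q, i, Tg, j), j}); });
      if ((int)cand.size() >= k) {
        std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
        if (cand[k - 1].first <= (double)R * h * (double)R * h) break;
      }
    }
    sort_take_k(cand, k, out, i);
  }
  return out;
}
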