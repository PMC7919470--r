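#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <stack>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Voxel grids are passed as flat integer/logical vectors in R array order
// (x fastest), with dims = (nx, ny, nz). Index helper:
static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// 26-connected component labelling of a binary mask.
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::stack<int> st;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    st.push((int)s);
    lab[s] = next;
    while (!st.empty()) {
      int cur = st.top(); st.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t q = vidx(ii, jj, kk, nx, ny);
            if (mask[q] && !lab[q]) { lab[q] = next; st.push((int)q); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Separable box min/max filter (binary dilation/erosion with a rectangular
// structuring element of full size (kx, ky, kz), each odd).
static void line_filter(std::vector<int>& buf, std::vector<int>& out, int n,
                        int r, bool take_max) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    int v = take_max ? 0 : 1;
    for (int t = lo; t <= hi; ++t) {
      if (take_max) { if (buf[t]) { v = 1; break; } }
      else          { if (!buf[t]) { v = 0; break; } }
    }
    out[i] = v;
  }
}

// [[Rcpp::export(name = ".box_filter")]]
LogicalVector box_filter(LogicalVector mask, IntegerVector dims,
                         IntegerVector kernel, bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = (kernel[0] - 1) / 2, ry = (kernel[1] - 1) / 2, rz = (kernel[2] - 1) / 2;
  std::vector<int> a(mask.size());
  for (R_xlen_t s = 0; s < mask.size(); ++s) a[s] = mask[s] ? 1 : 0;
  std::vector<int> line, outl;
  // x pass
  if (rx > 0) {
    line.resize(nx); outl.resize(nx);
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) line[i] = a[vidx(i, j, k, nx, ny)];
      line_filter(line, outl, nx, rx, dilate);
      for (int i = 0; i < nx; ++i) a[vidx(i, j, k, nx, ny)] = outl[i];
    }
  }
  if (ry > 0) {
    line.resize(ny); outl.resize(ny);
    for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = a[vidx(i, j, k, nx, ny)];
      line_filter(line, outl, ny, ry, dilate);
      for (int j = 0; j < ny; ++j) a[vidx(i, j, k, nx, ny)] = outl[j];
    }
  }
  if (rz > 0) {
    line.resize(nz); outl.resize(nz);
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = a[vidx(i, j, k, nx, ny)];
      line_filter(line, outl, nz, rz, dilate);
      for (int k = 0; k < nz; ++k) a[vidx(i, j, k, nx, ny)] = outl[k];
    }
  }
  LogicalVector res(mask.size());
  for (R_xlen_t s = 0; s < mask.size(); ++s) res[s] = a[s] != 0;
  return res;
}

// Surface extraction at the 0.5 iso-level of a binary mask: every voxel face
// between an inside voxel and an outside (or out-of-grid) voxel becomes two
// triangles with outward orientation. Vertices are welded on the corner
// lattice, then mapped to physical mm via spacing/origin (voxel centre i at
// origin + i*spacing).
// [[Rcpp::export(name = ".mask_to_mesh")]]
List mask_to_mesh(LogicalVector mask, IntegerVector dims,
                  NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<long long, int> corner_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  long long NY = ny + 1, NZ = nz + 1;
  auto corner = [&](int ci, int cj, int ck) -> int {
    long long key = ((long long)ci * NY + cj) * NZ + ck;
    auto it = corner_id.find(key);
    if (it != corner_id.end()) return it->second;
    int id = (int)vx.size();
    corner_id.emplace(key, id);
    vx.push_back(origin[0] + (ci - 0.5) * spacing[0]);
    vy.push_back(origin[1] + (cj - 0.5) * spacing[1]);
    vz.push_back(origin[2] + (ck - 0.5) * spacing[2]);
    return id;
  };
  auto inside = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[vidx(i, j, k, nx, ny)];
  };
  auto quad = [&](int a, int b, int c, int d) {
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
    f0.push_back(a); f1.push_back(c); f2.push_back(d);
  };
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (!inside(i, j, k)) continue;
    // +x / -x faces: quad in (y,z) at plane i+1 / i
    if (!inside(i + 1, j, k))
      quad(corner(i + 1, j, k), corner(i + 1, j + 1, k),
           corner(i + 1, j + 1, k + 1), corner(i + 1, j, k + 1));
    if (!inside(i - 1, j, k))
      quad(corner(i, j, k), corner(i, j, k + 1),
           corner(i, j + 1, k + 1), corner(i, j + 1, k));
    // +y / -y: cycle (z, x)
    if (!inside(i, j + 1, k))
      quad(corner(i, j + 1, k), corner(i, j + 1, k + 1),
           corner(i + 1, j + 1, k + 1), corner(i + 1, j + 1, k));
    if (!inside(i, j - 1, k))
      quad(corner(i, j, k), corner(i + 1, j, k),
           corner(i + 1, j, k + 1), corner(i, j, k + 1));
    // +z / -z: cycle (x, y)
    if (!inside(i, j, k + 1))
      quad(corner(i, j, k + 1), corner(i + 1, j, k + 1),
           corner(i + 1, j + 1, k + 1), corner(i, j + 1, k + 1));
    if (!inside(i, j, k - 1))
      quad(corner(i, j, k), corner(i, j + 1, k),
           corner(i + 1, j + 1, k), corner(i + 1, j, k));
  }
  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int s = 0; s < nv; ++s) { V(s, 0) = vx[s]; V(s, 1) = vy[s]; V(s, 2) = vz[s]; }
  IntegerMatrix F(nf, 3);
  for (int s = 0; s < nf; ++s) { F(s, 0) = f0[s]; F(s, 1) = f1[s]; F(s, 2) = f2[s]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
};

// Ericson: closest point on triangle abc to point p.
static V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) { double v = d1 / (d1 - d3); return a + ab * v; }
  V3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) { double w = d2 / (d2 - d6); return a + ac * w; }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// Closest surface point (and owning face, 0-based) for each query point.
// [[Rcpp::export(name = ".closest_point_on_mesh")]]
List closest_point_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericMatrix Q(np, 3);
  NumericVector d(np);
  IntegerVector face(np);
  for (int s = 0; s < np; ++s) {
    V3 p(P(s, 0), P(s, 1), P(s, 2));
    double best = R_PosInf; V3 bq; int bf = -1;
    for (int t = 0; t < nf; ++t) {
      V3 a(V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2));
      V3 b(V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2));
      V3 c(V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2));
      V3 q = closest_on_tri(p, a, b, c);
      V3 dq = p - q;
      double dd = dq.dot(dq);
      if (dd < best) { best = dd; bq = q; bf = t; }
    }
    Q(s, 0) = bq.x; Q(s, 1) = bq.y; Q(s, 2) = bq.z;
    d[s] = std::sqrt(best); face[s] = bf;
  }
  return List::create(_["points"] = Q, _["distance"] = d, _["face"] = face);
}

// Ray-parity inside test, ray along +x from each query point.
// [[Rcpp::export(name = ".points_in_mesh")]]
LogicalVector points_in_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  LogicalVector res(np);
  for (int s = 0; s < np; ++s) {
    double py = P(s, 1), pz = P(s, 2), px = P(s, 0);
    int crossings = 0;
    for (int t = 0; t < nf; ++t) {
      double y0 = V(F(t, 0), 1), z0 = V(F(t, 0), 2), x0 = V(F(t, 0), 0);
      double y1 = V(F(t, 1), 1), z1 = V(F(t, 1), 2), x1 = V(F(t, 1), 0);
      double y2 = V(F(t, 2), 1), z2 = V(F(t, 2), 2), x2 = V(F(t, 2), 0);
      double det = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
      if (std::fabs(det) < 1e-14) continue;
      double u = ((py - y0) * (z2 - z0) - (pz - z0) * (y2 - y0)) / det;
      double v = ((y1 - y0) * (pz - z0) - (z1 - z0) * (py - y0)) / det;
      if (u < 0 || v < 0 || u + v > 1) continue;
      double xi = x0 + u * (x1 - x0) + v * (x2 - x0);
      if (xi > px) ++crossings;
    }
    res[s] = (crossings % 2) == 1;
  }
  return res;
}

// Voxelize a closed mesh by x-column ray parity: voxel centres whose x lies
// inside an odd crossing interval are marked. Grid: centre of voxel (i,j,k)
// at origin + (i,j,k)*spacing.
// [[Rcpp::export(name = ".voxelize_mesh")]]
LogicalVector voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nf = F.nrow();
  std::vector<std::vector<double> > cross((size_t)ny * nz);
  for (int t = 0; t < nf; ++t) {
    double y0 = V(F(t, 0), 1), z0 = V(F(t, 0), 2), x0 = V(F(t, 0), 0);
    double y1 = V(F(t, 1), 1), z1 = V(F(t, 1), 2), x1 = V(F(t, 1), 0);
    double y2 = V(F(t, 2), 1), z2 = V(F(t, 2), 2), x2 = V(F(t, 2), 0);
    double det = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
    if (std::fabs(det) < 1e-14) continue;
    double ylo = std::min(y0, std::min(y1, y2)), yhi = std::max(y0, std::max(y1, y2));
    double zlo = std::min(z0, std::min(z1, z2)), zhi = std::max(z0, std::max(z1, z2));
    int jlo = std::max(0, (int)std::ceil((ylo - origin[1]) / spacing[1]));
    int jhi = std::min(ny - 1, (int)std::floor((yhi - origin[1]) / spacing[1]));
    int klo = std::max(0, (int)std::ceil((zlo - origin[2]) / spacing[2]));
    int khi = std::min(nz - 1, (int)std::floor((zhi - origin[2]) / spacing[2]));
    for (int k = klo; k <= khi; ++k) for (int j = jlo; j <= jhi; ++j) {
      double yc = origin[1] + j * spacing[1];
      double zc = origin[2] + k * spacing[2];
      double u = ((yc - y0) * (z2 - z0) - (zc - z0) * (y2 - y0)) / det;
      double v = ((y1 - y0) * (zc - z0) - (z1 - z0) * (yc - y0)) / det;
      if (u < 0 || v < 0 || u + v > 1) continue;
      double xi = x0 + u * (x1 - x0) + v * (x2 - x0);
      cross[(size_t)j + (size_t)ny * k].push_back(xi);
    }
  }
  LogicalVector res((R_xlen_t)nx * ny * nz, false);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    std::vector<double>& xs = cross[(size_t)j + (size_t)ny * k];
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    size_t m = xs.size() - (xs.size() % 2);  // drop unpaired stragglers
    for (size_t q = 0; q + 1 < m; q += 2) {
      int ilo = std::max(0, (int)std::ceil((xs[q] - origin[0]) / spacing[0]));
      int ihi = std::min(nx - 1, (int)std::floor((xs[q + 1] - origin[0]) / spacing[0]));
      for (int i = ilo; i <= ihi; ++i) res[vidx(i, j, k, nx, ny)] = true;
    }
  }
  return res;
}
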