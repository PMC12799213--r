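#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling on a logical array.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int k = -1; k <= 1; ++k)
    for (int j = -1; j <= 1; ++j)
      for (int i = -1; i <= 1; ++i) {
        if (i == 0 && j == 0 && k == 0) continue;
        int m = std::abs(i) + std::abs(j) + std::abs(k);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(i); dy.push_back(j); dz.push_back(k);
      }
  const int nn = (int)dx.size();

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; ++q) {
        int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Boundary voxels of one label: voxels of the component with at least one
// 6-neighbour outside the component (array border counts as outside).
// [[Rcpp::export(name = ".boundary_mask_3d")]]
LogicalVector boundary_mask_3d(IntegerVector labels, IntegerVector dims, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dz[6] = {0,0,0,0,1,-1};
  for (R_xlen_t v = 0; v < n; ++v) {
    if (labels[v] != label) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
    bool bd = false;
    for (int q = 0; q < 6 && !bd; ++q) {
      int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) { bd = true; break; }
      R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (labels[w] != label) bd = true;
    }
    out[v] = bd;
  }
  out.attr("dim") = dims;
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt_1d(const double *f, double *d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Euclidean distance transform: distance (physical units) from every voxel
// to the nearest voxel where mask is TRUE. Anisotropic spacing supported.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
      edt_1d(buf.data(), res.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = res[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
      edt_1d(buf.data(), res.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = res[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) buf[z] = out[base + (R_xlen_t)z * nx * ny];
      edt_1d(buf.data(), res.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = res[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double cx = u[1]*v[2] - u[2]*v[1];
  double cy = u[2]*v[0] - u[0]*v[2];
  double cz = u[0]*v[1] - u[1]*v[0];
  return 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
}

// Isosurface area by marching tetrahedra (Kuhn triangulation of each grid
// cell) on a scalar field sampled at voxel centres with anisotropic spacing.
// When collect_points is true, the triangle vertices are also returned
// (sub-voxel surface samples used for surface-to-surface distances).
static SEXP isosurface_core(NumericVector field, IntegerVector dims,
                            NumericVector spacing, double level,
                            bool collect_points);

// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector field, IntegerVector dims,
                       NumericVector spacing, double level) {
  return as<List>(isosurface_core(field, dims, spacing, level, false))["area"];
}

// [[Rcpp::export(name = ".isosurface_mesh")]]
List isosurface_mesh(NumericVector field, IntegerVector dims,
                     NumericVector spacing, double level) {
  return as<List>(isosurface_core(field, dims, spacing, level, true));
}

static SEXP isosurface_core(NumericVector field, IntegerVector dims,
                            NumericVector spacing, double level,
                            bool collect_points) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, bit0 = x, bit1 = y, bit2 = z
  const int cx[8] = {0,1,0,1,0,1,0,1};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  // Kuhn triangulation: 6 tetrahedra sharing diagonal 0-7
  const int tets[6][4] = {
    {0,1,3,7}, {0,1,5,7}, {0,2,3,7}, {0,2,6,7}, {0,4,5,7}, {0,4,6,7}
  };
  double area = 0.0;
  std::vector<double> pts;
  double val[8], px[8], py[8], pz[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          R_xlen_t idx = (R_xlen_t)(z + cz[c]) * nx * ny +
                         (R_xlen_t)(y + cy[c]) * nx + (x + cx[c]);
          val[c] = field[idx];
          px[c] = (x + cx[c]) * sx;
          py[c] = (y + cy[c]) * sy;
          pz[c] = (z + cz[c]) * sz;
          if (val[c] > level) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int above[4], nab = 0;
          for (int c = 0; c < 4; ++c) if (val[T[c]] > level) above[nab++] = c;
          if (nab == 0 || nab == 4) continue;
          // edge interpolation helper
          auto interp = [&](int a, int b, double out[3]) {
            int va = T[a], vb = T[b];
            double tfrac = (level - val[va]) / (val[vb] - val[va]);
            out[0] = px[va] + tfrac * (px[vb] - px[va]);
            out[1] = py[va] + tfrac * (py[vb] - py[va]);
            out[2] = pz[va] + tfrac * (pz[vb] - pz[va]);
          };
          if (nab == 1 || nab == 3) {
            // single vertex separated: one triangle
            int apex;
            if (nab == 1) apex = above[0];
            else { // find the vertex below
              bool isab[4] = {false,false,false,false};
              for (int q = 0; q < 3; ++q) isab[above[q]] = true;
              apex = 0; while (isab[apex]) ++apex;
            }
            double p0[3], p1[3], p2[3];
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != apex) others[no++] = c;
            interp(apex, others[0], p0);
            interp(apex, others[1], p1);
            interp(apex, others[2], p2);
            area += tri_area(p0, p1, p2);
            if (collect_points) {
              for (int c = 0; c < 3; ++c) pts.push_back(p0[c]);
              for (int c = 0; c < 3; ++c) pts.push_back(p1[c]);
              for (int c = 0; c < 3; ++c) pts.push_back(p2[c]);
            }
          } else {
            // 2 vs 2: quad through the four crossing edges
            int a0 = above[0], a1 = above[1];
            int b0 = -1, b1 = -1;
            for (int c = 0; c < 4; ++c) if (c != a0 && c != a1) { if (b0 < 0) b0 = c; else b1 = c; }
            double q00[3], q01[3], q11[3], q10[3];
            interp(a0, b0, q00);
            interp(a0, b1, q01);
            interp(a1, b1, q11);
            interp(a1, b0, q10);
            area += tri_area(q00, q01, q11);
            area += tri_area(q00, q11, q10);
            if (collect_points) {
              for (int c = 0; c < 3; ++c) pts.push_back(q00[c]);
              for (int c = 0; c < 3; ++c) pts.push_back(q01[c]);
              for (int c = 0; c < 3; ++c) pts.push_back(q11[c]);
              for (int c = 0; c < 3; ++c) pts.push_back(q10[c]);
            }
          }
        }
      }
  NumericMatrix pmat(pts.size() / 3, 3);
  if (collect_points)
    for (R_xlen_t i = 0; i < (R_xlen_t)pts.size() / 3; ++i)
      for (int c = 0; c < 3; ++c) pmat(i, c) = pts[3 * i + c];
  return List::create(_["area"] = area, _["points"] = pmat);
}
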