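#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

// Voxel (i,j,k) lives at physical center ((i+.5)dx, (j+.5)dy, (k+.5)dz).
// Arrays are R-ordered: index = i + nx*(j + ny*k).

// [[Rcpp::export]]
IntegerVector cpp_power_assign(int nx, int ny, int nz,
                               NumericVector spacing,
                               NumericVector center,
                               NumericVector semi_axes,
                               NumericMatrix seeds,
                               NumericVector weights) {
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double ax = semi_axes[0], ay = semi_axes[1], az = semi_axes[2];
  const int n = seeds.nrow();
  IntegerVector out(nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    double z = (k + 0.5) * dz, ez = (z - center[2]) / az;
    for (int j = 0; j < ny; ++j) {
      double y = (j + 0.5) * dy, ey = (y - center[1]) / ay;
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * dx, ex = (x - center[0]) / ax;
        int idx = i + nx * (j + ny * k);
        if (ex * ex + ey * ey + ez * ez > 1.0) { out[idx] = 0; continue; }
        int best = 0; double bestd = R_PosInf;
        for (int c = 0; c < n; ++c) {
          double u = x - seeds(c, 0), v = y - seeds(c, 1), w = z - seeds(c, 2);
          double d = u * u + v * v + w * w - weights[c];
          if (d < bestd) { bestd = d; best = c + 1; }
        }
        out[idx] = best;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, int nx, int ny, int nz,
                     NumericVector spacing, int max_label) {
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  NumericVector count(max_label), sx(max_label), sy(max_label), sz(max_label);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lab = labels[i + nx * (j + ny * k)];
        if (lab <= 0 || lab > max_label) continue;
        count[lab - 1] += 1.0;
        sx[lab - 1] += (i + 0.5) * dx;
        sy[lab - 1] += (j + 0.5) * dy;
        sz[lab - 1] += (k + 0.5) * dz;
      }
  for (int c = 0; c < max_label; ++c) {
    if (count[c] > 0) { sx[c] /= count[c]; sy[c] /= count[c]; sz[c] /= count[c]; }
    else { sx[c] = NA_REAL; sy[c] = NA_REAL; sz[c] = NA_REAL; }
  }
  return List::create(_["count"] = count, _["cx"] = sx, _["cy"] = sy, _["cz"] = sz);
}

// Contact areas between 6-adjacent voxels of distinct positive labels.
// Faces normal to x contribute dy*dz, to y dx*dz, to z dx*dy.
// [[Rcpp::export]]
NumericMatrix cpp_contact_areas(IntegerVector labels, int nx, int ny, int nz,
                                NumericVector spacing) {
  const double ax = spacing[1] * spacing[2];
  const double ay = spacing[0] * spacing[2];
  const double az = spacing[0] * spacing[1];
  std::map<std::pair<int, int>, double> acc;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = labels[i + nx * (j + ny * k)];
        if (a <= 0) continue;
        if (i + 1 < nx) {
          int b = labels[(i + 1) + nx * (j + ny * k)];
          if (b > 0 && b != a)
            acc[std::make_pair(std::min(a, b), std::max(a, b))] += ax;
        }
        if (j + 1 < ny) {
          int b = labels[i + nx * ((j + 1) + ny * k)];
          if (b > 0 && b != a)
            acc[std::make_pair(std::min(a, b), std::max(a, b))] += ay;
        }
        if (k + 1 < nz) {
          int b = labels[i + nx * (j + ny * (k + 1))];
          if (b > 0 && b != a)
            acc[std::make_pair(std::min(a, b), std::max(a, b))] += az;
        }
      }
  NumericMatrix out(acc.size(), 3);
  int r = 0;
  for (std::map<std::pair<int, int>, double>::iterator it = acc.begin();
       it != acc.end(); ++it, ++r) {
    out(r, 0) = it->first.first;
    out(r, 1) = it->first.second;
    out(r, 2) = it->second;
  }
  return out;
}

// Per-label count of voxels with at least one 6-neighbor carrying a different
// label (grid boundary counts as outside the cell).
// [[Rcpp::export]]
NumericVector cpp_boundary_counts(IntegerVector labels, int nx, int ny, int nz,
                                  int max_label) {
  NumericVector out(max_label);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lab = labels[i + nx * (j + ny * k)];
        if (lab <= 0 || lab > max_label) continue;
        bool surf = false;
        if (i == 0 || labels[(i - 1) + nx * (j + ny * k)] != lab) surf = true;
        else if (i == nx - 1 || labels[(i + 1) + nx * (j + ny * k)] != lab) surf = true;
        else if (j == 0 || labels[i + nx * ((j - 1) + ny * k)] != lab) surf = true;
        else if (j == ny - 1 || labels[i + nx * ((j + 1) + ny * k)] != lab) surf = true;
        else if (k == 0 || labels[i + nx * (j + ny * (k - 1))] != lab) surf = true;
        else if (k == nz - 1 || labels[i + nx * (j + ny * (k + 1))] != lab) surf = true;
        if (surf) out[lab - 1] += 1.0;
      }
  return out;
}

// 3x3x3 box mean filter, zero padding outside the grid.
// [[Rcpp::export]]
NumericVector cpp_box_smooth3(NumericVector vol, int nx, int ny, int nz) {
  NumericVector out(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di; if (ii < 0 || ii >= nx) continue;
              s += vol[ii + nx * (jj + ny * kk)];
            }
          }
        }
        out[i + nx * (j + ny * k)] = s / 27.0;
      }
  return out;
}

static inline double tri_area(const double *p, const double *q, const double *r) {
  double u[3] = { q[0] - p[0], q[1] - p[1], q[2] - p[2] };
  double v[3] = { r[0] - p[0], r[1] - p[1], r[2] - p[2] };
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Isosurface area by marching tetrahedra (each cube split into 6 tetrahedra
// around the main diagonal) on an anisotropic grid.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector vol, int nx, int ny, int nz,
                   NumericVector spacing, double iso) {
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  // cube corner offsets in (x,y,z) voxel units, bit order (x,y,z)
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  static const int tets[6][4] = {
    {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}
  };
  double total = 0.0;
  double cpos[8][3], v[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double vmin = R_PosInf, vmax = R_NegInf;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          v[c] = vol[ii + nx * (jj + ny * kk)];
          if (v[c] < vmin) vmin = v[c];
          if (v[c] > vmax) vmax = v[c];
          cpos[c][0] = ii * dx; cpos[c][1] = jj * dy; cpos[c][2] = kk * dz;
        }
        if (vmax < iso || vmin >= iso) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = { tets[t][0], tets[t][1], tets[t][2], tets[t][3] };
          int inside[4], outside[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (v[id[c]] >= iso) inside[ni++] = id[c];
            else outside[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;
          double p[4][3];
          // interpolated crossing between corner a (any side) and b
          #define INTERP(dst, a, b) do { \
            double tt = (iso - v[a]) / (v[b] - v[a]); \
            for (int d_ = 0; d_ < 3; ++d_) \
              dst[d_] = cpos[a][d_] + tt * (cpos[b][d_] - cpos[a][d_]); \
          } while (0)
          if (ni == 1) {
            for (int c = 0; c < 3; ++c) INTERP(p[c], inside[0], outside[c]);
            total += tri_area(p[0], p[1], p[2]);
          } else if (ni == 3) {
            for (int c = 0; c < 3; ++c) INTERP(p[c], inside[c], outside[0]);
            total += tri_area(p[0], p[1], p[2]);
          } else {
            INTERP(p[0], inside[0], outside[0]);
            INTERP(p[1], inside[0], outside[1]);
            INTERP(p[2], inside[1], outside[1]);
            INTERP(p[3], inside[1], outside[0]);
            total += tri_area(p[0], p[1], p[2]);
            total += tri_area(p[0], p[2], p[3]);
          }
          #undef INTERP
        }
      }
  return total;
}
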