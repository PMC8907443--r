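#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u0 = b[0] - a[0], u1 = b[1] - a[1], u2 = b[2] - a[2];
  double v0 = c[0] - a[0], v1 = c[1] - a[1], v2 = c[2] - a[2];
  double x = u1 * v2 - u2 * v1;
  double y = u2 * v0 - u0 * v2;
  double z = u0 * v1 - u1 * v0;
  return 0.5 * std::sqrt(x * x + y * y + z * z);
}

// Marching-tetrahedra surface area of the iso-surface of a scalar field.
// The field must already be zero-padded by the caller so the surface closes.
// Each cell is split into 6 tetrahedra sharing the 0-6 diagonal; iso
// crossings are linearly interpolated along edges.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, IntegerVector dim,
                     NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int co[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double area = 0.0;
  double v[8], P[8][3], m[4][3];
  for (int z = 0; z < nz - 1; ++z) {
    for (int y = 0; y < ny - 1; ++y) {
      for (int x = 0; x < nx - 1; ++x) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int xi = x + co[c][0], yi = y + co[c][1], zi = z + co[c][2];
          v[c] = field[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          P[c][0] = xi * spacing[0];
          P[c][1] = yi * spacing[1];
          P[c][2] = zi * spacing[2];
          if (v[c] >= iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], outs[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            int id = tets[t][k];
            if (v[id] >= iso) ins[nin++] = id; else outs[nout++] = id;
          }
          if (nin == 0 || nin == 4) continue;
          // midpoint of the iso crossing on edge (a inside-ish, b)
          #define INTERP(a, b, out)                                   \
            {                                                         \
              double tt = (iso - v[a]) / (v[b] - v[a]);               \
              out[0] = P[a][0] + tt * (P[b][0] - P[a][0]);            \
              out[1] = P[a][1] + tt * (P[b][1] - P[a][1]);            \
              out[2] = P[a][2] + tt * (P[b][2] - P[a][2]);            \
            }
          if (nin == 1) {
            INTERP(ins[0], outs[0], m[0]);
            INTERP(ins[0], outs[1], m[1]);
            INTERP(ins[0], outs[2], m[2]);
            area += tri_area(m[0], m[1], m[2]);
          } else if (nin == 3) {
            INTERP(ins[0], outs[0], m[0]);
            INTERP(ins[1], outs[0], m[1]);
            INTERP(ins[2], outs[0], m[2]);
            area += tri_area(m[0], m[1], m[2]);
          } else {
            INTERP(ins[0], outs[0], m[0]);
            INTERP(ins[0], outs[1], m[1]);
            INTERP(ins[1], outs[1], m[2]);
            INTERP(ins[1], outs[0], m[3]);
            area += tri_area(m[0], m[1], m[2]);
            area += tri_area(m[0], m[2], m[3]);
          }
          #undef INTERP
        }
      }
    }
  }
  return area;
}

// Symmetric grey-level co-occurrence counts. `levels` is 0 outside the ROI
// and 1..ng inside. Returns an ng x ng x n_offsets count array (each pair
// counted in both orders, so every slice is symmetric by construction).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int noff = offsets.nrow();
  NumericVector counts((R_xlen_t)ng * ng * noff);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int li = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (li <= 0) continue;
        for (int o = 0; o < noff; ++o) {
          int xj = x + offsets(o, 0), yj = y + offsets(o, 1),
              zj = z + offsets(o, 2);
          if (xj < 0 || xj >= nx || yj < 0 || yj >= ny || zj < 0 || zj >= nz)
            continue;
          int lj = levels[xj + (R_xlen_t)nx * (yj + (R_xlen_t)ny * zj)];
          if (lj <= 0) continue;
          counts[(li - 1) + ng * ((lj - 1) + (R_xlen_t)ng * o)] += 1.0;
          counts[(lj - 1) + ng * ((li - 1) + (R_xlen_t)ng * o)] += 1.0;
        }
      }
    }
  }
  counts.attr("dim") = IntegerVector::create(ng, ng, noff);
  return counts;
}

// Grey-level run-length counts per direction: ng x maxlen x n_dirs.
// A run starts at a voxel whose backward neighbour along the direction is
// outside the grid, outside the ROI, or of a different level.
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim,
                               IntegerMatrix dirs, int ng, int maxlen) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = dirs.nrow();
  NumericVector counts((R_xlen_t)ng * maxlen * nd);
  for (int d = 0; d < nd; ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int g = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
          if (g <= 0) continue;
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz) {
            int gp = levels[xp + (R_xlen_t)nx * (yp + (R_xlen_t)ny * zp)];
            if (gp == g) continue; // interior of a run
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 &&
                 zn < nz &&
                 levels[xn + (R_xlen_t)nx * (yn + (R_xlen_t)ny * zn)] == g) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          if (len > maxlen) len = maxlen;
          counts[(g - 1) + ng * ((len - 1) + (R_xlen_t)maxlen * d)] += 1.0;
        }
      }
    }
  }
  counts.attr("dim") = IntegerVector::create(ng, maxlen, nd);
  return counts;
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    double local = 0.0;   // plain max over j: auto-vectorizable
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > local) local = d2;
    }
    if (local > best) best = local;
  }
  return std::sqrt(best);
}

static inline double auc_pairs(const std::vector<double> &pos,
                               const std::vector<double> &neg) {
  double s = 0.0;
  for (size_t i = 0; i < pos.size(); ++i) {
    for (size_t j = 0; j < neg.size(); ++j) {
      if (pos[i] > neg[j]) s += 1.0;
      else if (pos[i] == neg[j]) s += 0.5;
    }
  }
  return s / ((double)pos.size() * (double)neg.size());
}

// Stratified (within-class) bootstrap draws of the pair-counting AUC.
// Uses the R RNG so set.seed() controls the draws.
// [[Rcpp::export]]
NumericVector cpp_boot_auc(NumericVector pos, NumericVector neg, int n_boot) {
  const int n1 = pos.size(), n0 = neg.size();
  NumericVector out(n_boot);
  std::vector<double> bp(n1), bn(n0);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n1; ++i) {
      int k = (int)(unif_rand() * n1);
      if (k == n1) k = n1 - 1;
      bp[i] = pos[k];
    }
    for (int j = 0; j < n0; ++j) {
      int k = (int)(unif_rand() * n0);
      if (k == n0) k = n0 - 1;
      bn[j] = neg[k];
    }
    out[b] = auc_pairs(bp, bn);
  }
  return out;
}

// Rasterize a radial tumour model on a voxel subgrid: ellipsoid radius
// plus Gaussian angular bumps (lobulation), multiplied by a zero-mean
// angular ripple (surface corrugation at roughly constant volume). A voxel
// center x is inside when
//   |x - c| <= [r_e(dir) + sum_j amp_j exp(-theta_j^2 invw2_j)]
//              * [1 + sum_k ramp_k cos(romega_k (dir . rv_k) + rphase_k)]
// with r_e the ellipsoid radius along dir and theta_j the angle to bump j.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_radial(IntegerVector dim, NumericVector origin,
                                   NumericVector spacing,
                                   NumericVector center,
                                   NumericVector inv_ax2,
                                   NumericMatrix bump_dir,
                                   NumericVector bump_amp,
                                   NumericVector bump_invw2,
                                   NumericMatrix rip_dir,
                                   NumericVector rip_amp,
                                   NumericVector rip_omega,
                                   NumericVector rip_phase) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nb = bump_amp.size();
  const int nr = rip_amp.size();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  // radius bounds for cheap accept/reject (bump amplitudes are >= 0)
  double rmin = 1.0 / std::sqrt(std::max(inv_ax2[0],
                 std::max(inv_ax2[1], inv_ax2[2])));
  double rmax = 1.0 / std::sqrt(std::min(inv_ax2[0],
                 std::min(inv_ax2[1], inv_ax2[2])));
  for (int b = 0; b < nb; ++b) rmax += bump_amp[b];
  double rsum = 0.0;
  for (int k = 0; k < nr; ++k) rsum += std::fabs(rip_amp[k]);
  rmax *= (1.0 + rsum);
  rmin *= std::max(0.01, 1.0 - rsum);
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    double pz = origin[2] + z * spacing[2] - center[2];
    for (int y = 0; y < ny; ++y) {
      double py = origin[1] + y * spacing[1] - center[1];
      for (int x = 0; x < nx; ++x, ++idx) {
        double px = origin[0] + x * spacing[0] - center[0];
        double r2 = px * px + py * py + pz * pz;
        if (r2 < 1e-12) { out[idx] = true; continue; }
        if (r2 > rmax * rmax) { out[idx] = false; continue; }
        if (r2 <= rmin * rmin) { out[idx] = true; continue; }
        double r = std::sqrt(r2);
        double ux = px / r, uy = py / r, uz = pz / r;
        double q = ux * ux * inv_ax2[0] + uy * uy * inv_ax2[1] +
                   uz * uz * inv_ax2[2];
        double R = 1.0 / std::sqrt(q);
        for (int b = 0; b < nb; ++b) {
          double c = ux * bump_dir(b, 0) + uy * bump_dir(b, 1) +
                     uz * bump_dir(b, 2);
          if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
          double th = std::acos(c);
          R += bump_amp[b] * std::exp(-th * th * bump_invw2[b]);
        }
        if (nr > 0) {
          double rip = 1.0;
          for (int k = 0; k < nr; ++k) {
            double proj = ux * rip_dir(k, 0) + uy * rip_dir(k, 1) +
                          uz * rip_dir(k, 2);
            rip += rip_amp[k] * std::cos(rip_omega[k] * proj + rip_phase[k]);
          }
          R *= std::max(0.0, rip);
        }
        out[idx] = (r <= R);
      }
    }
  }
  return out;
}
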