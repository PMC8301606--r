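#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear / nearest-neighbour sampling of `vol` at voxel coordinates
// x + u(x)/spacing, where u is a displacement in mm on the same grid.
// method: 0 = trilinear, 1 = nearest neighbour. Out of bounds -> fill.
// [[Rcpp::export]]
NumericVector warp_volume_cpp(NumericVector vol, IntegerVector dim,
                              NumericVector field, NumericVector spacing,
                              int method, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double px = x + field[i] / sx;
        double py = y + field[i + nvox] / sy;
        double pz = z + field[i + 2 * nvox] / sz;
        if (method == 1) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py),
              iz = (int)std::lround(pz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
            out[i] = fill;
          else
            out[i] = vol[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          // clamp-band border handling: positions within half a voxel of
          // the grid are clamped to the edge; only farther ones take fill
          if (px < -0.5 || py < -0.5 || pz < -0.5 || px > nx - 0.5 ||
              py > ny - 0.5 || pz > nz - 0.5) {
            out[i] = fill;
            continue;
          }
          if (px < 0) px = 0;
          if (py < 0) py = 0;
          if (pz < 0) pz = 0;
          if (px > nx - 1) px = nx - 1;
          if (py > ny - 1) py = ny - 1;
          if (pz > nz - 1) pz = nz - 1;
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            int zz = dz ? z1 : z0;
            double wz = dz ? fz : 1 - fz;
            for (int dy = 0; dy <= 1; ++dy) {
              int yy = dy ? y1 : y0;
              double wy = dy ? fy : 1 - fy;
              for (int dx = 0; dx <= 1; ++dx) {
                int xx = dx ? x1 : x0;
                double wx = dx ? fx : 1 - fx;
                acc += wx * wy * wz *
                       vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
              }
            }
          }
          out[i] = acc;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxels, reflected edges.
// [[Rcpp::export]]
NumericVector smooth3_cpp(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(nvox);
  const R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * rad + 1);
    double ksum = 0;
    for (int j = -rad; j <= rad; ++j) {
      k[j + rad] = std::exp(-0.5 * j * j / (s * s));
      ksum += k[j + rad];
    }
    for (auto &v : k) v /= ksum;
    int na = n[axis];
    R_xlen_t st = stride[axis];
    // iterate over all lines along `axis`
    int nb = (axis == 0) ? n[1] : n[0];
    int nc = (axis == 2) ? n[1] : n[2];
    R_xlen_t stb = (axis == 0) ? stride[1] : stride[0];
    R_xlen_t stc = (axis == 2) ? stride[1] : stride[2];
    for (int c = 0; c < nc; ++c) {
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = b * stb + c * stc;
        for (int a = 0; a < na; ++a) {
          double acc = 0;
          for (int j = -rad; j <= rad; ++j) {
            int aj = a + j;
            if (aj < 0) aj = -aj;               // reflect
            if (aj >= na) aj = 2 * na - 2 - aj;
            aj = clampi(aj, 0, na - 1);
            acc += k[j + rad] * buf[base + (R_xlen_t)aj * st];
          }
          tmp[base + (R_xlen_t)a * st] = acc;
        }
      }
    }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Spatial gradient by central differences (one-sided at edges), per mm.
// Returns an (nx*ny*nz*3) vector.
// [[Rcpp::export]]
NumericVector gradient3_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox * 3);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int idx[3] = {x, y, z};
        for (int a = 0; a < 3; ++a) {
          int lo = idx[a] > 0 ? idx[a] - 1 : idx[a];
          int hi = idx[a] < n[a] - 1 ? idx[a] + 1 : idx[a];
          double h = (hi - lo) * spacing[a];
          double d = h > 0
            ? (vol[i + (R_xlen_t)(hi - idx[a]) * stride[a]] -
               vol[i + (R_xlen_t)(lo - idx[a]) * stride[a]]) / h
            : 0.0;
          out[i + (R_xlen_t)a * nvox] = d;
        }
      }
  return out;
}

// Jacobian determinant det(I + du/dx) of a displacement field (mm) by
// central finite differences with spacing-aware derivatives.
// [[Rcpp::export]]
NumericVector jacobian_cpp(NumericVector field, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int idx[3] = {x, y, z};
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          for (int a = 0; a < 3; ++a) {
            int lo = idx[a] > 0 ? idx[a] - 1 : idx[a];
            int hi = idx[a] < n[a] - 1 ? idx[a] + 1 : idx[a];
            double h = (hi - lo) * spacing[a];
            double d = h > 0
              ? (field[i + (R_xlen_t)(hi - idx[a]) * stride[a] + (R_xlen_t)c * nvox] -
                 field[i + (R_xlen_t)(lo - idx[a]) * stride[a] + (R_xlen_t)c * nvox]) / h
              : 0.0;
            J[c][a] = d + (a == c ? 1.0 : 0.0);
          }
        }
        out[i] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                 J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                 J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Trilinear resampling to a new grid, align-corners convention: voxel
// centre i of the new grid sits at source position i*(n-1)/(m-1), so grid
// positions coincide in world coordinates (origin at voxel 0).
// [[Rcpp::export]]
NumericVector resample3_cpp(NumericVector vol, IntegerVector dim,
                            IntegerVector newdim, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = newdim[0], my = newdim[1], mz = newdim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  double rx = mx > 1 ? (double)(nx - 1) / (mx - 1) : 0.0;
  double ry = my > 1 ? (double)(ny - 1) / (my - 1) : 0.0;
  double rz = mz > 1 ? (double)(nz - 1) / (mz - 1) : 0.0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        double px = x * rx;
        double py = y * ry;
        double pz = z * rz;
        px = std::min(std::max(px, 0.0), (double)(nx - 1));
        py = std::min(std::max(py, 0.0), (double)(ny - 1));
        pz = std::min(std::max(pz, 0.0), (double)(nz - 1));
        R_xlen_t o = x + (R_xlen_t)mx * (y + (R_xlen_t)my * z);
        if (method == 1) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py),
              iz = (int)std::lround(pz);
          out[o] = vol[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
                acc += w * vol[(dx ? x1 : x0) +
                               (R_xlen_t)nx * ((dy ? y1 : y0) +
                                               (R_xlen_t)ny * (dz ? z1 : z0))];
              }
          out[o] = acc;
        }
      }
  return out;
}

static void rank_avg(const std::vector<double> &v, std::vector<double> &r) {
  int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  r.resize(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;  // average rank, 1-based
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

// Per-column Spearman rank correlation of X (n x V) against y, with
// listwise deletion of non-finite pairs per column; average ranks for ties.
// Returns rho and the n used per column (rho = NA for degenerate columns).
// [[Rcpp::export]]
List spearman_cols_cpp(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), V = X.ncol();
  NumericVector rho(V);
  IntegerVector nuse(V);
  std::vector<double> xs, ys, rx, ry;
  for (int v = 0; v < V; ++v) {
    xs.clear(); ys.clear();
    for (int i = 0; i < n; ++i) {
      double xv = X(i, v), yv = y[i];
      if (R_finite(xv) && R_finite(yv)) { xs.push_back(xv); ys.push_back(yv); }
    }
    int m = xs.size();
    nuse[v] = m;
    if (m < 4) { rho[v] = NA_REAL; continue; }
    rank_avg(xs, rx);
    rank_avg(ys, ry);
    double mx = 0, my = 0;
    for (int i = 0; i < m; ++i) { mx += rx[i]; my += ry[i]; }
    mx /= m; my /= m;
    double sxy = 0, sxx = 0, syy = 0;
    for (int i = 0; i < m; ++i) {
      double dx = rx[i] - mx, dy = ry[i] - my;
      sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    if (sxx <= 0 || syy <= 0) { rho[v] = NA_REAL; continue; }
    double r = sxy / std::sqrt(sxx * syy);
    rho[v] = std::min(1.0, std::max(-1.0, r));
  }
  return List::create(_["rho"] = rho, _["n"] = nuse);
}

// 26-connected component labelling of a logical mask; 0 = background.
// [[Rcpp::export]]
IntegerVector label_components26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                zz >= nz)
              continue;
            R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[j] && !lab[j]) {
              lab[j] = cur;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// One multi-resolution level of the constrained demons iteration, fully in
// C++: per iteration warp the moving image by the current field, compute
// Thirion forces from the warped image gradient, cap the step, smooth the
// update (fluid-like) and optionally the accumulated field (diffusion-like),
// and re-freeze constrained voxels. Returns the updated field.
// [[Rcpp::export]]
NumericVector demons_level_cpp(NumericVector ref, NumericVector subj,
                               NumericVector u0, NumericVector constr,
                               LogicalVector frozen, IntegerVector dim,
                               NumericVector spacing, int iters,
                               NumericVector sigma, NumericVector sigma_total,
                               double step_max, double stop_tol) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector u = clone(u0);
  const double ms = (spacing[0] + spacing[1] + spacing[2]) / 3.0;
  std::vector<char> body(nvox);
  R_xlen_t n_body = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    body[i] = ref[i] > 0.05;
    if (body[i]) ++n_body;
  }
  if (n_body == 0) n_body = 1;
  NumericVector du(nvox * 3);
  for (int it = 0; it < iters; ++it) {
    NumericVector warped = warp_volume_cpp(subj, dim, u, spacing, 0, 0.0);
    NumericVector grad = gradient3_cpp(warped, dim, spacing);
    for (R_xlen_t i = 0; i < nvox; ++i) {
      double diff = warped[i] - ref[i];
      double gx = grad[i], gy = grad[i + nvox], gz = grad[i + 2 * nvox];
      double g2 = gx * gx + gy * gy + gz * gz;
      double f = 0.0;
      if (g2 > 1e-9 && std::fabs(diff) > 1e-6)
        f = -diff / (g2 + (diff / ms) * (diff / ms));
      double dx = f * gx, dy = f * gy, dz = f * gz;
      double sl = std::sqrt((dx / spacing[0]) * (dx / spacing[0]) +
                            (dy / spacing[1]) * (dy / spacing[1]) +
                            (dz / spacing[2]) * (dz / spacing[2]));
      if (sl > step_max) {
        double sc = step_max / sl;
        dx *= sc; dy *= sc; dz *= sc;
      }
      du[i] = dx; du[i + nvox] = dy; du[i + 2 * nvox] = dz;
    }
    double upd_sum = 0.0;
    for (int c = 0; c < 3; ++c) {
      NumericVector comp(du.begin() + c * nvox, du.begin() + (c + 1) * nvox);
      NumericVector sm = smooth3_cpp(comp, dim, sigma);
      for (R_xlen_t i = 0; i < nvox; ++i) du[i + c * nvox] = sm[i];
    }
    for (R_xlen_t i = 0; i < nvox; ++i) {
      u[i] += du[i];
      u[i + nvox] += du[i + nvox];
      u[i + 2 * nvox] += du[i + 2 * nvox];
      if (body[i]) {
        double a = du[i] / spacing[0], b = du[i + nvox] / spacing[1],
               cc = du[i + 2 * nvox] / spacing[2];
        upd_sum += std::sqrt(a * a + b * b + cc * cc);
      }
    }
    if (sigma_total[0] > 0 || sigma_total[1] > 0 || sigma_total[2] > 0) {
      for (int c = 0; c < 3; ++c) {
        NumericVector comp(u.begin() + c * nvox, u.begin() + (c + 1) * nvox);
        NumericVector sm = smooth3_cpp(comp, dim, sigma_total);
        for (R_xlen_t i = 0; i < nvox; ++i) u[i + c * nvox] = sm[i];
      }
    }
    for (R_xlen_t i = 0; i < nvox; ++i) {
      if (frozen[i]) {
        u[i] = constr[i];
        u[i + nvox] = constr[i + nvox];
        u[i + 2 * nvox] = constr[i + 2 * nvox];
      }
    }
    if (upd_sum / n_body < stop_tol) break;
  }
  return u;
}
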