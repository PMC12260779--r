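#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parallel-beam geometry conventions shared by all routines:
//  - image pixel (ix, iy), 0-based, centred at (ix - cx, iy - cy), cx = (n-1)/2;
//  - detector bin k centred at s_k = k - (ndet-1)/2, unit = one pixel pitch;
//  - a ray at angle theta and detector coordinate s is r(t) = s*w + t*w_perp,
//    w = (cos t, sin t), w_perp = (-sin t, cos t);
//  - projections are integrals of the image along t (pixel-length units).

static inline double bilinear_sample(const double *img, int nx, int ny,
                                     double x, double y) {
  // x, y are 0-based grid coordinates
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int ix = (int)std::floor(x);
  int iy = (int)std::floor(y);
  if (ix == nx - 1) ix--;
  if (iy == ny - 1) iy--;
  double fx = x - ix, fy = y - iy;
  const double *c = img + (size_t)iy * nx + ix;
  return (1.0 - fx) * (1.0 - fy) * c[0] + fx * (1.0 - fy) * c[1] +
         (1.0 - fx) * fy * c[nx] + fx * fy * c[nx + 1];
}

// Joseph-style ray-driven forward projection of one image (nx x ny) for all
// angles. step is the sampling interval along the ray in pixel units.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector cos_t,
                                  NumericVector sin_t, int ndet, double step) {
  int nx = img.nrow(), ny = img.ncol(), nang = cos_t.size();
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  double cdet = 0.5 * (ndet - 1);
  double T = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) + 1.0;
  int m = (int)std::ceil(2.0 * T / step);
  NumericMatrix out(nang, ndet);
  const double *p = &img(0, 0);
  for (int a = 0; a < nang; a++) {
    double c = cos_t[a], s = sin_t[a];
    for (int k = 0; k < ndet; k++) {
      double sk = k - cdet;
      double acc = 0.0;
      double x0 = sk * c + cx, y0 = sk * s + cy;
      for (int j = 0; j <= m; j++) {
        double t = -T + j * step;
        acc += bilinear_sample(p, nx, ny, x0 - t * s, y0 + t * c);
      }
      out(a, k) = acc * step;
    }
  }
  return out;
}

// Pixel-driven backprojection with linear interpolation between detector bins.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector cos_t,
                              NumericVector sin_t, int nx, int ny) {
  int nang = sino.nrow(), ndet = sino.ncol();
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cdet = 0.5 * (ndet - 1);
  NumericMatrix out(nx, ny);
  for (int a = 0; a < nang; a++) {
    double c = cos_t[a], s = sin_t[a];
    for (int iy = 0; iy < ny; iy++) {
      double y = iy - cy;
      double base = y * s + cdet;
      for (int ix = 0; ix < nx; ix++) {
        double g = (ix - cx) * c + base;
        if (g < 0.0 || g > ndet - 1.0) continue;
        int k = (int)std::floor(g);
        if (k == ndet - 1) k--;
        double f = g - k;
        out(ix, iy) += (1.0 - f) * sino(a, k) + f * sino(a, k + 1);
      }
    }
  }
  return out;
}

// One SART sweep over the supplied angle order (0-based indices into the
// angle vectors), updating vol in place slice by slice.  vol: nx x ny x nz,
// sino: nang x ndet x nz.  etas gives the relaxation factor for each processed
// step of this sweep.  Every filter_period processed steps (counted from
// global_step0 across sweeps) the 3D bilateral filter is applied.  Returns the
// summed squared residual of each processed step (before its update).
// [[Rcpp::export]]
NumericVector cpp_sart_sweep(NumericVector vol, IntegerVector dims,
                             NumericVector sino, IntegerVector sdims,
                             NumericVector cos_t, NumericVector sin_t,
                             IntegerVector order, NumericVector etas,
                             double step, int global_step0, int filter_period,
                             double sigma_xy, double sigma_z, double sigma_v,
                             double wblend);

static void bilateral3d_core(double *vol, int nx, int ny, int nz,
                             double sigma_xy, double sigma_z, double sigma_v,
                             double wblend) {
  if (wblend <= 0.0) return;
  int rxy = (int)std::ceil(3.0 * sigma_xy);
  int rz = (nz > 1) ? (int)std::ceil(3.0 * sigma_z) : 0;
  double axy = 1.0 / (2.0 * sigma_xy * sigma_xy);
  double az = (sigma_z > 0.0) ? 1.0 / (2.0 * sigma_z * sigma_z) : 0.0;
  double av = 1.0 / (2.0 * sigma_v * sigma_v);
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> outbuf(nvox);
  // precompute spatial kernel
  int wside = 2 * rxy + 1, wz = 2 * rz + 1;
  std::vector<double> kxy((size_t)wside * wside), kz(wz);
  for (int dy = -rxy; dy <= rxy; dy++)
    for (int dx = -rxy; dx <= rxy; dx++)
      kxy[(size_t)(dy + rxy) * wside + (dx + rxy)] =
          std::exp(-(double)(dx * dx + dy * dy) * axy);
  for (int dz = -rz; dz <= rz; dz++) kz[dz + rz] = std::exp(-(double)(dz * dz) * az);
  for (int z = 0; z < nz; z++) {
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) {
        double v0 = vol[(size_t)z * nx * ny + (size_t)y * nx + x];
        double num = 0.0, den = 0.0;
        for (int dz = -rz; dz <= rz; dz++) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          double kzv = kz[dz + rz];
          for (int dy = -rxy; dy <= rxy; dy++) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const double *row = vol + (size_t)zz * nx * ny + (size_t)yy * nx;
            const double *krow = &kxy[(size_t)(dy + rxy) * wside];
            int x0 = std::max(0, x - rxy), x1 = std::min(nx - 1, x + rxy);
            for (int xx = x0; xx <= x1; xx++) {
              double dv = row[xx] - v0;
              double wgt = kzv * krow[xx - x + rxy] * std::exp(-dv * dv * av);
              num += wgt * row[xx];
              den += wgt;
            }
          }
        }
        outbuf[(size_t)z * nx * ny + (size_t)y * nx + x] =
            (den > 0.0) ? num / den : v0;
      }
    }
  }
  for (size_t i = 0; i < nvox; i++)
    vol[i] = (1.0 - wblend) * vol[i] + wblend * outbuf[i];
}

// 3D bilateral filter; sigma_v is an absolute intensity width.  Output is the
// convex blend (1-w)*input + w*filtered.
// [[Rcpp::export]]
NumericVector cpp_bilateral3d(NumericVector vol, IntegerVector dims,
                              double sigma_xy, double sigma_z, double sigma_v,
                              double wblend) {
  NumericVector out = clone(vol);
  bilateral3d_core(&out[0], dims[0], dims[1], dims[2], sigma_xy, sigma_z,
                   sigma_v, wblend);
  return out;
}

NumericVector cpp_sart_sweep(NumericVector vol, IntegerVector dims,
                             NumericVector sino, IntegerVector sdims,
                             NumericVector cos_t, NumericVector sin_t,
                             IntegerVector order, NumericVector etas,
                             double step, int global_step0, int filter_period,
                             double sigma_xy, double sigma_z, double sigma_v,
                             double wblend) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nang = sdims[0], ndet = sdims[1];
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cdet = 0.5 * (ndet - 1);
  double T = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) + 1.0;
  int m = (int)std::ceil(2.0 * T / step);
  int nsteps = order.size();
  NumericVector res2(nsteps);
  std::vector<double> pcur(ndet), raylen(ndet), resid(ndet);
  for (int q = 0; q < nsteps; q++) {
    int a = order[q];
    double c = cos_t[a], s = sin_t[a];
    double eta = etas[q];
    double r2sum = 0.0;
    for (int z = 0; z < nz; z++) {
      double *slice = &vol[(size_t)z * nx * ny];
      const double *meas = &sino[0] + (size_t)z * nang * ndet;
      // forward project current slice at this angle; ray length via weights
      for (int k = 0; k < ndet; k++) {
        double sk = k - cdet;
        double x0 = sk * c + cx, y0 = sk * s + cy;
        double acc = 0.0, len = 0.0;
        for (int j = 0; j <= m; j++) {
          double t = -T + j * step;
          double x = x0 - t * s, y = y0 + t * c;
          if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) continue;
          acc += bilinear_sample(slice, nx, ny, x, y);
          len += 1.0;
        }
        pcur[k] = acc * step;
        raylen[k] = len * step;
        double r = meas[(size_t)k * nang + a] - pcur[k];
        r2sum += r * r;
        resid[k] = (raylen[k] > 1.0) ? r / raylen[k] : 0.0;
      }
      // pixel-driven backprojection of the normalized residual
      for (int iy = 0; iy < ny; iy++) {
        double y = iy - cy;
        double base = y * s + cdet;
        for (int ix = 0; ix < nx; ix++) {
          double g = (ix - cx) * c + base;
          if (g < 0.0 || g > ndet - 1.0) continue;
          int k = (int)std::floor(g);
          if (k == ndet - 1) k--;
          double f = g - k;
          slice[(size_t)iy * nx + ix] +=
              eta * ((1.0 - f) * resid[k] + f * resid[k + 1]);
        }
      }
    }
    res2[q] = r2sum;
    if (filter_period > 0 && wblend > 0.0 &&
        ((global_step0 + q + 1) % filter_period == 0)) {
      bilateral3d_core(&vol[0], nx, ny, nz, sigma_xy, sigma_z, sigma_v, wblend);
    }
  }
  return res2;
}

// Bilinear scatter-add of complex polar samples onto an L x L Cartesian DFT
// grid with periodic wrap-around.  gx, gy are fractional 0-based coordinates.
// [[Rcpp::export]]
List cpp_grid_splat(NumericVector re, NumericVector im, NumericVector gx,
                    NumericVector gy, int L) {
  NumericMatrix Re(L, L), Im(L, L);
  int npts = re.size();
  for (int i = 0; i < npts; i++) {
    double x = gx[i], y = gy[i];
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    int xa = ((x0 % L) + L) % L, xb = (xa + 1) % L;
    int ya = ((y0 % L) + L) % L, yb = (ya + 1) % L;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    double w01 = (1 - fx) * fy, w11 = fx * fy;
    Re(xa, ya) += w00 * re[i]; Im(xa, ya) += w00 * im[i];
    Re(xb, ya) += w10 * re[i]; Im(xb, ya) += w10 * im[i];
    Re(xa, yb) += w01 * re[i]; Im(xa, yb) += w01 * im[i];
    Re(xb, yb) += w11 * re[i]; Im(xb, yb) += w11 * im[i];
  }
  return List::create(_["re"] = Re, _["im"] = Im);
}
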