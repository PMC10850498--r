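#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / tricubic (Catmull-Rom) sampling of a 3D volume at one point.
// Coordinates are 0-based voxel indices into `vol`. Returns NA outside the
// interpolation support.

static inline double catmull_w(double s, int k) {
  // Catmull-Rom weight for node offset k in {-1,0,1,2}, local coord s in [0,1)
  switch (k) {
  case -1: return ((-0.5 * s + 1.0) * s - 0.5) * s;
  case 0:  return (1.5 * s - 2.5) * s * s + 1.0;
  case 1:  return ((-1.5 * s + 2.0) * s + 0.5) * s;
  default: return (0.5 * s - 0.5) * s * s;
  }
}

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return NA_REAL;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double *p = v;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    double wz = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      double wy = dj ? fy : 1.0 - fy;
      double wyz = wy * wz;
      const double *col = p + (size_t)(k0 + dk) * nx * ny + (size_t)(j0 + dj) * nx + i0;
      acc += wyz * ((1.0 - fx) * col[0] + fx * col[1]);
    }
  }
  return acc;
}

static inline double sample_tricubic(const double *v, int nx, int ny, int nz,
                                     double x, double y, double z) {
  // needs one voxel of support on each side
  if (x < 1.0 || y < 1.0 || z < 1.0 ||
      x > nx - 2.0 || y > ny - 2.0 || z > nz - 2.0)
    return NA_REAL;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 3) i0 = nx - 3;
  if (j0 > ny - 3) j0 = ny - 3;
  if (k0 > nz - 3) k0 = nz - 3;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double wx[4], wy[4], wz[4];
  for (int k = -1; k <= 2; ++k) {
    wx[k + 1] = catmull_w(fx, k);
    wy[k + 1] = catmull_w(fy, k);
    wz[k + 1] = catmull_w(fz, k);
  }
  double acc = 0.0;
  for (int dk = 0; dk < 4; ++dk) {
    for (int dj = 0; dj < 4; ++dj) {
      double wyz = wy[dj] * wz[dk];
      const double *col = v + (size_t)(k0 + dk - 1) * nx * ny +
        (size_t)(j0 + dj - 1) * nx + (i0 - 1);
      double s = wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] + wx[3] * col[3];
      acc += wyz * s;
    }
  }
  return acc;
}

// [[Rcpp::export(name = ".cpp_resample_rigid")]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector volDim,
                                 IntegerVector outDim,
                                 NumericVector outOrigin, NumericVector volOrigin,
                                 NumericVector center,
                                 NumericMatrix R, NumericVector t,
                                 int order) {
  const int nx = volDim[0], ny = volDim[1], nz = volDim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = REAL(vol);
  double *o = REAL(out);
  const double r11 = R(0, 0), r12 = R(0, 1), r13 = R(0, 2);
  const double r21 = R(1, 0), r22 = R(1, 1), r23 = R(1, 2);
  const double r31 = R(2, 0), r32 = R(2, 1), r33 = R(2, 2);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    double pz = outOrigin[2] + k - center[2];
    for (int j = 0; j < oy; ++j) {
      double py = outOrigin[1] + j - center[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        double px = outOrigin[0] + i - center[0];
        // y = R (x - c) + c + t, then to vol-local coordinates
        double qx = r11 * px + r12 * py + r13 * pz + center[0] + t[0] - volOrigin[0];
        double qy = r21 * px + r22 * py + r23 * pz + center[1] + t[1] - volOrigin[1];
        double qz = r31 * px + r32 * py + r33 * pz + center[2] + t[2] - volOrigin[2];
        o[idx] = (order >= 3)
          ? sample_tricubic(v, nx, ny, nz, qx, qy, qz)
          : sample_trilinear(v, nx, ny, nz, qx, qy, qz);
      }
    }
  }
  out.attr("dim") = outDim;
  return out;
}

// Normalized cross-correlation between two equal-length vectors, ignoring
// positions where either is NA. Returns c(ncc, n_valid).
// [[Rcpp::export(name = ".cpp_ncc")]]
NumericVector cpp_ncc(NumericVector a, NumericVector b) {
  const double *x = REAL(a), *y = REAL(b);
  const size_t n = a.size();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  size_t m = 0;
  for (size_t i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (ISNAN(xi) || ISNAN(yi)) continue;
    sx += xi; sy += yi; sxx += xi * xi; syy += yi * yi; sxy += xi * yi;
    ++m;
  }
  NumericVector out(2);
  if (m < 2) { out[0] = NA_REAL; out[1] = (double)m; return out; }
  double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
  double cv = sxy - sx * sy / m;
  out[0] = (vx <= 0 || vy <= 0) ? NA_REAL : cv / std::sqrt(vx * vy);
  out[1] = (double)m;
  return out;
}

// Joint histogram with bilinear (partial-volume) binning for a smooth
// mutual-information estimate. Inputs assumed pre-scaled to [0, nbins-1].
// Returns nbins x nbins matrix of weights (unnormalized).
// [[Rcpp::export(name = ".cpp_joint_hist")]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins) {
  NumericMatrix h(nbins, nbins);
  const double *x = REAL(a), *y = REAL(b);
  const size_t n = a.size();
  for (size_t i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (ISNAN(xi) || ISNAN(yi)) continue;
    if (xi < 0) xi = 0; if (xi > nbins - 1) xi = nbins - 1;
    if (yi < 0) yi = 0; if (yi > nbins - 1) yi = nbins - 1;
    int i0 = (int)std::floor(xi), j0 = (int)std::floor(yi);
    if (i0 == nbins - 1) i0--;
    if (j0 == nbins - 1) j0--;
    double fx = xi - i0, fy = yi - j0;
    h(i0, j0) += (1 - fx) * (1 - fy);
    h(i0 + 1, j0) += fx * (1 - fy);
    h(i0, j0 + 1) += (1 - fx) * fy;
    h(i0 + 1, j0 + 1) += fx * fy;
  }
  return h;
}
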