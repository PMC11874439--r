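#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian atom density with the libmolgrid-style quadratic tail:
//   exp(-2 d^2 / r^2)                          for d <= r
//   (4/(e^2 r^2)) d^2 - (12/(e^2 r)) d + 9/e^2 for r < d <= 1.5 r
//   0                                          beyond 1.5 r
// Continuous with continuous first derivative at d = r, zero at 1.5 r.
static inline double density(double d, double r) {
  if (d <= r) return std::exp(-2.0 * d * d / (r * r));
  if (d <= 1.5 * r) {
    double e2 = std::exp(2.0);
    return 4.0 / (e2 * r * r) * d * d - 12.0 / (e2 * r) * d + 9.0 / e2;
  }
  return 0.0;
}

// [[Rcpp::export]]
double cpp_atom_density(double d, double r) { return density(d, r); }

// Additive voxelization: each atom adds its density, evaluated analytically
// at voxel centers, to its assigned channel within radiusMultiple * r.
// channel is 0-based per atom; atoms with channel < 0 are skipped.
// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix xyz, NumericVector radius,
                           IntegerVector channel, int nchan, int npts,
                           double resolution, NumericVector center,
                           double radiusMultiple) {
  NumericVector grid(nchan * (R_xlen_t)npts * npts * npts);
  double half = (npts - 1) * resolution / 2.0;
  double x0 = center[0] - half, y0 = center[1] - half, z0 = center[2] - half;
  for (int a = 0; a < xyz.nrow(); ++a) {
    int ch = channel[a];
    if (ch < 0) continue;
    double r = radius[a], reach = radiusMultiple * r;
    double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int ix0 = std::max(0, (int)std::ceil((ax - reach - x0) / resolution));
    int ix1 = std::min(npts - 1, (int)std::floor((ax + reach - x0) / resolution));
    int iy0 = std::max(0, (int)std::ceil((ay - reach - y0) / resolution));
    int iy1 = std::min(npts - 1, (int)std::floor((ay + reach - y0) / resolution));
    int iz0 = std::max(0, (int)std::ceil((az - reach - z0) / resolution));
    int iz1 = std::min(npts - 1, (int)std::floor((az + reach - z0) / resolution));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = z0 + iz * resolution - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = y0 + iy * resolution - ay;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = x0 + ix * resolution - ax;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > reach) continue;
          R_xlen_t idx = ch + (R_xlen_t)nchan *
            (ix + (R_xlen_t)npts * (iy + (R_xlen_t)npts * iz));
          grid[idx] += density(d, r);
        }
      }
    }
  }
  grid.attr("dim") = IntegerVector::create(nchan, npts, npts, npts);
  return grid;
}
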