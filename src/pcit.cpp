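#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT trio scan over a Pearson correlation matrix.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed, e.g. r_xy.z = (r_xy - r_xz r_yz) /
// sqrt((1 - r_xz^2)(1 - r_yz^2)), and the tolerance
// eps = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3.
// An edge is flagged (explainable by the third node) when its |r| falls
// below eps times the magnitude of BOTH edges to the third node.
// Trios where any direct correlation or any sqrt(1 - r^2) denominator is
// below `guard` carry no usable conditional information and are skipped.
//
// Returns the symmetric logical flag matrix plus the skipped-trio count;
// retained edges are the never-flagged nonzero correlations.
// [[Rcpp::export(name = ".pcit_scan")]]
List pcit_scan(NumericMatrix r, double guard = 1e-12) {
  int n = r.nrow();
  LogicalMatrix flagged(n, n);
  double skipped = 0;
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      double rxy = r(x, y);
      double dxy = 1.0 - rxy * rxy;
      for (int z = y + 1; z < n; ++z) {
        double rxz = r(x, z), ryz = r(y, z);
        double dxz = 1.0 - rxz * rxz, dyz = 1.0 - ryz * ryz;
        if (std::fabs(rxy) < guard || std::fabs(rxz) < guard ||
            std::fabs(ryz) < guard || dxy < guard || dxz < guard ||
            dyz < guard) {
          skipped += 1;
          continue;
        }
        double pxy = (rxy - rxz * ryz) / std::sqrt(dxz * dyz);
        double pxz = (rxz - rxy * ryz) / std::sqrt(dxy * dyz);
        double pyz = (ryz - rxy * rxz) / std::sqrt(dxy * dxz);
        double eps = (pxy / rxy + pxz / rxz + pyz / ryz) / 3.0;
        double axy = std::fabs(rxy), axz = std::fabs(rxz),
               ayz = std::fabs(ryz);
        double exy = std::fabs(eps) * axy, exz = std::fabs(eps) * axz,
               eyz = std::fabs(eps) * ayz;
        if (axy < exz && axy < eyz) {
          flagged(x, y) = true;
          flagged(y, x) = true;
        }
        if (axz < exy && axz < eyz) {
          flagged(x, z) = true;
          flagged(z, x) = true;
        }
        if (ayz < exy && ayz < exz) {
          flagged(y, z) = true;
          flagged(z, y) = true;
        }
      }
    }
  }
  return List::create(_["flagged"] = flagged, _["skipped"] = skipped);
}
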