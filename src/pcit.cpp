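#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT edge elimination over all unordered trios.
//
// For a trio (x, y, z) the three first-order partial correlations are
//   r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))
// (and rotations), and the trio tolerance is the mean absolute ratio of
// partial to direct correlation, a ratio with zero direct correlation
// contributing 0. An edge (x, y) is eliminated if some z satisfies
// |r_xy| < |eps * r_xz| and |r_xy| < |eps * r_yz|; edges never eliminated
// are flagged significant. Trios where any pairwise |r| = 1 would divide
// by zero and are skipped (counted).
//
// [[Rcpp::export(name = ".pcit_core")]]
LogicalMatrix pcit_core(NumericMatrix r) {
  const int n = r.nrow();
  LogicalMatrix elim(n, n);
  long long skipped = 0;

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);
        if (std::fabs(rxy) >= 1.0 || std::fabs(rxz) >= 1.0 ||
            std::fabs(ryz) >= 1.0) {
          ++skipped;
          continue;
        }
        const double pxy = (rxy - rxz * ryz) /
          std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        const double pxz = (rxz - rxy * ryz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        const double pyz = (ryz - rxy * rxz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));

        double eps = 0.0;
        eps += (rxy != 0.0) ? std::fabs(pxy / rxy) : 0.0;
        eps += (rxz != 0.0) ? std::fabs(pxz / rxz) : 0.0;
        eps += (ryz != 0.0) ? std::fabs(pyz / ryz) : 0.0;
        eps /= 3.0;

        const double axy = std::fabs(rxy), axz = std::fabs(rxz),
                     ayz = std::fabs(ryz);
        if (axy < eps * axz && axy < eps * ayz) {
          elim(x, y) = true; elim(y, x) = true;
        }
        if (axz < eps * axy && axz < eps * ayz) {
          elim(x, z) = true; elim(z, x) = true;
        }
        if (ayz < eps * axy && ayz < eps * axz) {
          elim(y, z) = true; elim(z, y) = true;
        }
      }
    }
  }

  LogicalMatrix sig(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      sig(i, j) = (i != j) && !elim(i, j);
  sig.attr("skipped_trios") = (double)skipped;
  return sig;
}
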