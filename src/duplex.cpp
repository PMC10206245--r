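#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Intermolecular-only duplex minimum free energy.
//
// Hybridization dynamic program over base pairs between a short query
// (miRNA, 5'->3') and a target scanned antiparallel: no intramolecular
// structure, Watson-Crick and G:U pairs, nearest-neighbor stack energies,
// length-dependent bulge/internal loop penalties with an asymmetry term,
// and a single duplex initiation penalty. E(i, k) is the best energy of a
// duplex whose last pair is miRNA base i with (reversed) target base k;
// the minimum over all (i, k) is the mfe, clamped to 0 when no duplex is
// stable.
//
// seq encodings: 0=A, 1=C, 2=G, 3=U. pairtype: 4x4, -1 = no pair, else
// 0..5 indexing the stack matrix rows/cols as (miRNA base, target base)
// pairs. loop penalty vectors are indexed by total unpaired length.
//
// [[Rcpp::export(name = ".duplex_core")]]
List duplex_core(IntegerVector mi, IntegerVector ta, IntegerMatrix pairtype,
                 NumericMatrix stack_e, NumericVector bulge_e,
                 NumericVector internal_e, double asym_slope,
                 double asym_max, double init_e, int maxloop) {
  const int m = mi.size(), n = ta.size();
  // reverse target so both indices increase along the duplex
  IntegerVector tr(n);
  for (int k = 0; k < n; ++k) tr[k] = ta[n - 1 - k];

  const double INF = 1e9;
  NumericMatrix E(m, n);
  IntegerMatrix PT(m, n);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < n; ++k) {
      PT(i, k) = pairtype(mi[i], tr[k]);
      E(i, k) = INF;
    }

  double best = INF;
  int best_i = -1, best_k = -1;
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < n; ++k) {
      const int pc = PT(i, k);
      if (pc < 0) continue;
      double e = init_e;  // open a new duplex at this pair
      const int i0 = (i - 1 - maxloop < 0) ? 0 : i - 1 - maxloop;
      const int k0 = (k - 1 - maxloop < 0) ? 0 : k - 1 - maxloop;
      for (int i2 = i0; i2 <= i - 1; ++i2) {
        for (int k2 = k0; k2 <= k - 1; ++k2) {
          if (PT(i2, k2) < 0 || E(i2, k2) >= INF) continue;
          const int a = i - i2 - 1, b = k - k2 - 1;
          double cost;
          if (a == 0 && b == 0)
            cost = stack_e(PT(i2, k2), pc);
          else if (a == 0 || b == 0)
            cost = bulge_e[a + b - 1];
          else {
            double asym = asym_slope * std::abs(a - b);
            cost = internal_e[a + b - 1] + (asym > asym_max ? asym_max : asym);
          }
          const double cand = E(i2, k2) + cost;
          if (cand < e) e = cand;
        }
      }
      E(i, k) = e;
      if (e < best) { best = e; best_i = i; best_k = k; }
    }
  }

  if (best_i < 0 || best > 0.0)
    return List::create(_["mfe"] = 0.0, _["best_site_start"] = NA_INTEGER);
  // last pair sits at the 5'-most target position of the duplex
  return List::create(_["mfe"] = best, _["best_site_start"] = n - best_k);
}
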