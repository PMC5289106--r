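#include <Rcpp.h>
using namespace Rcpp;

// Site states are encoded as integers:
//   1..14 : IUPAC state-set bitmask (A=1, C=2, G=4, T=8); popcount >= 2 is a 2ISP
//   15    : missing (N or ?)
//   0     : gap
//   < 0   : opaque indel-2ISP code (gap-plus-base superposition)
// Missing and gap states are never comparable at the site level; gaps are
// carried by the coded binary indel characters instead.

static const double POPCNT[16] = {0, 1, 1, 2, 1, 2, 2, 3,
                                  1, 2, 2, 3, 2, 3, 3, 4};

// Jaccard distance between two state-sets; dist < 0 flags "not comparable".
static inline double site_dist(int a, int b) {
  if (a == 15 || b == 15) return -1.0;          // missing
  if (a < 0 || b < 0) {
    if (a == 0 || b == 0) return -1.0;          // indel2isp vs gap: skip
    return (a == b) ? 0.0 : 1.0;                // code equality
  }
  if (a == 0 || b == 0) return -1.0;            // gap
  double inter = POPCNT[a & b];
  double uni = POPCNT[a | b];
  return 1.0 - inter / uni;
}

// [[Rcpp::export(name = ".poly_p_distmat")]]
NumericMatrix poly_p_distmat(IntegerMatrix states, LogicalVector site_use,
                             IntegerMatrix indels) {
  int n = states.nrow(), L = states.ncol(), m = indels.ncol();
  if (site_use.size() != L) stop("site_use length mismatch");
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double num = 0.0;
      long denom = 0;
      for (int s = 0; s < L; ++s) {
        if (!site_use[s]) continue;
        double d = site_dist(states(i, s), states(j, s));
        if (d >= 0.0) { num += d; ++denom; }
      }
      for (int k = 0; k < m; ++k) {
        int a = indels(i, k), b = indels(j, k);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        num += (a != b) ? 1.0 : 0.0;
        ++denom;
      }
      double v = (denom == 0) ? NA_REAL : num / denom;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
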