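#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding-window scan of a bit-encoded primer over a bit-encoded
// target (A=1, C=2, G=4, T=8; ambiguity codes are bit unions). A position
// matches when the masks intersect. Returns the offset (0-based) with the
// fewest mismatches, earliest offset winning ties.
// [[Rcpp::export(name = ".scan_best_site")]]
IntegerVector scan_best_site(IntegerVector primer_bits, IntegerVector target_bits) {
  const int L = primer_bits.size();
  const int T = target_bits.size();
  if (L == 0) stop("empty primer");
  if (T < L) stop("target shorter than primer");
  int best_off = 0;
  int best_mm = L + 1;
  for (int off = 0; off <= T - L; ++off) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      if ((primer_bits[i] & target_bits[off + i]) == 0) {
        if (++mm >= best_mm) break;  // cannot beat current best
      }
    }
    if (mm < best_mm) {
      best_mm = mm;
      best_off = off;
      if (mm == 0) break;  // earliest perfect site
    }
  }
  return IntegerVector::create(best_off, best_mm);
}
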