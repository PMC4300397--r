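#include <Rcpp.h>
using namespace Rcpp;

//' Pairwise Hamming distance between equal-index string pairs
//'
//' Counts mismatching characters between \code{a[i]} and \code{b[i]}.
//' Strings of unequal length count the overhang as mismatches.
//'
//' @param a,b character vectors of equal length
//' @return integer vector of mismatch counts
//' @keywords internal
// [[Rcpp::export]]
IntegerVector hamming_pairs(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int m = 0; R_xlen_t j = 0;
    while (x[j] != '\0' && y[j] != '\0') { if (x[j] != y[j]) ++m; ++j; }
    while (x[j] != '\0') { ++m; ++j; }
    while (y[j] != '\0') { ++m; ++j; }
    out[i] = m;
  }
  return out;
}
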