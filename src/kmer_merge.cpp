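#include <Rcpp.h>
using namespace Rcpp;

// Streaming two-way merge of two sorted (key, species taxid) k-mer lists.
// Keys are exact integers held in doubles. Records identical in both fields
// collapse to one; equal keys with different taxids are all kept. Sortedness
// of each input is verified during the single pass; the concatenation is
// never materialized (output is written directly at its final position).
// [[Rcpp::export(name = ".mergeKmerRuns")]]
List mergeKmerRuns(NumericVector k1, IntegerVector t1,
                   NumericVector k2, IntegerVector t2) {
  const R_xlen_t n1 = k1.size(), n2 = k2.size();
  if (t1.size() != n1 || t2.size() != n2)
    stop("keys and taxids lengths differ");
  NumericVector outk(n1 + n2);
  IntegerVector outt(n1 + n2);
  R_xlen_t i = 0, j = 0, m = 0;
  auto lessOrEq = [](double ka, int ta, double kb, int tb) {
    return ka < kb || (ka == kb && ta <= tb);
  };
  while (i < n1 || j < n2) {
    bool takeFirst;
    if (i >= n1) takeFirst = false;
    else if (j >= n2) takeFirst = true;
    else takeFirst = lessOrEq(k1[i], t1[i], k2[j], t2[j]);
    double kk; int tt;
    if (takeFirst) {
      if (i > 0 && lessOrEq(k1[i], t1[i], k1[i - 1], t1[i - 1]))
        stop("existing list unsorted or duplicated at record %td",
             (ptrdiff_t)(i + 1));
      kk = k1[i]; tt = t1[i]; ++i;
    } else {
      if (j > 0 && lessOrEq(k2[j], t2[j], k2[j - 1], t2[j - 1]))
        stop("incoming list unsorted or duplicated at record %td",
             (ptrdiff_t)(j + 1));
      kk = k2[j]; tt = t2[j]; ++j;
    }
    if (m == 0 || outk[m - 1] != kk || outt[m - 1] != tt) {
      outk[m] = kk; outt[m] = tt; ++m;
    }
  }
  return List::create(
      _["keys"] = NumericVector(outk.begin(), outk.begin() + m),
      _["taxids"] = IntegerVector(outt.begin(), outt.begin() + m));
}
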