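#include <Rcpp.h>
using namespace Rcpp;

// Ungapped Hamming scan of a query against a subject. Sequences are 0-based
// integer-encoded (A=0, U=1, G=2, C=3). Returns a two-column matrix of
// (start0, mismatches) for every offset with distance <= max_mm, sorted by
// start. Overlapping hits are all reported.
// [[Rcpp::export]]
IntegerMatrix seq_scan_cpp(IntegerVector query, IntegerVector subject, int max_mm) {
  const int lq = query.size(), ls = subject.size();
  if (lq == 0) stop("empty query");
  std::vector<int> starts, mms;
  for (int off = 0; off + lq <= ls; ++off) {
    int mm = 0;
    for (int i = 0; i < lq; ++i) {
      if (query[i] != subject[off + i] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { starts.push_back(off); mms.push_back(mm); }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) { out(i, 0) = starts[i]; out(i, 1) = mms[i]; }
  return out;
}

// Hamming distance of two equal-length integer-encoded sequences.
// [[Rcpp::export]]
int seq_hamming_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int mm = 0;
  for (int i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++mm;
  return mm;
}

// Minimum Hamming distance from a candidate to every row of a set matrix
// (used by the negative-set <=2-mismatch exclusion against all positives).
// [[Rcpp::export]]
int seq_min_hamming_cpp(IntegerVector cand, IntegerMatrix set) {
  const int L = cand.size();
  if (set.ncol() != L) stop("set width does not match candidate length");
  int best = L + 1;
  for (int r = 0; r < set.nrow(); ++r) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      if (set(r, i) != cand[i] && ++mm >= best) break;
    }
    if (mm < best) best = mm;
    if (best == 0) return 0;
  }
  return best;
}
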