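#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Evaluate a batch of conjunctive range filters against a descriptor matrix.
//
// The candidate ranges are shared across filters, so each range's pass mask
// over the molecules is materialized once as a bitset; a filter is then the
// AND of its ranges' masks and TP/FP counts are popcounts against the
// positive mask.
//
// values: n x d numeric matrix (molecules x descriptors)
// rdesc: 0-based descriptor column per candidate range
// rlo, rhi: closed interval bounds per candidate range
// start, len: per-filter offsets into `cond` (0-based start)
// cond: 0-based candidate-range index per condition
// pos: length-n positive mask
//
// Returns an F x 2 integer matrix of (TP, FP) counts: a molecule counts as
// predicted-positive for a filter iff it satisfies every condition.
// [[Rcpp::export]]
IntegerMatrix cpp_eval_filters(NumericMatrix values, IntegerVector rdesc,
                               NumericVector rlo, NumericVector rhi,
                               IntegerVector start, IntegerVector len,
                               IntegerVector cond, LogicalVector pos) {
  const int n = values.nrow();
  const int nr = rdesc.size();
  const int nf = start.size();
  const int nw = (n + 63) / 64;
  std::vector<uint64_t> masks((size_t)nr * nw, 0ULL);
  for (int r = 0; r < nr; ++r) {
    const double *col = &values(0, rdesc[r]);
    uint64_t *m = &masks[(size_t)r * nw];
    const double a = rlo[r], b = rhi[r];
    for (int i = 0; i < n; ++i)
      if (col[i] >= a && col[i] <= b) m[i >> 6] |= (1ULL << (i & 63));
  }
  std::vector<uint64_t> posmask(nw, 0ULL);
  for (int i = 0; i < n; ++i)
    if (pos[i]) posmask[i >> 6] |= (1ULL << (i & 63));
  IntegerMatrix out(nf, 2);
  std::vector<uint64_t> acc(nw);
  for (int f = 0; f < nf; ++f) {
    const int s = start[f], k = len[f];
    const uint64_t *m0 = &masks[(size_t)cond[s] * nw];
    std::copy(m0, m0 + nw, acc.begin());
    for (int c = s + 1; c < s + k; ++c) {
      const uint64_t *mc = &masks[(size_t)cond[c] * nw];
      for (int w = 0; w < nw; ++w) acc[w] &= mc[w];
    }
    int tp = 0, tot = 0;
    for (int w = 0; w < nw; ++w) {
      tot += __builtin_popcountll(acc[w]);
      tp += __builtin_popcountll(acc[w] & posmask[w]);
    }
    out(f, 0) = tp;
    out(f, 1) = tot - tp;
  }
  return out;
}
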