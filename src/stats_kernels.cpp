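// Compiled kernels for the per-locus summary statistics.  These implement
// the inner loops of the LD, AFIBS and windowed haplotypic-heterozygosity
// classes; the R wrappers own all masking, binning and aggregation logic.

#include <Rcpp.h>
using namespace Rcpp;

// Squared allele-frequency correlation r^2 for a list of site pairs.
// X: haplotypes x sites 0/1 matrix; ii, jj: 1-based column indices.
// [[Rcpp::export(name = ".ld_r2_pairs")]]
NumericVector ld_r2_pairs(const IntegerMatrix& X, const IntegerVector& ii,
                          const IntegerVector& jj) {
  const int n = X.nrow();
  const int K = ii.size();
  NumericVector out(K);
  const int* xp = INTEGER(X);
  for (int k = 0; k < K; ++k) {
    const int* xa = xp + (R_xlen_t)(ii[k] - 1) * n;
    const int* xb = xp + (R_xlen_t)(jj[k] - 1) * n;
    int ca = 0, cb = 0, cab = 0;
    for (int r = 0; r < n; ++r) {
      ca += xa[r]; cb += xb[r]; cab += xa[r] & xb[r];
    }
    const double pa = (double)ca / n, pb = (double)cb / n;
    const double pab = (double)cab / n;
    const double d = pab - pa * pb;
    out[k] = d * d / (pa * (1.0 - pa) * pb * (1.0 - pb));
  }
  return out;
}

// AFIBS segment length per focal site: extend left/right from the focal
// site to the nearest site at which the carriers of the focal derived
// allele are not all identical (exclusive), truncated at [0, L].
// H: haplotypes x sites; focal: 1-based site indices (derived count >= 2).
// [[Rcpp::export(name = ".afibs_lengths")]]
NumericVector afibs_lengths(const IntegerMatrix& H, const NumericVector& pos,
                            const IntegerVector& focal, double L) {
  const int n = H.nrow(), S = H.ncol();
  const int nf = focal.size();
  NumericVector out(nf);
  const int* hp = INTEGER(H);
  std::vector<int> carriers;
  carriers.reserve(n);
  for (int f = 0; f < nf; ++f) {
    const int j = focal[f] - 1;
    const int* colj = hp + (R_xlen_t)j * n;
    carriers.clear();
    for (int r = 0; r < n; ++r)
      if (colj[r] == 1) carriers.push_back(r);
    const int m = (int)carriers.size();
    double lb = 0.0, rb = L;
    for (int k = j - 1; k >= 0; --k) {
      const int* col = hp + (R_xlen_t)k * n;
      int s = 0;
      for (int c = 0; c < m; ++c) s += col[carriers[c]];
      if (s > 0 && s < m) { lb = pos[k]; break; }
    }
    for (int k = j + 1; k < S; ++k) {
      const int* col = hp + (R_xlen_t)k * n;
      int s = 0;
      for (int c = 0; c < m; ++c) s += col[carriers[c]];
      if (s > 0 && s < m) { rb = pos[k]; break; }
    }
    out[f] = rb - lb;
  }
  return out;
}

// Haplotypic heterozygosity 1 - sum(f_h^2) per non-overlapping window.
// winIdx: 0-based window index per site (NA-free; sites outside any
// window already removed); nWin: number of windows.
// [[Rcpp::export(name = ".winh_het")]]
NumericVector winh_het(const IntegerMatrix& H, const IntegerVector& winIdx,
                       int nWin) {
  const int n = H.nrow(), S = H.ncol();
  NumericVector out(nWin);
  std::vector<int> start(nWin, -1), len(nWin, 0);
  // windows are contiguous runs in sorted position order
  for (int s = 0; s < S; ++s) {
    const int w = winIdx[s];
    if (start[w] < 0) start[w] = s;
    ++len[w];
  }
  std::vector<int> group(n), newGroup(n);
  for (int w = 0; w < nWin; ++w) {
    if (len[w] == 0) { out[w] = 0.0; continue; }
    std::fill(group.begin(), group.end(), 0);
    int nGroups = 1;
    for (int s = start[w]; s < start[w] + len[w]; ++s) {
      // refine the row partition by the alleles at site s
      std::vector<int> first0(nGroups, -1), first1(nGroups, -1);
      int next = 0;
      for (int r = 0; r < n; ++r) {
        const int g = group[r];
        int* slot = H(r, s) ? &first1[g] : &first0[g];
        if (*slot < 0) *slot = next++;
        newGroup[r] = *slot;
      }
      std::swap(group, newGroup);
      nGroups = next;
    }
    std::vector<int> cnt(nGroups, 0);
    for (int r = 0; r < n; ++r) ++cnt[group[r]];
    double ss = 0.0;
    for (int g = 0; g < nGroups; ++g) {
      const double f = (double)cnt[g] / n;
      ss += f * f;
    }
    out[w] = 1.0 - ss;
  }
  return out;
}
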