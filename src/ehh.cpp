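#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// EHH decay on one side of a core site.
//
// haps: haplotypes x sites 0/1 integer matrix (no missing entries).
// carriers: 0-based row indices of haplotypes carrying the core allele.
// core: 0-based column index of the core site; dir: +1 (right) or -1 (left).
// threshold: computation stops after the first value < threshold (that value
// is still reported).
//
// EHH at marker x = (# pairs of carrier haplotypes identical over every site
// between the core and x, inclusive) / choose(n_carriers, 2).  Implemented by
// refining a partition of the carriers one marker at a time.
//
// [[Rcpp::export]]
List ehh_side_cpp(IntegerMatrix haps, IntegerVector carriers, int core,
                  int dir, double threshold) {
  const int n = carriers.size();
  const double denom = (double)n * (n - 1) / 2.0;
  const int ncol = haps.ncol();
  std::vector<int> grp(n, 0), newgrp(n);
  std::vector<int> cols;
  std::vector<double> vals;
  bool hit = false;
  int ngrp = 1;
  for (int j = core + dir; j >= 0 && j < ncol; j += dir) {
    std::unordered_map<long long, int> seen;
    seen.reserve(2 * ngrp);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
      long long key = 2LL * grp[i] + haps(carriers[i], j);
      auto it = seen.find(key);
      if (it == seen.end()) {
        seen.emplace(key, ng);
        newgrp[i] = ng++;
      } else {
        newgrp[i] = it->second;
      }
    }
    std::vector<int> cnt(ng, 0);
    for (int i = 0; i < n; ++i) cnt[newgrp[i]]++;
    double pairs = 0;
    for (int g = 0; g < ng; ++g)
      pairs += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    const double e = pairs / denom;
    grp.swap(newgrp);
    ngrp = ng;
    cols.push_back(j);
    vals.push_back(e);
    if (e < threshold) { hit = true; break; }
    if (e == 0.0) break;  // cannot recover; threshold may be 0
  }
  return List::create(_["cols"] = wrap(cols), _["ehh"] = wrap(vals),
                      _["hit_threshold"] = hit);
}
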