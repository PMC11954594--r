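#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Batch structured-coalescent SNP simulator.
//
// One independent genealogy per site under a multi-population model with
// piecewise-constant diploid sizes and backward-in-time divergence events
// (child lineages move into the parent population); no migration.  Within a
// population holding k lineages of size N, pairs coalesce at rate
// k(k-1)/2 / (2N).  A single mutation per site is placed on a branch chosen
// proportional to its length; the derived allele marks the leaves under it.
//
// lin_pop0: 1-based population index per sampled haplotype.
// size_times/size_vals: per population, epoch start times (ascending, first
//   element 0) and diploid sizes.
// div_time/div_child/div_parent: divergence events sorted by time (1-based
//   population indices).
// bound_times: sorted unique times at which rates can change.
//
// Sites are ascertained as SNPs produced by the mutational process: a
// genealogy contributes a site with probability proportional to its total
// branch length (rejection sampling against an adaptive cap calibrated on 100
// warm-up trees), which reproduces the neutral site-frequency law exactly;
// weight = false keeps one site per genealogy unconditionally.
//
// Uses R's RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerMatrix sim_snp_sites_cpp(int n_sites, IntegerVector lin_pop0,
                                int n_pops, List size_times, List size_vals,
                                NumericVector div_time, IntegerVector div_child,
                                IntegerVector div_parent,
                                NumericVector bound_times, bool weight = true) {
  const int n = lin_pop0.size();
  IntegerMatrix out(n_sites, n);
  std::vector<std::vector<double>> st(n_pops), sv(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    st[p] = as<std::vector<double>>(size_times[p]);
    sv[p] = as<std::vector<double>>(size_vals[p]);
  }
  std::vector<double> bt = as<std::vector<double>>(bound_times);
  const int ndiv = div_time.size();

  std::vector<int> linpop(n);
  std::vector<double> birth(n);
  std::vector<std::vector<int>> leaves(n);
  std::vector<double> brlen;
  std::vector<std::vector<int>> brleaves;
  std::vector<double> rate(n_pops);
  std::vector<int> cnt(n_pops);

  // simulates one genealogy into brlen/brleaves, returns total branch length
  auto sim_tree = [&]() -> double {
    for (int i = 0; i < n; ++i) {
      linpop[i] = lin_pop0[i] - 1;
      birth[i] = 0.0;
      leaves[i].assign(1, i);
    }
    brlen.clear();
    brleaves.clear();
    brlen.reserve(2 * n);
    brleaves.reserve(2 * n);
    int m = n;
    double t = 0.0;
    size_t bidx = 0;
    int didx = 0;
    // divergence events scheduled at time 0 apply immediately
    while (didx < ndiv && div_time[didx] <= 0.0) {
      const int child = div_child[didx] - 1, parent = div_parent[didx] - 1;
      for (int i = 0; i < m; ++i)
        if (linpop[i] == child) linpop[i] = parent;
      ++didx;
    }

    while (m > 1) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < m; ++i) cnt[linpop[i]]++;
      double total = 0.0;
      for (int p = 0; p < n_pops; ++p) {
        rate[p] = 0.0;
        if (cnt[p] >= 2) {
          const std::vector<double>& T = st[p];
          int j = (int)(std::upper_bound(T.begin(), T.end(), t) - T.begin()) - 1;
          rate[p] = cnt[p] * (cnt[p] - 1) / 2.0 / (2.0 * sv[p][j]);
          total += rate[p];
        }
      }
      while (bidx < bt.size() && bt[bidx] <= t) ++bidx;
      const double nxt = (bidx < bt.size()) ? bt[bidx] : R_PosInf;
      const double w = (total > 0) ? R::exp_rand() / total : R_PosInf;
      if (t + w < nxt) {
        t += w;
        double u = unif_rand() * total;
        int p = 0;
        double acc = rate[0];
        while (u > acc && p < n_pops - 1) { ++p; acc += rate[p]; }
        // two distinct lineages of population p, uniformly
        int r1 = (int)(unif_rand() * cnt[p]); if (r1 >= cnt[p]) r1 = cnt[p] - 1;
        int r2 = (int)(unif_rand() * (cnt[p] - 1)); if (r2 >= cnt[p] - 1) r2 = cnt[p] - 2;
        if (r2 >= r1) ++r2;
        int i1 = -1, i2 = -1, seen = 0;
        for (int i = 0; i < m; ++i) {
          if (linpop[i] == p) {
            if (seen == r1) i1 = i;
            if (seen == r2) i2 = i;
            ++seen;
          }
        }
        brlen.push_back(t - birth[i1]);
        brleaves.push_back(leaves[i1]);
        brlen.push_back(t - birth[i2]);
        brleaves.push_back(leaves[i2]);
        leaves[i1].insert(leaves[i1].end(), leaves[i2].begin(), leaves[i2].end());
        birth[i1] = t;
        std::swap(leaves[i2], leaves[m - 1]);
        linpop[i2] = linpop[m - 1];
        birth[i2] = birth[m - 1];
        --m;
      } else {
        if (!R_FINITE(nxt))
          stop("coalescent cannot complete: disconnected model");
        t = nxt;
        while (didx < ndiv && div_time[didx] <= t) {
          if (div_time[didx] == t) {
            const int child = div_child[didx] - 1, parent = div_parent[didx] - 1;
            for (int i = 0; i < m; ++i)
              if (linpop[i] == child) linpop[i] = parent;
          }
          ++didx;
        }
      }
    }
    double totlen = 0.0;
    for (size_t b = 0; b < brlen.size(); ++b) totlen += brlen[b];
    return totlen;
  };

  double cap = 0.0;
  if (weight) {
    double mean_len = 0.0;
    for (int w = 0; w < 100; ++w) mean_len += sim_tree();
    cap = 3.0 * mean_len / 100.0;
  }

  for (int s = 0; s < n_sites; ++s) {
    double totlen;
    for (;;) {
      totlen = sim_tree();
      if (!weight || totlen >= cap || unif_rand() * cap < totlen) break;
    }
    double u = unif_rand() * totlen;
    size_t b = 0;
    double acc = brlen[0];
    while (u > acc && b + 1 < brlen.size()) { ++b; acc += brlen[b]; }
    const std::vector<int>& dl = brleaves[b];
    for (size_t i = 0; i < dl.size(); ++i) out(s, dl[i]) = 1;
  }
  return out;
}
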