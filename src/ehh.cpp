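#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Site-EHH: probability that two randomly drawn haplotypes are identical
// over all markers from the core through marker x (core allele included,
// alleles pooled). Computed by progressive partition refinement with
// counting-based group relabelling (no sorting).

namespace {

// refine partition by alleles in column j and return the new
// homozygosity sum n_g (n_g - 1) / (n (n - 1)); grp holds group ids
// 0..G-1, scratch must have size >= 2 * n
inline double refine_and_h(std::vector<int> &grp, int &G,
                           const int *col, int n,
                           std::vector<int> &remap,
                           std::vector<int> &cnt) {
  const int keys = 2 * G;
  for (int k = 0; k < keys; ++k) remap[k] = -1;
  int newG = 0;
  for (int i = 0; i < n; ++i) {
    int key = grp[i] * 2 + col[i];
    if (remap[key] < 0) {
      remap[key] = newG;
      cnt[newG] = 0;
      ++newG;
    }
    grp[i] = remap[key];
    cnt[grp[i]]++;
  }
  G = newG;
  double s = 0.0;
  for (int g = 0; g < newG; ++g)
    s += (double)cnt[g] * (cnt[g] - 1);
  return s / ((double)n * (n - 1));
}

}  // namespace

// [[Rcpp::export(name = ".ehh_profile_cpp")]]
List ehh_profile_cpp(IntegerMatrix hap, int core, double trunc) {
  int n = hap.nrow(), L = hap.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  if (core < 0 || core >= L) stop("core out of range");
  NumericVector ehh(L, NA_REAL);
  std::vector<int> grp0(n, 0), grp(n), remap(2 * n + 2), cnt(n + 1);
  std::vector<int> col(n);
  int G0 = 1, G;
  for (int i = 0; i < n; ++i) col[i] = hap(i, core);
  double e0 = refine_and_h(grp0, G0, col.data(), n, remap, cnt);
  ehh[core] = e0;
  int right = core, left = core;
  if (e0 >= trunc) {
    grp = grp0; G = G0;
    for (int j = core + 1; j < L; ++j) {
      for (int i = 0; i < n; ++i) col[i] = hap(i, j);
      double e = refine_and_h(grp, G, col.data(), n, remap, cnt);
      if (e < trunc) break;
      ehh[j] = e;
      right = j;
    }
    grp = grp0; G = G0;
    for (int j = core - 1; j >= 0; --j) {
      for (int i = 0; i < n; ++i) col[i] = hap(i, j);
      double e = refine_and_h(grp, G, col.data(), n, remap, cnt);
      if (e < trunc) break;
      ehh[j] = e;
      left = j;
    }
  }
  return List::create(_["ehh"] = ehh, _["left"] = left + 1,
                      _["right"] = right + 1);
}

// [[Rcpp::export(name = ".ies_all_cpp")]]
NumericVector ies_all_cpp(IntegerMatrix hap, NumericVector pos,
                          double trunc) {
  int n = hap.nrow(), L = hap.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  NumericVector ies(L, NA_REAL);
  std::vector<int> grp0(n), grp(n), remap(2 * n + 2), cnt(n + 1);
  std::vector<int> col(n);
  for (int core = 0; core < L; ++core) {
    std::fill(grp0.begin(), grp0.end(), 0);
    int G0 = 1, G;
    for (int i = 0; i < n; ++i) col[i] = hap(i, core);
    double e0 = refine_and_h(grp0, G0, col.data(), n, remap, cnt);
    double s = 0.0;
    if (e0 >= trunc) {
      double prev = e0, prev_pos = pos[core];
      grp = grp0; G = G0;
      for (int j = core + 1; j < L; ++j) {
        for (int i = 0; i < n; ++i) col[i] = hap(i, j);
        double e = refine_and_h(grp, G, col.data(), n, remap, cnt);
        if (e < trunc) break;
        s += 0.5 * (prev + e) * (pos[j] - prev_pos);
        prev = e; prev_pos = pos[j];
        if (G == n) break;  // all singleton groups: profile is flat 0
      }
      prev = e0; prev_pos = pos[core];
      grp = grp0; G = G0;
      for (int j = core - 1; j >= 0; --j) {
        for (int i = 0; i < n; ++i) col[i] = hap(i, j);
        double e = refine_and_h(grp, G, col.data(), n, remap, cnt);
        if (e < trunc) break;
        s += 0.5 * (prev + e) * (prev_pos - pos[j]);
        prev = e; prev_pos = pos[j];
        if (G == n) break;
      }
    }
    ies[core] = s;
  }
  return ies;
}
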