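#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured coalescent for three extant demes with two splits (T2 <= T1),
// an optional migration-rate change at TC (TC <= T2), and a two-lineage
// epoch [T2, T1) with its own symmetric migration rate m3.
//
// Backward in time:
//   [0, TC)   : demes {0,1,2}, sizes N0,N1,N2, pairwise rates m01,m02,m12
//   [TC, T2)  : demes {0,1,2}, same sizes, pairwise rates k01,k02,k12
//   at T2     : deme 2 lineages move into deme `dest2` (1 = nested shape,
//               0 = radiating shape); deme dest2 takes size NB
//   [T2, T1)  : two demes, symmetric migration m3 between them
//   at T1     : all lineages move into deme 0, size NA_ (root)
//
// Time is continuous in generations; coalescence in deme i occurs at rate
// n_i(n_i-1)/2 / (2 N_i); backward migration i->j at rate m_ij per lineage.
// Rates are treated as symmetric per pair.

namespace {

struct Lineage {
  int deme;
  int d0, d1, d2;              // sampled-deme descendant counts
  double birth;                // time the branch started (toward past)
  std::vector<int> leaves;     // only filled when trees are requested
};

struct SimParams {
  int n0, n1, n2;
  double N0, N1, N2, NA_, NB;
  double T1, T2, TC;
  double m01, m02, m12;        // younger than TC
  double k01, k02, k12;        // older than TC (up to T2)
  double m3;                   // between the two lineages in [T2, T1)
  int dest2;                   // deme receiving deme-2 lineages at T2
};

SimParams read_params(List cfg) {
  SimParams p;
  IntegerVector n = cfg["n"];
  if (n.size() != 3) stop("need three haploid sample sizes");
  p.n0 = n[0]; p.n1 = n[1]; p.n2 = n[2];
  p.N0 = as<double>(cfg["N0"]); p.N1 = as<double>(cfg["N1"]);
  p.N2 = as<double>(cfg["N2"]);
  p.NA_ = as<double>(cfg["NA"]); p.NB = as<double>(cfg["NB"]);
  p.T1 = as<double>(cfg["T1"]); p.T2 = as<double>(cfg["T2"]);
  p.TC = as<double>(cfg["TC"]);
  p.m01 = as<double>(cfg["m01"]); p.m02 = as<double>(cfg["m02"]);
  p.m12 = as<double>(cfg["m12"]);
  p.k01 = as<double>(cfg["k01"]); p.k02 = as<double>(cfg["k02"]);
  p.k12 = as<double>(cfg["k12"]);
  p.m3 = as<double>(cfg["m3"]);
  p.dest2 = as<int>(cfg["dest2"]);
  if (p.T1 < p.T2) stop("T1 must be >= T2");
  if (p.TC > p.T2) stop("TC must be <= T2");
  if (p.dest2 != 0 && p.dest2 != 1) stop("dest2 must be 0 or 1");
  return p;
}

// One genealogy. If `record` is non-null, branch lengths and leaf sets are
// appended there as (length, leaves). If `acc` is non-null, per-interval
// lineage existence times are accumulated by descendant configuration into
// the flat array acc[(d0*(n1+1) + d1)*(n2+1) + d2].
void simulate_one(const SimParams &p, std::vector<double> *acc,
                  std::vector<double> *br_len,
                  std::vector<std::vector<int> > *br_leaves,
                  std::vector<double> *br_end,
                  long max_events) {
  const bool trees = (br_len != 0);
  std::vector<Lineage> act;
  act.reserve(p.n0 + p.n1 + p.n2);
  int id = 0;
  for (int d = 0; d < 3; ++d) {
    int nd = d == 0 ? p.n0 : (d == 1 ? p.n1 : p.n2);
    for (int i = 0; i < nd; ++i) {
      Lineage l;
      l.deme = d;
      l.d0 = (d == 0); l.d1 = (d == 1); l.d2 = (d == 2);
      l.birth = 0.0;
      if (trees) l.leaves.push_back(id);
      act.push_back(l);
      ++id;
    }
  }
  double t = 0.0;
  // epoch boundaries to honour, in order
  double bounds[3] = {p.TC, p.T2, p.T1};
  int next_bound = 0;
  if (p.TC <= 0) next_bound = 1;
  if (next_bound == 1 && p.T2 <= 0) next_bound = 2;
  if (next_bound == 2 && p.T1 <= 0) next_bound = 3;
  // apply instantaneous transitions for boundaries at time 0
  if (p.T2 <= 0) {
    for (size_t i = 0; i < act.size(); ++i)
      if (act[i].deme == 2) act[i].deme = p.dest2;
  }
  if (p.T1 <= 0) {
    for (size_t i = 0; i < act.size(); ++i) act[i].deme = 0;
  }
  long events = 0;
  const int n0p = p.n0 + 1, n1p = p.n1 + 1;
  while (act.size() > 1) {
    if (++events > max_events)
      stop("coalescent did not complete within the event cap; "
           "check sizes and migration rates");
    // apply any epoch transitions that are due (idempotent; guards
    // against floating-point drift around boundaries)
    while (next_bound < 3 && bounds[next_bound] <= t) {
      if (next_bound == 1) {
        for (size_t i = 0; i < act.size(); ++i)
          if (act[i].deme == 2) act[i].deme = p.dest2;
      } else if (next_bound == 2) {
        for (size_t i = 0; i < act.size(); ++i) act[i].deme = 0;
      }
      ++next_bound;
    }
    // census
    int cnt[3] = {0, 0, 0};
    for (size_t i = 0; i < act.size(); ++i) cnt[act[i].deme]++;
    // epoch-dependent sizes and migration
    double N[3] = {p.N0, p.N1, p.N2};
    double mig[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    if (t >= p.T1) {
      N[0] = p.NA_;
    } else if (t >= p.T2) {
      N[p.dest2] = p.NB;
      int other = 1 - p.dest2;
      mig[0][1] = mig[1][0] = 0.0;
      mig[p.dest2][other] = mig[other][p.dest2] = p.m3;
    } else if (t >= p.TC) {
      mig[0][1] = mig[1][0] = p.k01;
      mig[0][2] = mig[2][0] = p.k02;
      mig[1][2] = mig[2][1] = p.k12;
    } else {
      mig[0][1] = mig[1][0] = p.m01;
      mig[0][2] = mig[2][0] = p.m02;
      mig[1][2] = mig[2][1] = p.m12;
    }
    // total rates
    double rate_coal[3], rate_mig[3][3], total = 0.0;
    for (int d = 0; d < 3; ++d) {
      rate_coal[d] = cnt[d] > 1 ?
        (double)cnt[d] * (cnt[d] - 1) / 2.0 / (2.0 * N[d]) : 0.0;
      total += rate_coal[d];
      for (int e = 0; e < 3; ++e) {
        rate_mig[d][e] = (d != e) ? cnt[d] * mig[d][e] : 0.0;
        total += rate_mig[d][e];
      }
    }
    double bound = next_bound < 3 ? bounds[next_bound] : R_PosInf;
    double dt;
    bool hit_bound;
    if (total <= 0.0) {
      if (!R_finite(bound))
        stop("no events possible and no epoch boundary ahead "
             "(t=%g, next_bound=%d, counts=%d/%d/%d); lineages cannot "
             "coalesce under this parameterization",
             t, next_bound, cnt[0], cnt[1], cnt[2]);
      dt = bound - t;
      hit_bound = true;
    } else {
      dt = R::rexp(1.0 / total);
      hit_bound = (t + dt >= bound);
      if (hit_bound) dt = bound - t;
    }
    // accumulate interval
    if (acc && dt > 0) {
      // column-major flat index (d0 fastest) to match R's array()
      for (size_t i = 0; i < act.size(); ++i) {
        const Lineage &l = act[i];
        (*acc)[(size_t)l.d0 + n0p * ((size_t)l.d1 + n1p * l.d2)] += dt;
      }
    }
    if (hit_bound) {
      t = bound;  // exact landing; transitions run at the loop top
      continue;
    }
    t += dt;
    // choose event
    double u = R::runif(0.0, 1.0) * total;
    int ev_deme = -1, ev_to = -1;
    bool coal = false;
    int lp_deme = -1, lp_to = -1;       // last event with positive rate
    bool lp_coal = false;
    for (int d = 0; d < 3 && ev_deme < 0; ++d) {
      if (rate_coal[d] > 0) { lp_deme = d; lp_to = -1; lp_coal = true; }
      if (u < rate_coal[d]) { ev_deme = d; coal = true; break; }
      u -= rate_coal[d];
      for (int e = 0; e < 3; ++e) {
        if (d == e) continue;
        if (rate_mig[d][e] > 0) { lp_deme = d; lp_to = e; lp_coal = false; }
        if (u < rate_mig[d][e]) { ev_deme = d; ev_to = e; break; }
        u -= rate_mig[d][e];
      }
    }
    if (ev_deme < 0) { ev_deme = lp_deme; ev_to = lp_to; coal = lp_coal; }
    if (coal) {
      // pick two distinct lineages in ev_deme
      std::vector<int> idx;
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == ev_deme) idx.push_back((int)i);
      int a = (int)std::floor(R::runif(0.0, 1.0) * idx.size());
      if (a >= (int)idx.size()) a = idx.size() - 1;
      int b = (int)std::floor(R::runif(0.0, 1.0) * (idx.size() - 1));
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      if (trees) {
        br_len->push_back(t - act[ia].birth);
        br_leaves->push_back(act[ia].leaves);
        br_end->push_back(t);
        br_len->push_back(t - act[ib].birth);
        br_leaves->push_back(act[ib].leaves);
        br_end->push_back(t);
      }
      Lineage par;
      par.deme = ev_deme;
      par.d0 = act[ia].d0 + act[ib].d0;
      par.d1 = act[ia].d1 + act[ib].d1;
      par.d2 = act[ia].d2 + act[ib].d2;
      par.birth = t;
      if (trees) {
        par.leaves = act[ia].leaves;
        par.leaves.insert(par.leaves.end(), act[ib].leaves.begin(),
                          act[ib].leaves.end());
      }
      // remove higher index first
      if (ia < ib) std::swap(ia, ib);
      act.erase(act.begin() + ia);
      act.erase(act.begin() + ib);
      act.push_back(par);
    } else {
      std::vector<int> idx;
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == ev_deme) idx.push_back((int)i);
      int a = (int)std::floor(R::runif(0.0, 1.0) * idx.size());
      if (a >= (int)idx.size()) a = idx.size() - 1;
      act[idx[a]].deme = ev_to;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_config_lengths_cpp")]]
NumericVector sim_config_lengths_cpp(List cfg, int n_sims,
                                     double max_events = 1e7) {
  SimParams p = read_params(cfg);
  size_t len = (size_t)(p.n0 + 1) * (p.n1 + 1) * (p.n2 + 1);
  std::vector<double> acc(len, 0.0);
  RNGScope scope;
  for (int s = 0; s < n_sims; ++s) {
    simulate_one(p, &acc, 0, 0, 0, (long)max_events);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector out(acc.begin(), acc.end());
  return out;
}

// [[Rcpp::export(name = ".sim_tree_cpp")]]
List sim_tree_cpp(List cfg, double max_events = 1e7) {
  SimParams p = read_params(cfg);
  std::vector<double> bl, be;
  std::vector<std::vector<int> > lv;
  RNGScope scope;
  simulate_one(p, 0, &bl, &lv, &be, (long)max_events);
  List leaves(lv.size());
  for (size_t i = 0; i < lv.size(); ++i)
    leaves[i] = IntegerVector(lv[i].begin(), lv[i].end());
  return List::create(_["length"] = NumericVector(bl.begin(), bl.end()),
                      _["t_end"] = NumericVector(be.begin(), be.end()),
                      _["leaves"] = leaves);
}
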