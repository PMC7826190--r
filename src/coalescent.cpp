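// Structured-coalescent simulation of unlinked sites.
//
// Time runs backward from the present in units of 2N_ref generations.
// Within a population of relative size nu, each pair of lineages coalesces
// at rate 1/nu. A migration epoch (dest, source, start, end, rate) moves
// each lineage currently in `dest` to `source` at the given per-lineage
// backward rate; the R layer converts forward gene-flow specifications
// (donor -> recipient at M = 2Nm) into backward epochs with dest = recipient,
// source = donor, rate = M. Population merges (backward-time joins) move all
// lineages from one pool into another at a fixed time. Events are generated
// by exponential racing with rates held piecewise constant between model
// breakpoints.
//
// For each site an independent genealogy is drawn and a single mutation is
// placed uniformly on total branch length, optionally restricted to branch
// segments inside a time window; the derived-allele counts of the three
// sampled populations index a cell of the joint SFS.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct MigEpoch {
  int dest, source;
  double rate;
};

struct Interval {
  double start, end;
  std::vector<double> nu;             // per population
  std::vector<MigEpoch> migs;         // active in this interval
  std::vector<std::pair<int, int>> merges_at_end;  // (from, to)
};

struct Model {
  int npop;
  std::vector<Interval> intervals;
};

const double TIME_GUARD = 1e6;  // beyond this, pools are considered isolated

Model build_model(int npop, const NumericMatrix& sizes,
                  const NumericMatrix& merges, const NumericMatrix& migs) {
  // breakpoints: every time at which any rate changes
  std::vector<double> bp;
  bp.push_back(0.0);
  for (int i = 0; i < sizes.nrow(); ++i) bp.push_back(sizes(i, 1));
  for (int i = 0; i < merges.nrow(); ++i) bp.push_back(merges(i, 0));
  for (int i = 0; i < migs.nrow(); ++i) {
    bp.push_back(migs(i, 2));
    if (R_finite(migs(i, 3))) bp.push_back(migs(i, 3));
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::abs(a - b) < 1e-12; }),
           bp.end());

  Model m;
  m.npop = npop;
  for (size_t i = 0; i < bp.size(); ++i) {
    Interval iv;
    iv.start = bp[i];
    iv.end = (i + 1 < bp.size()) ? bp[i + 1] : R_PosInf;
    iv.nu.assign(npop, 1.0);
    for (int p = 0; p < npop; ++p) {
      double best_t = -1.0;
      for (int r = 0; r < sizes.nrow(); ++r) {
        if ((int)sizes(r, 0) == p && sizes(r, 1) <= iv.start + 1e-12 &&
            sizes(r, 1) > best_t) {
          best_t = sizes(r, 1);
          iv.nu[p] = sizes(r, 2);
        }
      }
    }
    for (int r = 0; r < migs.nrow(); ++r) {
      if (migs(r, 2) <= iv.start + 1e-12 && migs(r, 3) > iv.start + 1e-12) {
        iv.migs.push_back({(int)migs(r, 0), (int)migs(r, 1), migs(r, 4)});
      }
    }
    for (int r = 0; r < merges.nrow(); ++r) {
      if (R_finite(iv.end) && std::abs(merges(r, 0) - iv.end) < 1e-12) {
        iv.merges_at_end.push_back({(int)merges(r, 1), (int)merges(r, 2)});
      }
    }
    m.intervals.push_back(iv);
  }
  return m;
}

struct Genealogy {
  std::vector<double> time;
  std::vector<int> parent;                 // -1 for the root
  std::vector<std::array<int, 3>> leaves;  // sampled-population leaf counts
  int root;
  int nsamp_total;
};

// one structured-coalescent genealogy; returns false if pools never merge
bool sim_one(const Model& mod, const std::vector<int>& nsamp,
             std::mt19937_64& rng, Genealogy& g) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const int npop = mod.npop;
  int ntot = 0;
  for (int p = 0; p < (int)nsamp.size(); ++p) ntot += nsamp[p];

  g.time.assign(2 * ntot - 1, 0.0);
  g.parent.assign(2 * ntot - 1, -1);
  g.leaves.assign(2 * ntot - 1, {0, 0, 0});
  g.nsamp_total = ntot;

  std::vector<int> lin_node;  // active lineage -> node id
  std::vector<int> lin_pop;   // active lineage -> current population
  int next_node = 0;
  for (int p = 0; p < (int)nsamp.size(); ++p) {
    for (int s = 0; s < nsamp[p]; ++s) {
      if (p < 3) g.leaves[next_node][p] = 1;
      lin_node.push_back(next_node);
      lin_pop.push_back(p);
      ++next_node;
    }
  }

  double t = 0.0;
  size_t iv_idx = 0;
  std::vector<int> per_pop(npop);
  while (lin_node.size() > 1) {
    const Interval& iv = mod.intervals[iv_idx];
    std::fill(per_pop.begin(), per_pop.end(), 0);
    for (size_t i = 0; i < lin_pop.size(); ++i) per_pop[lin_pop[i]]++;

    double coal_total = 0.0;
    for (int p = 0; p < npop; ++p) {
      if (per_pop[p] > 1) coal_total += per_pop[p] * (per_pop[p] - 1) * 0.5 / iv.nu[p];
    }
    double mig_total = 0.0;
    for (const MigEpoch& me : iv.migs) mig_total += per_pop[me.dest] * me.rate;
    double total = coal_total + mig_total;

    double t_event = R_PosInf;
    if (total > 0) t_event = t - std::log(1.0 - U(rng)) / total;

    if (t_event >= iv.end) {
      if (!R_finite(iv.end)) return false;  // isolated pools, no events left
      t = iv.end;
      for (const auto& mg : iv.merges_at_end) {
        for (size_t i = 0; i < lin_pop.size(); ++i) {
          if (lin_pop[i] == mg.first) lin_pop[i] = mg.second;
        }
      }
      ++iv_idx;
      continue;
    }
    if (t_event > TIME_GUARD) return false;
    t = t_event;

    double u = U(rng) * total;
    bool done = false;
    for (int p = 0; p < npop && !done; ++p) {
      if (per_pop[p] < 2) continue;
      double r = per_pop[p] * (per_pop[p] - 1) * 0.5 / iv.nu[p];
      if (u < r) {
        // coalesce a uniform random pair within population p
        int k = per_pop[p];
        int a = (int)(U(rng) * k);
        int b = (int)(U(rng) * (k - 1));
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (size_t i = 0; i < lin_pop.size(); ++i) {
          if (lin_pop[i] == p) {
            if (seen == a) ia = (int)i;
            if (seen == b) ib = (int)i;
            ++seen;
          }
        }
        int node = next_node++;
        g.time[node] = t;
        g.parent[lin_node[ia]] = node;
        g.parent[lin_node[ib]] = node;
        for (int q = 0; q < 3; ++q) {
          g.leaves[node][q] = g.leaves[lin_node[ia]][q] + g.leaves[lin_node[ib]][q];
        }
        // replace ia by new node, remove ib
        lin_node[ia] = node;
        size_t last = lin_node.size() - 1;
        lin_node[ib] = lin_node[last];
        lin_pop[ib] = lin_pop[last];
        lin_node.pop_back();
        lin_pop.pop_back();
        done = true;
      } else {
        u -= r;
      }
    }
    if (!done) {
      for (const MigEpoch& me : iv.migs) {
        double r = per_pop[me.dest] * me.rate;
        if (u < r) {
          int k = per_pop[me.dest];
          int a = (int)(U(rng) * k);
          int seen = 0;
          for (size_t i = 0; i < lin_pop.size(); ++i) {
            if (lin_pop[i] == me.dest) {
              if (seen == a) { lin_pop[i] = me.source; break; }
              ++seen;
            }
          }
          done = true;
          break;
        }
        u -= r;
      }
    }
    if (!done) return false;  // numerical fallthrough; should not happen
  }
  g.root = lin_node[0];
  return true;
}

}  // namespace

// [[Rcpp::export]]
List sim_joint_sfs_cpp(IntegerVector n_samp, int npop,
                       NumericMatrix sizes, NumericMatrix merges,
                       NumericMatrix migs, int n_sites,
                       double win_lo, double win_hi,
                       double seed1, double seed2) {
  Model mod = build_model(npop, sizes, merges, migs);
  std::vector<int> ns(n_samp.begin(), n_samp.end());
  std::seed_seq sseq{(uint64_t)seed1, (uint64_t)seed2};
  std::mt19937_64 rng(sseq);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  int n1 = ns[0], n2 = ns[1], n3 = (ns.size() > 2) ? ns[2] : 0;
  NumericVector counts((n1 + 1) * (n2 + 1) * (n3 + 1));
  counts.attr("dim") = IntegerVector::create(n1 + 1, n2 + 1, n3 + 1);

  Genealogy g;
  long resampled = 0;
  for (int s = 0; s < n_sites; ++s) {
    for (;;) {
      if (!sim_one(mod, ns, rng, g)) {
        stop("demographic model has lineage pools that never merge "
             "(no coalescence possible); check split/merge times");
      }
      // total branch length inside the mutation window
      double L = 0.0;
      int nn = 2 * g.nsamp_total - 1;
      for (int nd = 0; nd < nn; ++nd) {
        if (g.parent[nd] < 0) continue;
        double lo = std::max(g.time[nd], win_lo);
        double hi = std::min(g.time[g.parent[nd]], win_hi);
        if (hi > lo) L += hi - lo;
      }
      if (L <= 0) { ++resampled; continue; }
      double u = U(rng) * L;
      int chosen = -1;
      for (int nd = 0; nd < nn; ++nd) {
        if (g.parent[nd] < 0) continue;
        double lo = std::max(g.time[nd], win_lo);
        double hi = std::min(g.time[g.parent[nd]], win_hi);
        if (hi > lo) {
          u -= (hi - lo);
          if (u <= 0) { chosen = nd; break; }
        }
      }
      if (chosen < 0) chosen = nn - 2;  // guard against rounding at u ~ L
      const std::array<int, 3>& lc = g.leaves[chosen];
      counts[lc[0] + (n1 + 1) * (lc[1] + (n2 + 1) * lc[2])] += 1.0;
      break;
    }
  }
  return List::create(_["counts"] = counts, _["resampled"] = (double)resampled);
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector n_samp, int npop,
                       NumericMatrix sizes, NumericMatrix merges,
                       NumericMatrix migs, double seed1, double seed2) {
  Model mod = build_model(npop, sizes, merges, migs);
  std::vector<int> ns(n_samp.begin(), n_samp.end());
  std::seed_seq sseq{(uint64_t)seed1, (uint64_t)seed2};
  std::mt19937_64 rng(sseq);
  Genealogy g;
  if (!sim_one(mod, ns, rng, g)) {
    stop("demographic model has lineage pools that never merge "
         "(no coalescence possible); check split/merge times");
  }
  int nn = 2 * g.nsamp_total - 1;
  NumericVector time(nn);
  IntegerVector parent(nn);
  IntegerMatrix leaves(nn, 3);
  for (int nd = 0; nd < nn; ++nd) {
    time[nd] = g.time[nd];
    parent[nd] = g.parent[nd] + 1;  // 1-based; 0 = root
    for (int q = 0; q < 3; ++q) leaves(nd, q) = g.leaves[nd][q];
  }
  return List::create(_["time"] = time, _["parent"] = parent,
                      _["leaves"] = leaves, _["root"] = g.root + 1);
}

// [[Rcpp::export]]
NumericVector sim_tmrca_cpp(IntegerVector n_samp, int npop,
                            NumericMatrix sizes, NumericMatrix merges,
                            NumericMatrix migs, int n_rep,
                            double seed1, double seed2) {
  Model mod = build_model(npop, sizes, merges, migs);
  std::vector<int> ns(n_samp.begin(), n_samp.end());
  std::seed_seq sseq{(uint64_t)seed1, (uint64_t)seed2};
  std::mt19937_64 rng(sseq);
  Genealogy g;
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    if (!sim_one(mod, ns, rng, g)) {
      stop("demographic model has lineage pools that never merge");
    }
    out[r] = g.time[g.root];
  }
  return out;
}
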