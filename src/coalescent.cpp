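// Structured two-deme coalescent with epoch-limited migration.
//
// Time runs backward in generations. Two demes of diploid sizes N1, N2
// merge into a single ancestral deme of size Nanc at TS. Lineage migration
// (backward in time) is active only on [mig_lo, mig_hi): a lineage in deme 1
// moves to deme 2 at rate m1 per generation, and a lineage in deme 2 moves
// to deme 1 at rate m2. Pairwise coalescence within a deme of diploid size N
// occurs at rate 1/(2N) per pair. R's RNG is used throughout so results are
// reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Lineage {
  int node;   // node index in the output tree
  int deme;   // 0 or 1 (or 0 after the ancestral merge)
  int d1, d2; // descendant leaf counts per deme (for SFS accumulation)
};

inline int pick(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// index of the j-th (0-based) active lineage in `deme`; pooled when deme < 0
inline int nth_in_deme(const std::vector<Lineage>& act, int deme, int j) {
  for (int i = 0; i < (int)act.size(); ++i) {
    if (deme < 0 || act[i].deme == deme) {
      if (j == 0) return i;
      --j;
    }
  }
  return (int)act.size() - 1; // unreachable
}

// Core simulation. If `sfs` is non-null, branch lengths are accumulated into
// sfs(d1, d2) for every active lineage as time advances. If `parent`/`time`
// are non-null the tree topology is recorded (nodes 0..n-1 are leaves,
// deme-0 leaves first).
void run_coalescent(int n1, int n2,
                    double N1, double N2, double Nanc, double TS,
                    double mig_lo, double mig_hi, double m1, double m2,
                    double* sfs, int sfs_nrow,
                    int* parent, double* node_time) {
  const int n = n1 + n2;
  std::vector<Lineage> act;
  act.reserve(n);
  for (int i = 0; i < n1; ++i) act.push_back({i, 0, 1, 0});
  for (int i = 0; i < n2; ++i) act.push_back({n1 + i, 1, 0, 1});
  int next_node = n;
  double t = 0.0;
  bool merged = (TS <= 0.0);
  if (merged) for (auto& L : act) L.deme = 0;
  int k1 = merged ? n : n1, k2 = merged ? 0 : n2;

  // Strong-migration limit: once lineages have migrated many times without
  // any coalescence, deme locations are at their stationary distribution
  // pi = (m2, m1)/(m1+m2) and the structured process converges to a
  // panmictic coalescent with pair rate pi1^2/(2 N1) + pi2^2/(2 N2).
  // Switching to that limit keeps the event count bounded when an optimizer
  // explores migration-dominated parameter regions.
  double pending = 0.0;
  bool strong_mig = false;
  long mig_since_coal = 0;
  const long mig_cap = 10L * n + 100L;
  double pi1 = 0.5;
  if (m1 + m2 > 0) pi1 = m2 / (m1 + m2);

  while ((int)act.size() > 1) {
    double c1, c2, r1, r2;
    if (strong_mig && !merged) {
      int k = (int)act.size();
      double pair_rate = pi1 * pi1 / (2.0 * N1) +
        (1.0 - pi1) * (1.0 - pi1) / (2.0 * N2);
      c1 = k * (k - 1) / 2.0 * pair_rate; // pooled coalescence
      c2 = 0.0; r1 = 0.0; r2 = 0.0;
    } else {
      double NN1 = merged ? Nanc : N1;
      c1 = k1 * (k1 - 1) / 2.0 / (2.0 * NN1);
      c2 = merged ? 0.0 : k2 * (k2 - 1) / 2.0 / (2.0 * N2);
      bool mig_on = !merged && t >= mig_lo && t < mig_hi && (m1 > 0 || m2 > 0);
      r1 = mig_on ? k1 * m1 : 0.0;
      r2 = mig_on ? k2 * m2 : 0.0;
    }
    double tot = c1 + c2 + r1 + r2;

    // next structural boundary ahead of t
    double bound = R_PosInf;
    if (!merged) {
      if (t < mig_lo && (m1 > 0 || m2 > 0)) bound = std::min(bound, mig_lo);
      if (t >= mig_lo && t < mig_hi) bound = std::min(bound, mig_hi);
      bound = std::min(bound, TS);
    }

    double dt;
    bool event;
    if (tot <= 0.0) {
      if (!R_FINITE(bound)) stop("coalescent stalled: no events and no boundary");
      dt = bound - t;
      event = false;
    } else {
      dt = exp_rand() / tot;
      if (t + dt >= bound) { dt = bound - t; event = false; }
      else event = true;
    }

    // lazy accumulation: lineage classes (d1, d2) only change at
    // coalescences, so elapsed time is flushed to the matrix just before
    // one executes (migration and boundary events leave classes intact)
    pending += dt;
    t += dt;

    if (!event) {
      if (!merged && t >= TS) {
        merged = true;
        strong_mig = false;
        for (auto& L : act) L.deme = 0;
        k1 = (int)act.size(); k2 = 0;
      } else if (strong_mig && t >= mig_hi) {
        // migration epoch over: draw demes from the stationary distribution
        strong_mig = false;
        mig_since_coal = 0;
        k1 = 0; k2 = 0;
        for (auto& L : act) {
          L.deme = (unif_rand() < pi1) ? 0 : 1;
          (L.deme == 0 ? k1 : k2)++;
        }
      }
      continue;
    }

    double u = unif_rand() * tot;
    if (u < c1 + c2) {
      if (sfs && pending > 0) {
        for (auto& L : act) sfs[L.d1 + sfs_nrow * L.d2] += pending;
        pending = 0.0;
      }
      mig_since_coal = 0;
      bool pooled = (strong_mig && !merged);
      int deme = pooled ? -1 : ((u < c1) ? 0 : 1);
      int kd = pooled ? (int)act.size() : (deme == 0 ? k1 : k2);
      int a = pick(kd), b = pick(kd - 1);
      if (b >= a) b++;
      int ia = nth_in_deme(act, deme, a);
      int ib = nth_in_deme(act, deme, b);
      Lineage par;
      par.node = next_node++;
      par.deme = pooled ? 0 : deme;
      par.d1 = act[ia].d1 + act[ib].d1;
      par.d2 = act[ia].d2 + act[ib].d2;
      if (parent) {
        parent[act[ia].node] = par.node;
        parent[act[ib].node] = par.node;
        node_time[par.node] = t;
      }
      if (!pooled) { if (deme == 0) k1--; else k2--; }
      else { if (act[ia].deme == 0) k1--; else k2--; } // keep counts sane
      if (ia < ib) std::swap(ia, ib); // erase larger index first
      act.erase(act.begin() + ia);
      act.erase(act.begin() + ib);
      act.push_back(par);
      if (pooled) {
        // recount (labels are meaningless while pooled, counts unused)
        k1 = (int)act.size(); k2 = 0;
      }
    } else if (u < c1 + c2 + r1) {
      act[nth_in_deme(act, 0, pick(k1))].deme = 1;
      k1--; k2++;
      if (++mig_since_coal > mig_cap) strong_mig = true;
    } else {
      act[nth_in_deme(act, 1, pick(k2))].deme = 0;
      k2--; k1++;
      if (++mig_since_coal > mig_cap) strong_mig = true;
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(int n1, int n2, double N1, double N2, double Nanc,
                       double TS, double mig_lo, double mig_hi,
                       double m1, double m2) {
  int n = n1 + n2;
  if (n < 2) stop("need at least two lineages");
  IntegerVector parent(2 * n - 1, NA_INTEGER);
  NumericVector node_time(2 * n - 1, 0.0);
  run_coalescent(n1, n2, N1, N2, Nanc, TS, mig_lo, mig_hi, m1, m2,
                 nullptr, 0, INTEGER(parent), REAL(node_time));
  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["n1"] = n1, _["n2"] = n2);
}

//' @noRd
// [[Rcpp::export(name = ".sfs_branch_cpp")]]
NumericMatrix sfs_branch_cpp(int n1, int n2, double N1, double N2, double Nanc,
                             double TS, double mig_lo, double mig_hi,
                             double m1, double m2, int n_loci) {
  NumericMatrix acc(n1 + 1, n2 + 1);
  double* p = REAL(acc);
  for (int l = 0; l < n_loci; ++l)
    run_coalescent(n1, n2, N1, N2, Nanc, TS, mig_lo, mig_hi, m1, m2,
                   p, n1 + 1, nullptr, nullptr);
  // the root lineage (carrying all n1+n2 leaves) accrues no length because
  // the loop stops at k == 1; zero the corner defensively anyway
  acc(n1, n2) = 0.0;
  return acc;
}
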