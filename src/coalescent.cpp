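#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-constant multi-population coalescent with divergence (merge) and
// instantaneous size-change events, continuous-time approximation: pair
// coalescence rate k(k-1)/(4N) per generation for diploid size N.
//
// events: rows sorted by ascending time; columns
//   0 time (generations before present)
//   1 type: 0 = merge (lineages of `pop` move into pop `value`),
//           1 = resize (`pop` takes diploid size `value` further back in time)
//   2 pop (0-based)
//   3 value (destination pop for merges, new size for resizes)
//
// Each locus carries exactly one segregating mutation. The target law is the
// infinitely-many-sites limit conditioned on the locus being polymorphic in
// the sample: the genealogy is length-biased (a tree of total branch length
// L carries a segregating site with probability proportional to L as the
// mutation rate goes to zero) and the mutation falls uniformly on the total
// branch length. Length biasing is realized by rejection: a simulated tree
// is accepted with probability L / M, where the envelope M is set to twice
// the mean length of a small pilot sample for the same parameter set; the
// rare trees with L > M (about 4 standard deviations above the mean) are
// always accepted, a truncation that affects a negligible fraction of the
// weight. Branches above the MRCA carry no length, so every locus
// segregates in the pooled sample.

struct CoalescentEngine {
  int P;
  int n;
  int n_nodes;
  const IntegerVector &nlin_per_pop;
  const NumericVector &sizes0;
  const NumericMatrix &events;
  std::vector<double> node_time;
  std::vector<int> parent;
  std::vector<std::vector<int> > act;
  std::vector<double> sizes;

  CoalescentEngine(const IntegerVector &nlin, const NumericVector &s0,
                   const NumericMatrix &ev)
      : nlin_per_pop(nlin), sizes0(s0), events(ev) {
    P = nlin.size();
    n = 0;
    for (int p = 0; p < P; ++p) n += nlin[p];
    if (n < 2) stop("need at least 2 lineages in total");
    n_nodes = 2 * n - 1;
    node_time.resize(n_nodes);
    parent.resize(n_nodes);
    act.resize(P);
    sizes.resize(P);
  }

  // build one genealogy; returns its total branch length
  double simulate_tree() {
    for (int p = 0; p < P; ++p) {
      sizes[p] = sizes0[p];
      act[p].clear();
    }
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int k = 0; k < nlin_per_pop[p]; ++k) {
        act[p].push_back(id);
        node_time[id] = 0.0;
        parent[id] = -1;
        ++id;
      }
    double t = 0.0;
    int ev = 0;
    const int nev = events.nrow();
    int nact = n;

    while (nact > 1) {
      double rate = 0.0;
      for (int p = 0; p < P; ++p) {
        const double k = (double)act[p].size();
        if (k >= 2.0) rate += k * (k - 1.0) / (4.0 * sizes[p]);
      }
      double tnext = R_PosInf;
      if (rate > 0.0) tnext = t + R::rexp(1.0 / rate);
      const double tev = (ev < nev) ? events(ev, 0) : R_PosInf;
      if (rate <= 0.0 && ev >= nev)
        stop("lineages cannot fully coalesce: populations never merge");
      if (tev <= tnext) {
        t = tev;
        const int type = (int)events(ev, 1);
        const int p = (int)events(ev, 2);
        if (type == 0) {
          const int q = (int)events(ev, 3);
          for (size_t i = 0; i < act[p].size(); ++i)
            act[q].push_back(act[p][i]);
          act[p].clear();
        } else {
          sizes[p] = events(ev, 3);
        }
        ++ev;
      } else {
        double u = R::runif(0.0, rate), acc = 0.0;
        int psel = -1;
        for (int p = 0; p < P; ++p) {
          const double k = (double)act[p].size();
          if (k >= 2.0) {
            acc += k * (k - 1.0) / (4.0 * sizes[p]);
            psel = p;
            if (u <= acc) break;
          }
        }
        t = tnext;
        const int k = (int)act[psel].size();
        int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        const int a = act[psel][i], b = act[psel][j];
        node_time[id] = t;
        parent[id] = -1;
        parent[a] = id;
        parent[b] = id;
        if (i < j) std::swap(i, j);     // erase the larger index first
        act[psel].erase(act[psel].begin() + i);
        act[psel].erase(act[psel].begin() + j);
        act[psel].push_back(id);
        ++id;
        --nact;
      }
    }
    double total = 0.0;
    for (int v = 0; v < n_nodes - 1; ++v)
      total += node_time[parent[v]] - node_time[v];
    return total;
  }

  // place one mutation uniformly on the total length and write the derived
  // indicators for column loc of out
  void place_mutation(double total, IntegerMatrix &out, int loc) {
    const double u = R::runif(0.0, total);
    double acc = 0.0;
    int branch = n_nodes - 2;
    for (int v = 0; v < n_nodes - 1; ++v) {
      acc += node_time[parent[v]] - node_time[v];
      if (u <= acc) { branch = v; break; }
    }
    for (int leaf = 0; leaf < n; ++leaf) {
      int v = leaf;
      int derived = 0;
      while (v != -1) {
        if (v == branch) { derived = 1; break; }
        v = parent[v];
      }
      out(leaf, loc) = derived;
    }
  }
};

// [[Rcpp::export]]
IntegerMatrix sim_loci_cpp(IntegerVector nlin_per_pop, NumericVector sizes0,
                           NumericMatrix events, int n_loci) {
  CoalescentEngine eng(nlin_per_pop, sizes0, events);
  IntegerMatrix out(eng.n, n_loci);
  RNGScope scope;

  // pilot sample to calibrate the length-bias envelope; the envelope then
  // tracks the running mean length of every simulated tree
  const int n_pilot = 8;
  double lsum = 0.0;
  long lcount = 0;
  for (int i = 0; i < n_pilot; ++i) {
    lsum += eng.simulate_tree();
    ++lcount;
  }

  for (int loc = 0; loc < n_loci; ++loc) {
    double total;
    for (;;) {
      total = eng.simulate_tree();
      lsum += total;
      ++lcount;
      const double M = 2.0 * lsum / lcount;
      if (total >= M || R::unif_rand() < total / M) break;
    }
    eng.place_mutation(total, out, loc);
  }
  return out;
}
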