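// Sequentially Markovian coalescent (SMC') with recombination and
// piecewise-constant population size, used for neutral haplotype samples
// and for initialising the forward simulator at stationarity.
//
// Conventions: time in units of 2*N_ref generations; theta = 4*N_ref*mu*L;
// rho = 4*N_ref*r*L; sequence coordinates are fractions of the locus in
// (0, 1). Pairwise coalescence rate in an epoch of relative size lambda is
// 1/lambda.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Demography {
  std::vector<double> start;  // epoch start times, start[0] == 0
  std::vector<double> size;   // relative sizes, > 0
  bool constant;
  size_t epoch_of(double t) const {
    size_t e = 0;
    while (e + 1 < start.size() && t >= start[e + 1]) ++e;
    return e;
  }
  // First event time after t for an event with instantaneous rate
  // mult / size(t); returns a value >= cap if none occurs before cap.
  double draw_event(double t, double mult, double cap) const {
    if (mult <= 0.0) return R_PosInf;
    if (constant) return t + exp_rand() * size[0] / mult;
    size_t e = epoch_of(t);
    while (true) {
      double rate = mult / size[e];
      double dt = exp_rand() / rate;
      double end = (e + 1 < start.size()) ? start[e + 1] : R_PosInf;
      if (t + dt < std::min(end, cap)) return t + dt;
      if (end >= cap) return cap;
      t = end;
      ++e;
    }
  }
};

// Marginal genealogy plus the persistent state needed to process
// recombination breakpoints cheaply: the sorted internal node times and
// the total branch length are maintained incrementally.
struct Walker {
  int n;
  std::vector<double> time;
  std::vector<int> parent, c1, c2;
  int root;
  Demography dem;

  std::vector<double> sorted_times;  // internal node times, ascending
  double T_tot;
  std::vector<int> stack_buf;

  double blen(int u) const { return time[parent[u]] - time[u]; }

  void recompute_totals() {
    T_tot = 0.0;
    for (int u = 0; u < 2 * n - 1; ++u)
      if (u != root) T_tot += blen(u);
  }

  void init_tree() {
    time.assign(2 * n - 1, 0.0);
    parent.assign(2 * n - 1, -1);
    c1.assign(2 * n - 1, -1);
    c2.assign(2 * n - 1, -1);
    std::vector<int> active(n);
    for (int i = 0; i < n; ++i) active[i] = i;
    double t = 0.0;
    int next = n;
    while ((int)active.size() > 1) {
      int k = (int)active.size();
      t = dem.draw_event(t, 0.5 * k * (k - 1), R_PosInf);
      int i = (int)std::floor(unif_rand() * k);
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      int a = active[i], b = active[j];
      time[next] = t;
      c1[next] = a; c2[next] = b;
      parent[a] = next; parent[b] = next;
      active[i] = next;
      active.erase(active.begin() + j);
      ++next;
    }
    root = next - 1;
    sorted_times.assign(time.begin() + n, time.end());
    std::sort(sorted_times.begin(), sorted_times.end());
    recompute_totals();
  }

  // Uniform point on the branches; returns the node below the point and
  // sets u to its height.
  int sample_branch_point(double &u) const {
    double target = unif_rand() * T_tot;
    int last = -1;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == root) continue;
      double b = time[parent[v]] - time[v];
      if (target < b) { u = time[v] + target; return v; }
      target -= b;
      last = v;
    }
    u = time[last] + 0.5 * blen(last); // numerical fallthrough
    return last;
  }

  void leaves_under(int u, std::vector<int> &out) {
    stack_buf.clear();
    stack_buf.push_back(u);
    while (!stack_buf.empty()) {
      int w = stack_buf.back();
      stack_buf.pop_back();
      if (w < n) out.push_back(w);
      else { stack_buf.push_back(c1[w]); stack_buf.push_back(c2[w]); }
    }
  }

  // SMC' update at one breakpoint.
  void recombine() {
    double u;
    int v = sample_branch_point(u);
    int p = parent[v];

    // lineages crossing height u
    int passed = (int)(std::upper_bound(sorted_times.begin(),
                                        sorted_times.end(), u) -
                       sorted_times.begin());
    int A = n - passed;
    size_t idx = passed;
    double t = u, tstar;
    while (true) {
      double cap = (idx < sorted_times.size()) ? sorted_times[idx]
                                               : R_PosInf;
      double cand = dem.draw_event(t, (double)A, cap);
      if (cand < cap) { tstar = cand; break; }
      t = cap;
      ++idx;
      if (--A < 1) A = 1; // above the root: the ancestral lineage remains
    }

    // uniform choice among the branches crossing tstar
    int A_star = n - (int)(std::upper_bound(sorted_times.begin(),
                                            sorted_times.end(), tstar) -
                           sorted_times.begin());
    if (A_star < 1) A_star = 1;
    int pick = (int)std::floor(unif_rand() * A_star);
    int target = -1;
    if (tstar >= time[root] || A_star == 1) {
      // candidates: only the extended root lineage (or numeric edge)
      target = root;
      if (tstar < time[root]) {
        for (int w = 0; w < 2 * n - 1; ++w) {
          if (w != root && time[w] <= tstar && tstar < time[parent[w]]) {
            target = w;
            break;
          }
        }
      }
    } else {
      for (int w = 0; w < 2 * n - 1; ++w) {
        if (w == root) continue;
        if (time[w] <= tstar && tstar < time[parent[w]]) {
          if (pick == 0) { target = w; break; }
          --pick;
        }
      }
      if (target < 0) target = root; // numeric edge
    }

    if (target == v) return; // re-coalesced onto its own stump: invisible
    if (target == p) target = (c1[p] == v) ? c2[p] : c1[p];

    double old_ptime = time[p];

    // detach v, dissolving p
    int sib = (c1[p] == v) ? c2[p] : c1[p];
    if (p == root) {
      root = sib;
      parent[sib] = -1;
    } else {
      int g = parent[p];
      if (c1[g] == p) c1[g] = sib; else c2[g] = sib;
      parent[sib] = g;
    }

    // re-attach at tstar on target's branch, recycling p
    time[p] = tstar;
    c1[p] = v; c2[p] = target;
    if (parent[target] == -1) { // above the (new) root
      parent[p] = -1;
      root = p;
    } else {
      int pw = parent[target];
      if (c1[pw] == target) c1[pw] = p; else c2[pw] = p;
      parent[p] = pw;
    }
    parent[v] = p;
    parent[target] = p;

    // incremental updates of sorted times
    std::vector<double>::iterator it =
        std::lower_bound(sorted_times.begin(), sorted_times.end(),
                         old_ptime);
    sorted_times.erase(it);
    it = std::lower_bound(sorted_times.begin(), sorted_times.end(), tstar);
    sorted_times.insert(it, tstar);
    recompute_totals();
  }
};

} // namespace

// [[Rcpp::export(name = ".coal_sample")]]
List coal_sample(int n, double theta, double rho,
                 NumericVector epoch_start, NumericVector epoch_size) {
  if (n < 2) stop("need at least 2 haplotypes");
  Walker w;
  w.n = n;
  w.dem.start.assign(epoch_start.begin(), epoch_start.end());
  w.dem.size.assign(epoch_size.begin(), epoch_size.end());
  if (w.dem.start.empty() || w.dem.start[0] != 0.0)
    stop("first epoch must start at time 0");
  if (w.dem.size.empty()) stop("at least one epoch size is required");
  for (size_t i = 0; i < w.dem.size.size(); ++i)
    if (!(w.dem.size[i] > 0)) stop("epoch sizes must be > 0");
  w.dem.constant = (w.dem.size.size() == 1);
  w.init_tree();

  std::vector<double> pos;
  std::vector<std::vector<int> > carriers;
  double x = 0.0;
  while (x < 1.0) {
    double d = (rho > 0.0) ? exp_rand() / (0.5 * rho * w.T_tot) : R_PosInf;
    double seg_end = std::min(1.0, x + d);
    double g = seg_end - x;
    int nmut = (int)R::rpois(0.5 * theta * w.T_tot * g);
    if (nmut > 0) {
      std::vector<double> mp(nmut);
      for (int m = 0; m < nmut; ++m) mp[m] = x + unif_rand() * g;
      std::sort(mp.begin(), mp.end());
      for (int m = 0; m < nmut; ++m) {
        double uu;
        int v = w.sample_branch_point(uu);
        pos.push_back(mp[m]);
        carriers.push_back(std::vector<int>());
        w.leaves_under(v, carriers.back());
      }
    }
    if (seg_end >= 1.0) break;
    x = seg_end;
    w.recombine();
  }

  int S = (int)pos.size();
  IntegerMatrix mat(n, S);
  for (int s = 0; s < S; ++s)
    for (size_t i = 0; i < carriers[s].size(); ++i)
      mat(carriers[s][i], s) = 1;
  return List::create(_["positions"] = NumericVector(pos.begin(), pos.end()),
                      _["alleles"] = mat);
}
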