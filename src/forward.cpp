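// Forward Wright-Fisher simulation of the selection phase of a sweep in a
// rescaled population, starting from a stationary neutral population.
//
// Haplotypes carry sorted neutral mutation positions (fractions of the
// locus in (0,1)) plus the state of a single adaptive site at position 0.5.
// Co-dominant selection: diploid fitness 1 : 1+s : 1+2s in the number of
// adaptive copies. Origin labels identify the mutational origin each
// adaptive copy descends from.
//
// Modes: 0 = neutral, run `fixed_gens` generations;
//        1 = de novo: selection + recurrent adaptive mutation until the
//            combined adaptive frequency first reaches PF, then a neutral
//            aging phase of `te_gens` generations;
//        2 = standing variation: a single copy drifts neutrally until it
//            first reaches f0 (rejection on loss), carriers are then
//            relabelled as distinct standing origins and selection runs
//            until PF, then aging;
//        3 = de novo with fixed selection duration (no PF conditioning),
//            used by the admixture template.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Pop {
  int nhap;                                  // 2 * N'
  std::vector<std::vector<double> > muts;    // sorted positions per haplotype
  std::vector<int> orig;                     // 0 = no adaptive copy
};

int count_carriers(const Pop &p) {
  int c = 0;
  for (int i = 0; i < p.nhap; ++i) if (p.orig[i] > 0) ++c;
  return c;
}

// One generation of reproduction into `next`.
void generation(const Pop &cur, Pop &next, double sel, bool select_on,
                double mu_g, double rr_g, double mua_g, bool adapt_on,
                int &origin_counter) {
  int np = cur.nhap / 2;
  std::vector<double> cumw(np);
  double tot = 0.0;
  for (int i = 0; i < np; ++i) {
    double w = 1.0;
    if (select_on) {
      int copies = (cur.orig[2 * i] > 0) + (cur.orig[2 * i + 1] > 0);
      w += sel * copies;
    }
    tot += w;
    cumw[i] = tot;
  }
  next.nhap = cur.nhap;
  next.muts.resize(cur.nhap);
  next.orig.assign(cur.nhap, 0);

  for (int j = 0; j < cur.nhap; ++j) {
    // pick a diploid parent proportional to fitness
    double r = unif_rand() * tot;
    int par = (int)(std::lower_bound(cumw.begin(), cumw.end(), r) - cumw.begin());
    if (par >= np) par = np - 1;
    int hA = 2 * par + (unif_rand() < 0.5 ? 0 : 1);
    int hB = 2 * par + 1 - (hA - 2 * par);

    std::vector<double> &gam = next.muts[j];
    gam.clear();
    int ncx = (int)R::rpois(rr_g);
    if (ncx == 0) {
      gam = cur.muts[hA];
      next.orig[j] = cur.orig[hA];
    } else {
      std::vector<double> bp(ncx);
      for (int k = 0; k < ncx; ++k) bp[k] = unif_rand();
      std::sort(bp.begin(), bp.end());
      bp.push_back(1.0);
      const std::vector<double> *src[2] = { &cur.muts[hA], &cur.muts[hB] };
      size_t ptr[2] = { 0, 0 };
      int which = 0;
      double lo = 0.0;
      for (size_t k = 0; k < bp.size(); ++k) {
        double hi = bp[k];
        // copy mutations of src[which] in [lo, hi)
        const std::vector<double> &sv = *src[which];
        size_t &q = ptr[which];
        while (q < sv.size() && sv[q] < lo) ++q;
        while (q < sv.size() && sv[q] < hi) { gam.push_back(sv[q]); ++q; }
        // adaptive site at 0.5
        if (lo <= 0.5 && 0.5 < hi)
          next.orig[j] = (which == 0) ? cur.orig[hA] : cur.orig[hB];
        lo = hi;
        which = 1 - which;
      }
    }
    // neutral mutation
    int nmut = (int)R::rpois(mu_g);
    for (int k = 0; k < nmut; ++k) {
      double x = unif_rand();
      gam.insert(std::lower_bound(gam.begin(), gam.end(), x), x);
    }
    // adaptive mutation
    if (adapt_on && next.orig[j] == 0 && unif_rand() < mua_g)
      next.orig[j] = ++origin_counter;
  }
}

} // namespace

// [[Rcpp::export(name = ".forward_sweep")]]
List forward_sweep(NumericVector init_positions, IntegerMatrix init_alleles,
                   double mu_g, double rr_g, double sel, double mua_g,
                   int mode, double pf, double f0, int te_gens, int n_samp,
                   int fixed_gens, int max_gen, int max_restarts,
                   IntegerVector init_orig) {
  int nhap = init_alleles.nrow();
  if (nhap < 4 || nhap % 2 != 0) stop("initial population must have an even number (>= 4) of haplotypes");
  if (n_samp > nhap) stop("sample size exceeds population size");

  Pop cur, nxt;
  cur.nhap = nhap;
  cur.muts.resize(nhap);
  cur.orig.assign(nhap, 0);
  if (init_orig.size() == nhap)
    for (int i = 0; i < nhap; ++i) cur.orig[i] = init_orig[i];
  {
    // column-major scan keeps per-haplotype positions sorted
    const int *col = INTEGER(init_alleles);
    int S0 = init_alleles.ncol();
    for (int s = 0; s < S0; ++s, col += nhap) {
      double p = init_positions[s];
      for (int i = 0; i < nhap; ++i)
        if (col[i] == 1) cur.muts[i].push_back(p);
    }
  }

  int origin_counter = 0;
  for (int i = 0; i < nhap; ++i)
    if (cur.orig[i] > origin_counter) origin_counter = cur.orig[i];
  long gens = 0;
  int restarts = 0;

  auto step = [&](bool sel_on, bool adapt_on) {
    generation(cur, nxt, sel, sel_on, mu_g, rr_g, mua_g, adapt_on,
               origin_counter);
    std::swap(cur, nxt);
    ++gens;
  };

  if (mode == 0 || mode == 3) {
    bool sel_on = (mode == 3), adapt_on = (mode == 3);
    for (int g = 0; g < fixed_gens; ++g) step(sel_on, adapt_on);
  } else if (mode == 1) { // de novo, condition on reaching PF
    while (true) {
      // While no copy segregates the population is neutral and stationary,
      // so the waiting generations until the next adaptive mutation can be
      // skipped without changing the sampling distribution: force the
      // arrival into the next generation instead.
      bool empty = (count_carriers(cur) == 0);
      step(true, true);
      if (empty && count_carriers(cur) == 0 && mua_g > 0)
        cur.orig[(int)std::floor(unif_rand() * nhap)] = ++origin_counter;
      int c = count_carriers(cur);
      if ((double)c / nhap >= pf) break;
      if (gens > max_gen)
        stop("adaptive allele did not reach PF within max_gen generations");
    }
  } else if (mode == 2) { // standing variation
    bool done = false;
    while (!done) {
      // phase A: neutral drift of a single copy to f0
      for (int i = 0; i < nhap; ++i) cur.orig[i] = 0;
      cur.orig[(int)std::floor(unif_rand() * nhap)] = 1;
      bool hit = false;
      while (true) {
        step(false, false);
        int c = count_carriers(cur);
        if (c == 0) break; // lost: reintroduce
        if ((double)c / nhap >= f0) { hit = true; break; }
        if (gens > max_gen)
          stop("standing allele did not reach f0 within max_gen generations");
      }
      if (!hit) {
        if (++restarts > max_restarts)
          stop("standing-variation conditioning exceeded max_restarts");
        continue;
      }
      // relabel each standing copy as a distinct origin
      origin_counter = 0;
      for (int i = 0; i < nhap; ++i)
        if (cur.orig[i] > 0) cur.orig[i] = ++origin_counter;
      // phase B: selection until PF (loss restarts the conditioning)
      bool lost = false;
      while (true) {
        step(true, false);
        int c = count_carriers(cur);
        if (c == 0) { lost = true; break; }
        if ((double)c / nhap >= pf) break;
        if (gens > max_gen)
          stop("adaptive allele did not reach PF within max_gen generations");
      }
      if (lost) {
        if (++restarts > max_restarts)
          stop("sweep lost during selection; exceeded max_restarts");
        continue;
      }
      done = true;
    }
  } else {
    stop("unknown mode");
  }

  double freq_at_stop = (double)count_carriers(cur) / nhap;

  if (mode == 1 || mode == 2)
    for (int g = 0; g < te_gens; ++g) step(false, false);

  // sample without replacement
  std::vector<int> idx(nhap);
  for (int i = 0; i < nhap; ++i) idx[i] = i;
  for (int i = 0; i < n_samp; ++i) {
    int j = i + (int)std::floor(unif_rand() * (nhap - i));
    std::swap(idx[i], idx[j]);
  }

  // segregating positions in the sample, by sort-and-count
  std::vector<double> all;
  size_t tot = 0;
  for (int i = 0; i < n_samp; ++i) tot += cur.muts[idx[i]].size();
  all.reserve(tot);
  for (int i = 0; i < n_samp; ++i)
    all.insert(all.end(), cur.muts[idx[i]].begin(), cur.muts[idx[i]].end());
  std::sort(all.begin(), all.end());

  int n_adapt = 0;
  for (int i = 0; i < n_samp; ++i) if (cur.orig[idx[i]] > 0) ++n_adapt;
  bool adapt_col = (mode != 0) && n_adapt > 0 && n_adapt < n_samp;

  std::vector<double> segpos;
  for (size_t a = 0; a < all.size();) {
    size_t b = a;
    while (b < all.size() && all[b] == all[a]) ++b;
    size_t cnt = b - a;
    if (cnt < (size_t)n_samp) segpos.push_back(all[a]);
    a = b;
  }
  if (adapt_col)
    segpos.insert(std::lower_bound(segpos.begin(), segpos.end(), 0.5), 0.5);

  int S = (int)segpos.size();
  IntegerMatrix mat(n_samp, S);
  IntegerVector origins(n_samp);
  int *matp = INTEGER(mat);
  int acol0 = adapt_col
                  ? (int)(std::lower_bound(segpos.begin(), segpos.end(), 0.5) -
                          segpos.begin())
                  : -1;
  for (int i = 0; i < n_samp; ++i) {
    const std::vector<double> &mv = cur.muts[idx[i]];
    size_t q = 0;
    for (size_t k = 0; k < mv.size(); ++k) {
      while (q < segpos.size() && segpos[q] < mv[k]) ++q;
      if (q < segpos.size() && segpos[q] == mv[k]) matp[(size_t)q * n_samp + i] = 1;
    }
    origins[i] = cur.orig[idx[i]];
    if (adapt_col && cur.orig[idx[i]] > 0) matp[(size_t)acol0 * n_samp + i] = 1;
  }

  int acol = adapt_col ? acol0 + 1 : NA_INTEGER;
  double pop_freq = (double)count_carriers(cur) / nhap;

  return List::create(
      _["positions"] = NumericVector(segpos.begin(), segpos.end()),
      _["alleles"] = mat,
      _["origins"] = origins,
      _["adaptive_col"] = acol,
      _["freq_at_stop"] = freq_at_stop,
      _["final_freq"] = pop_freq,
      _["generations"] = (double)gens,
      _["restarts"] = restarts);
}
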