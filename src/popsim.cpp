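// Forward-in-time Wright-Fisher engine over sparse haplotypes.
//
// A haplotype is the sorted vector of bp positions (0-based ints) at which
// the chromosome carries the derived allele "1".  Recombination follows the
// Haldane model (Poisson crossover count, uniform positions, no
// interference); mutation is infinite-sites: each new mutation takes a bp
// position not currently occupied by a segregating site.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::vector<int> Hap;

static Hap make_gamete(const Hap &h1, const Hap &h2,
                       double map_length, double phys_len, double mu,
                       std::mt19937_64 &rng,
                       std::unordered_set<int> *active) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  if (phys_len <= 0.0) {
    // degenerate genome: a copy of one parental strand, no mutation
    return (unif(rng) < 0.5) ? h1 : h2;
  }
  int k = 0;
  if (map_length > 0.0) {
    std::poisson_distribution<int> pois_x(map_length);
    k = pois_x(rng);
  }
  std::vector<int> cuts(k);
  for (int i = 0; i < k; ++i)
    cuts[i] = (int)(unif(rng) * phys_len);
  std::sort(cuts.begin(), cuts.end());

  const Hap *cur = &h1, *oth = &h2;
  if (unif(rng) < 0.5) std::swap(cur, oth);

  Hap out;
  out.reserve(std::max(h1.size(), h2.size()) + 4);
  int seg_start = 0;
  for (int i = 0; i <= k; ++i) {
    int seg_end = (i == k) ? (int)phys_len : cuts[i]; // [seg_start, seg_end)
    std::vector<int>::const_iterator lo =
        std::lower_bound(cur->begin(), cur->end(), seg_start);
    std::vector<int>::const_iterator hi =
        std::lower_bound(cur->begin(), cur->end(), seg_end);
    out.insert(out.end(), lo, hi);
    std::swap(cur, oth);
    seg_start = seg_end;
  }

  if (mu > 0.0) {
    std::poisson_distribution<int> pois_m(mu * phys_len);
    int m = pois_m(rng);
    for (int i = 0; i < m; ++i) {
      int pos;
      for (;;) { // redraw on collision with a live site (infinite sites)
        pos = (int)(unif(rng) * phys_len);
        if (!active || active->count(pos) == 0) break;
      }
      if (active) active->insert(pos);
      std::vector<int>::iterator it =
          std::lower_bound(out.begin(), out.end(), pos);
      if (it == out.end() || *it != pos) out.insert(it, pos);
    }
  }
  return out;
}

// Drop sites lost from the population; optionally drop sites fixed in all
// 2n chromosomes.  Rebuilds the active-position set.
static void prune_sites(std::vector<Hap> &pop,
                        std::unordered_set<int> &active,
                        bool prune_fixed) {
  std::unordered_map<int, int> counts;
  counts.reserve(active.size() * 2 + 16);
  for (size_t h = 0; h < pop.size(); ++h)
    for (size_t i = 0; i < pop[h].size(); ++i)
      counts[pop[h][i]] += 1;

  active.clear();
  if (prune_fixed) {
    const int total = (int)pop.size();
    std::unordered_set<int> fixed;
    for (std::unordered_map<int, int>::iterator it = counts.begin();
         it != counts.end(); ++it) {
      if (it->second == total) fixed.insert(it->first);
      else active.insert(it->first);
    }
    if (!fixed.empty()) {
      for (size_t h = 0; h < pop.size(); ++h) {
        Hap &v = pop[h];
        Hap keep;
        keep.reserve(v.size());
        for (size_t i = 0; i < v.size(); ++i)
          if (fixed.count(v[i]) == 0) keep.push_back(v[i]);
        v.swap(keep);
      }
    }
  } else {
    for (std::unordered_map<int, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
      active.insert(it->first);
  }
}

static std::vector<Hap> haps_from_list(const List &haps_in) {
  std::vector<Hap> pop(haps_in.size());
  for (int i = 0; i < haps_in.size(); ++i) {
    IntegerVector v = haps_in[i];
    pop[i] = Hap(v.begin(), v.end());
  }
  return pop;
}

static List haps_to_list(const std::vector<Hap> &pop) {
  List out(pop.size());
  for (size_t i = 0; i < pop.size(); ++i)
    out[i] = IntegerVector(pop[i].begin(), pop[i].end());
  return out;
}

// One meiosis: recombine two parental haplotypes and add new mutations,
// avoiding the positions in `avoid`.
// [[Rcpp::export]]
IntegerVector cpp_meiosis(IntegerVector h1, IntegerVector h2,
                          double map_length, double phys_len, double mu,
                          int seed, IntegerVector avoid) {
  std::mt19937_64 rng((uint64_t)seed);
  std::unordered_set<int> active(avoid.begin(), avoid.end());
  Hap a(h1.begin(), h1.end()), b(h2.begin(), h2.end());
  Hap g = make_gamete(a, b, map_length, phys_len, mu, rng, &active);
  return IntegerVector(g.begin(), g.end());
}

// Propagate a dioecious population (first n/2 individuals are sires, the
// rest dams) for `generations` non-overlapping generations.  Each offspring
// draws a sire and a dam uniformly with replacement and receives one gamete
// from each.  The last generation produces `final_census` offspring.
// [[Rcpp::export]]
List cpp_propagate(List haps_in, int generations, int final_census,
                   double map_length, double phys_len, double mu,
                   int seed, bool prune_fixed, int prune_every) {
  std::vector<Hap> pop = haps_from_list(haps_in);
  int n_ind = (int)pop.size() / 2;
  if ((int)pop.size() != 2 * n_ind || n_ind < 2)
    stop("population must hold two haplotypes for each of >= 2 individuals");
  if (n_ind % 2 != 0)
    stop("number of individuals must be even (equal sires and dams)");

  std::mt19937_64 rng((uint64_t)seed);
  std::unordered_set<int> active;
  for (size_t h = 0; h < pop.size(); ++h)
    active.insert(pop[h].begin(), pop[h].end());

  for (int g = 1; g <= generations; ++g) {
    int n_off = (g == generations) ? final_census : n_ind;
    int n_males = n_ind / 2;
    std::uniform_int_distribution<int> pick_sire(0, n_males - 1);
    std::uniform_int_distribution<int> pick_dam(n_males, n_ind - 1);
    std::vector<Hap> next(2 * (size_t)n_off);
    for (int i = 0; i < n_off; ++i) {
      int s = pick_sire(rng), d = pick_dam(rng);
      next[2 * i] =
          make_gamete(pop[2 * s], pop[2 * s + 1], map_length, phys_len, mu,
                      rng, &active);
      next[2 * i + 1] =
          make_gamete(pop[2 * d], pop[2 * d + 1], map_length, phys_len, mu,
                      rng, &active);
    }
    pop.swap(next);
    n_ind = n_off;
    if (g % prune_every == 0 || g == generations)
      prune_sites(pop, active, prune_fixed);
  }
  if (generations == 0) prune_sites(pop, active, prune_fixed);
  return haps_to_list(pop);
}

// 0/1 haplotype matrix (haplotypes x markers) at sorted marker positions.
// [[Rcpp::export]]
IntegerMatrix cpp_hap_matrix(List haps_in, IntegerVector positions) {
  int nh = haps_in.size(), m = positions.size();
  IntegerMatrix out(nh, m);
  for (int h = 0; h < nh; ++h) {
    IntegerVector v = haps_in[h];
    int i = 0, j = 0;
    while (i < v.size() && j < m) {
      if (v[i] < positions[j]) ++i;
      else if (v[i] > positions[j]) ++j;
      else { out(h, j) = 1; ++i; ++j; }
    }
  }
  return out;
}

// Iterative conditional expectation (ICE) solver for the two-component
// normal-mixture marker model
//   y = mu + sum_j X_j b_j + e,  b_j ~ pi N(0, s1) + (1-pi) N(0, s2).
// Each marker update replaces b_j by its conditional posterior expectation
// given the current residual; the residual is updated incrementally so one
// sweep costs O(n * m).
// [[Rcpp::export]]
List cpp_mixp_ice(NumericMatrix X, NumericVector y, double pi1,
                  double s1, double s2, double se,
                  int max_iter, double tol) {
  int n = X.nrow(), m = X.ncol();
  if (y.size() != n) stop("length(y) must match nrow(X)");
  if (pi1 <= 0.0 || pi1 >= 1.0) stop("pi must lie in (0, 1)");
  if (s1 <= 0.0 || s2 <= 0.0 || se <= 0.0)
    stop("variance components must be positive");

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    NumericMatrix::Column col = X(_, j);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    xtx[j] = s;
  }

  std::vector<double> b(m, 0.0), w(m, 0.0), r(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  const double logpi = std::log(pi1), log1mpi = std::log(1.0 - pi1);
  double maxdelta = R_PosInf;
  int it = 0;
  while (it < max_iter && maxdelta >= tol) {
    ++it;
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    mu += rbar;
    for (int i = 0; i < n; ++i) r[i] -= rbar;

    maxdelta = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      NumericMatrix::Column col = X(_, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += col[i] * r[i];
      rhs += xtx[j] * b[j];
      // conditional posterior means under each component
      double m1 = rhs / (xtx[j] + se / s1);
      double m2 = rhs / (xtx[j] + se / s2);
      // marginal likelihood of rhs = X_j' (y - rest): N(0, xtx^2 s_c + xtx se)
      double v1 = xtx[j] * xtx[j] * s1 + xtx[j] * se;
      double v2 = xtx[j] * xtx[j] * s2 + xtx[j] * se;
      double ll1 = logpi - 0.5 * std::log(v1) - 0.5 * rhs * rhs / v1;
      double ll2 = log1mpi - 0.5 * std::log(v2) - 0.5 * rhs * rhs / v2;
      double wj = 1.0 / (1.0 + std::exp(ll2 - ll1));
      double bnew = wj * m1 + (1.0 - wj) * m2;
      double diff = bnew - b[j];
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) r[i] -= col[i] * diff;
      b[j] = bnew;
      w[j] = wj;
      double ad = std::fabs(diff);
      if (ad > maxdelta) maxdelta = ad;
    }
  }

  return List::create(_["mu"] = mu,
                      _["b"] = NumericVector(b.begin(), b.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = it,
                      _["delta"] = maxdelta,
                      _["converged"] = (maxdelta < tol));
}
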