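#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Forward Wright-Fisher simulator with diploid additive selection,
// crossover recombination and infinite-sites mutation on an integer grid
// of positions 1..L. Haplotypes are sorted vectors of derived positions.
// All randomness goes through R's RNG so runs are reproducible under
// set.seed() from the R side.

typedef std::vector<int> Hap;

static inline int runif_int(int n) {
  // uniform integer in 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static Hap make_gamete(const Hap& h1, const Hap& h2, double rhoL, int L) {
  const Hap* cur = (unif_rand() < 0.5) ? &h1 : &h2;
  const Hap* oth = (cur == &h1) ? &h2 : &h1;
  int nco = (int) R::rpois(rhoL);
  if (nco == 0) return *cur;
  std::vector<int> bp(nco);
  for (int i = 0; i < nco; ++i) bp[i] = 1 + runif_int(L - 1); // between pos b and b+1
  std::sort(bp.begin(), bp.end());
  bp.push_back(L + 1);
  Hap g;
  g.reserve(std::max(h1.size(), h2.size()) + 4);
  int lo = 0;
  for (size_t seg = 0; seg < bp.size(); ++seg) {
    int hi = bp[seg];
    Hap::const_iterator a = std::upper_bound(cur->begin(), cur->end(), lo);
    Hap::const_iterator b = std::upper_bound(cur->begin(), cur->end(), hi);
    g.insert(g.end(), a, b);
    lo = hi;
    std::swap(cur, oth);
  }
  return g;
}

static void add_mutations(Hap& g, double muL, int L,
                          std::unordered_set<int>& occupied) {
  int nmut = (int) R::rpois(muL);
  for (int m = 0; m < nmut; ++m) {
    int pos = 0;
    for (int tries = 0; tries < 10000; ++tries) {
      pos = 1 + runif_int(L);
      if (occupied.find(pos) == occupied.end()) break;
      pos = 0;
    }
    if (pos == 0) continue; // region saturated; drop the mutation
    occupied.insert(pos);
    g.insert(std::lower_bound(g.begin(), g.end(), pos), pos);
  }
}

static inline bool carries(const Hap& h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// Remove positions fixed in the whole population (invisible to downstream
// polymorphism statistics) and release lost/fixed positions for reuse by
// new mutations -- a removed column is equivalent to a fresh site under the
// infinite-sites model. The beneficial position is never released so its
// frequency stays observable.
static void prune_fixed(std::vector<Hap>& pop, int keep_pos,
                        std::unordered_set<int>& occupied) {
  std::unordered_map<int, int> cnt;
  for (size_t i = 0; i < pop.size(); ++i)
    for (size_t j = 0; j < pop[i].size(); ++j) cnt[pop[i][j]]++;
  std::unordered_set<int> fixed;
  int n = (int) pop.size();
  occupied.clear();
  occupied.insert(keep_pos);
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it) {
    if (it->second == n && it->first != keep_pos) fixed.insert(it->first);
    else occupied.insert(it->first);
  }
  if (fixed.empty()) return;
  for (size_t i = 0; i < pop.size(); ++i) {
    Hap& h = pop[i];
    Hap out;
    out.reserve(h.size());
    for (size_t j = 0; j < h.size(); ++j)
      if (fixed.find(h[j]) == fixed.end()) out.push_back(h[j]);
    h.swap(out);
  }
}

static void next_generation(const std::vector<Hap>& pop, std::vector<Hap>& nxt,
                            int N, double s, int benef_pos,
                            double muL, double rhoL, int L,
                            std::unordered_set<int>& occupied) {
  std::vector<double> cumw;
  double tot = 0.0;
  bool selected = (s > 0.0 && benef_pos > 0);
  if (selected) {
    cumw.resize(N);
    for (int i = 0; i < N; ++i) {
      int c = (carries(pop[2 * i], benef_pos) ? 1 : 0) +
              (carries(pop[2 * i + 1], benef_pos) ? 1 : 0);
      tot += 1.0 + s * c;
      cumw[i] = tot;
    }
  }
  for (int j = 0; j < N; ++j) {
    for (int par = 0; par < 2; ++par) {
      int p;
      if (selected) {
        double u = unif_rand() * tot;
        p = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
        if (p >= N) p = N - 1;
      } else {
        p = runif_int(N);
      }
      Hap g = make_gamete(pop[2 * p], pop[2 * p + 1], rhoL, L);
      add_mutations(g, muL, L, occupied);
      nxt[2 * j + par].swap(g);
    }
  }
}

static List sample_panel(const std::vector<Hap>& pop, int sample_hap) {
  int H = (int) pop.size();
  std::vector<int> idx(H);
  for (int i = 0; i < H; ++i) idx[i] = i;
  for (int i = 0; i < sample_hap; ++i) {
    int j = i + runif_int(H - i);
    std::swap(idx[i], idx[j]);
  }
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < sample_hap; ++i)
    for (size_t j = 0; j < pop[idx[i]].size(); ++j) cnt[pop[idx[i]][j]]++;
  std::vector<int> positions;
  positions.reserve(cnt.size());
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    positions.push_back(it->first);
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> col;
  for (size_t k = 0; k < positions.size(); ++k) col[positions[k]] = (int) k;
  IntegerMatrix geno(sample_hap, (int) positions.size());
  for (int i = 0; i < sample_hap; ++i) {
    const Hap& h = pop[idx[i]];
    for (size_t j = 0; j < h.size(); ++j) geno(i, col[h[j]]) = 1;
  }
  return List::create(_["positions"] = wrap(positions), _["geno"] = geno);
}

// Two populations splitting from a common ancestor: shared burn-in, then
// both daughters evolve independently for the duration of the sweep that
// fixes (or reaches end_freq) in daughter 2 while daughter 1 stays neutral.
// Models a recent two-breed contrast with a breed-specific sweep.
// [[Rcpp::export(name = ".wf_simulate_pair_cpp")]]
List wf_simulate_pair_cpp(int n_diploids, int seq_len, double mu, double rho,
                          int burnin_gens, double s, int sweep_pos,
                          double end_freq, int sample_hap, int max_attempts,
                          int min_split_gens) {
  int N = n_diploids, L = seq_len, H = 2 * N;
  double muL = mu * (double) L, rhoL = rho * (double) L;
  std::unordered_set<int> occupied;
  occupied.insert(sweep_pos);
  std::vector<Hap> pop(H), nxt(H);
  for (int g = 0; g < burnin_gens; ++g) {
    next_generation(pop, nxt, N, 0.0, 0, muL, rhoL, L, occupied);
    pop.swap(nxt);
    if (g % 25 == 24) prune_fixed(pop, sweep_pos, occupied);
  }
  // NOTE: no fixed-site pruning after the split -- a variant fixed in one
  // daughter may still segregate (or be absent) in the other
  std::vector<Hap> base = pop;
  std::vector<double> trajectory;
  int attempts = 0;
  bool done = false;
  while (!done) {
    ++attempts;
    if (attempts > max_attempts)
      stop("beneficial allele lost in %d attempts; increase s or n_diploids",
           max_attempts);
    pop = base;
    int h0 = runif_int(H);
    pop[h0].insert(std::lower_bound(pop[h0].begin(), pop[h0].end(), sweep_pos),
                   sweep_pos);
    trajectory.clear();
    trajectory.push_back(1.0 / H);
    if (trajectory.back() >= end_freq) break;
    for (;;) {
      next_generation(pop, nxt, N, s, sweep_pos, muL, rhoL, L, occupied);
      pop.swap(nxt);
      int c = 0;
      for (int i = 0; i < H; ++i) if (carries(pop[i], sweep_pos)) ++c;
      double f = (double) c / H;
      trajectory.push_back(f);
      if (c == 0) break;
      if (f >= end_freq) { done = true; break; }
    }
  }
  int split_gens = std::max((int) trajectory.size() - 1, min_split_gens);
  std::vector<Hap> pop1 = base;
  for (int g = 0; g < split_gens; ++g) {
    next_generation(pop1, nxt, N, 0.0, 0, muL, rhoL, L, occupied);
    pop1.swap(nxt);
  }
  List s1 = sample_panel(pop1, sample_hap);
  List s2 = sample_panel(pop, sample_hap);
  return List::create(
    _["positions1"] = s1["positions"], _["geno1"] = s1["geno"],
    _["positions2"] = s2["positions"], _["geno2"] = s2["geno"],
    _["trajectory"] = wrap(trajectory), _["attempts"] = attempts,
    _["split_gens"] = split_gens);
}

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(int n_diploids, int seq_len, double mu, double rho,
                     int burnin_gens, double s, int sweep_pos,
                     double end_freq, int sample_hap, int max_attempts) {
  int N = n_diploids, L = seq_len, H = 2 * N;
  double muL = mu * (double) L, rhoL = rho * (double) L;
  std::unordered_set<int> occupied;
  occupied.insert(sweep_pos); // reserve for the beneficial allele
  std::vector<Hap> pop(H), nxt(H);

  for (int g = 0; g < burnin_gens; ++g) {
    next_generation(pop, nxt, N, 0.0, 0, muL, rhoL, L, occupied);
    pop.swap(nxt);
    if (g % 25 == 24) prune_fixed(pop, sweep_pos, occupied);
  }
  prune_fixed(pop, sweep_pos, occupied);

  std::vector<double> trajectory;
  int attempts = 0;
  if (s > 0.0) {
    std::vector<Hap> base = pop; // post-burn-in state to restart from
    bool done = false;
    while (!done) {
      ++attempts;
      if (attempts > max_attempts)
        stop("beneficial allele lost in %d attempts; increase s or n_diploids",
             max_attempts);
      pop = base;
      int h0 = runif_int(H);
      pop[h0].insert(std::lower_bound(pop[h0].begin(), pop[h0].end(), sweep_pos),
                     sweep_pos);
      trajectory.clear();
      trajectory.push_back(1.0 / H);
      if (trajectory.back() >= end_freq) break;
      for (;;) {
        next_generation(pop, nxt, N, s, sweep_pos, muL, rhoL, L, occupied);
        pop.swap(nxt);
        int c = 0;
        for (int i = 0; i < H; ++i) if (carries(pop[i], sweep_pos)) ++c;
        double f = (double) c / H;
        trajectory.push_back(f);
        if (c == 0) break;                      // lost: reject, restart
        if (f >= end_freq) { done = true; break; }
        if (trajectory.size() % 50 == 0) prune_fixed(pop, sweep_pos, occupied);
      }
    }
  }

  // sample haplotypes without replacement (partial Fisher-Yates)
  std::vector<int> idx(H);
  for (int i = 0; i < H; ++i) idx[i] = i;
  for (int i = 0; i < sample_hap; ++i) {
    int j = i + runif_int(H - i);
    std::swap(idx[i], idx[j]);
  }

  std::unordered_map<int, int> cnt;
  for (int i = 0; i < sample_hap; ++i)
    for (size_t j = 0; j < pop[idx[i]].size(); ++j) cnt[pop[idx[i]][j]]++;
  std::vector<int> positions;
  positions.reserve(cnt.size());
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    positions.push_back(it->first);
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> col;
  for (size_t k = 0; k < positions.size(); ++k) col[positions[k]] = (int) k;

  IntegerMatrix geno(sample_hap, (int) positions.size());
  for (int i = 0; i < sample_hap; ++i) {
    const Hap& h = pop[idx[i]];
    for (size_t j = 0; j < h.size(); ++j) geno(i, col[h[j]]) = 1;
  }

  return List::create(
    _["positions"] = wrap(positions),
    _["geno"] = geno,
    _["trajectory"] = wrap(trajectory),
    _["attempts"] = attempts);
}
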