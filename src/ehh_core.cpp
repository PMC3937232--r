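#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Compiled inner loops for the haplotype-homozygosity walks. Haplotype
// groups are refined site by site: two carriers stay in the same group as
// long as they are identical over every site walked so far. Missing calls
// (NA) get allele code 2 and break homozygosity.

static inline int allele_code(int x) {
  return (x == NA_INTEGER) ? 2 : x;
}

// refine grouping g by the alleles at column j (for the carrier subset);
// returns number of identical pairs remaining
static long refine_and_count(std::vector<int>& g, const IntegerMatrix& h,
                             const std::vector<int>& carriers, int j,
                             std::vector<int>& relabel) {
  int nc = (int) carriers.size();
  std::fill(relabel.begin(), relabel.end(), -1);
  int next_id = 0;
  for (int i = 0; i < nc; ++i) {
    int key = g[i] * 3 + allele_code(h(carriers[i], j));
    if (relabel[key] < 0) relabel[key] = next_id++;
    g[i] = relabel[key];
  }
  std::vector<int> tab(next_id, 0);
  for (int i = 0; i < nc; ++i) tab[g[i]]++;
  long pairs = 0;
  for (int k = 0; k < next_id; ++k)
    pairs += (long) tab[k] * (tab[k] - 1) / 2;
  return pairs;
}

// EHH walk from a core site in one direction. Returns offsets (bp from the
// core, starting at 0), EHH values (starting at 1), and the stop reason.
// [[Rcpp::export(name = ".ehh_walk_cpp")]]
List ehh_walk_cpp(IntegerMatrix h, IntegerVector carriers, int core,
                  int step, int rng_lo, int rng_hi, NumericVector pos,
                  double cutoff, double max_gap) {
  std::vector<int> car(carriers.begin(), carriers.end());
  int nc = (int) car.size();
  double npairs = (double) nc * (nc - 1) / 2.0;
  std::vector<int> g(nc, 0);
  std::vector<int> relabel(3 * (nc + 1), -1);
  std::vector<double> offs(1, 0.0), vals(1, 1.0);
  int j = core;
  std::string reason = "edge";
  for (;;) {
    int nxt = j + step;
    if (nxt < rng_lo || nxt > rng_hi) { reason = "edge"; break; }
    if (std::abs(pos[nxt] - pos[j]) > max_gap) { reason = "gap"; break; }
    double ehh = refine_and_count(g, h, car, nxt, relabel) / npairs;
    offs.push_back(pos[nxt] - pos[core]);
    vals.push_back(ehh);
    j = nxt;
    if (ehh < cutoff) { reason = "cutoff"; break; }
  }
  return List::create(_["offsets"] = wrap(offs), _["values"] = wrap(vals),
                      _["stop_reason"] = reason);
}

// Sum over walk steps of the number of still-identical pairs, used by nSL:
// sum_k P_k where P_k counts carrier pairs identical from the core through
// the k-th consecutive site in the given direction.
// [[Rcpp::export(name = ".nsl_side_sum_cpp")]]
double nsl_side_sum_cpp(IntegerMatrix h, IntegerVector carriers, int core,
                        int step, int rng_lo, int rng_hi) {
  std::vector<int> car(carriers.begin(), carriers.end());
  int nc = (int) car.size();
  std::vector<int> g(nc, 0);
  std::vector<int> relabel(3 * (nc + 1), -1);
  double tot = 0.0;
  int j = core;
  for (;;) {
    int nxt = j + step;
    if (nxt < rng_lo || nxt > rng_hi) break;
    long p = refine_and_count(g, h, car, nxt, relabel);
    if (p == 0) break;
    tot += (double) p;
    j = nxt;
  }
  return tot;
}
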