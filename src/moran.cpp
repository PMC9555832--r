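#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cell-state codes shared with R (see R/population.R).
#define CELL_EMPTY 0
#define CELL_OCC 1
#define CELL_BARRIER 2

namespace {

// Uniform integer in [0, n); unif_rand() is R's stream, so set.seed()
// controls everything here.
inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One death/birth event.  Draw order is fixed: target uniform over
// non-barrier cells; parent index uniform over occupied Moore neighbours
// (drawn only when at least one exists); mutation uniform drawn on every
// birth regardless of mu.  A target with no occupied neighbour is a no-op:
// an occupied target survives, an empty target stays empty.
inline void one_step(std::vector<int> &cs, std::vector<int> &al, int nrow,
                     int ncol, const std::vector<int> &open, double mu,
                     int &next_id, double &noop) {
  int t = open[runif_int((int)open.size())];
  int r = t / ncol, c = t % ncol;
  int nb[8];
  int nn = 0;
  for (int dr = -1; dr <= 1; ++dr) {
    int rr = r + dr;
    if (rr < 0 || rr >= nrow) continue;
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int cc = c + dc;
      if (cc < 0 || cc >= ncol) continue;
      int u = rr * ncol + cc;
      if (cs[u] == CELL_OCC) nb[nn++] = u;
    }
  }
  if (nn == 0) {
    noop += 1.0;
    return;
  }
  int p = nb[runif_int(nn)];
  double um = unif_rand();
  if (um < mu) {
    al[t] = next_id++;
  } else {
    al[t] = al[p];
  }
  cs[t] = CELL_OCC;
}

std::vector<int> to_std(const IntegerVector &x) {
  return std::vector<int>(x.begin(), x.end());
}

} // namespace

// Run n_steps death/birth events.  cell_state/allele are full-grid vectors
// in 0-based row-major order; open holds the 0-based indices of non-barrier
// cells (fixed for the duration of the call).  NA alleles are passed through
// as NA_INTEGER and never read (only occupied cells are parents).
// [[Rcpp::export]]
List cpp_sim_steps(IntegerVector cell_state, IntegerVector allele, int nrow,
                   int ncol, IntegerVector open, double n_steps, double mu,
                   int next_allele_id, double noop_count) {
  if (open.size() == 0) stop("no non-barrier cells to simulate");
  std::vector<int> cs = to_std(cell_state), al = to_std(allele),
                   op = to_std(open);
  int next_id = next_allele_id;
  double noop = noop_count;
  for (double s = 0; s < n_steps; s += 1.0)
    one_step(cs, al, nrow, ncol, op, mu, next_id, noop);
  return List::create(
      _["cell_state"] = IntegerVector(cs.begin(), cs.end()),
      _["allele"] = IntegerVector(al.begin(), al.end()),
      _["next_allele_id"] = next_id, _["noop_count"] = noop);
}

namespace {

// Mark components that are currently fixed (>=1 occupied cell, all sharing
// one allele).  comp[] gives a 1..K label per cell, 0 = untracked.
void check_fixed(const std::vector<int> &cs, const std::vector<int> &al,
                 const std::vector<int> &op, const std::vector<int> &comp,
                 int K, int gen, std::vector<int> &fixed_gen) {
  std::vector<int> first(K + 1, NA_INTEGER);
  std::vector<char> mixed(K + 1, 0), occ(K + 1, 0);
  for (size_t i = 0; i < op.size(); ++i) {
    int u = op[i];
    int k = comp[u];
    if (k <= 0 || cs[u] != CELL_OCC) continue;
    if (!occ[k]) {
      occ[k] = 1;
      first[k] = al[u];
    } else if (al[u] != first[k]) {
      mixed[k] = 1;
    }
  }
  for (int k = 1; k <= K; ++k)
    if (fixed_gen[k] == NA_INTEGER && occ[k] && !mixed[k]) fixed_gen[k] = gen;
}

} // namespace

// Generation-batched run until every tracked component is fixed or
// max_generations have been executed.  Fixation is evaluated on generation
// snapshots only (including the starting one), mirroring the R-level loop;
// both paths consume the RNG stream identically because checks draw nothing.
// [[Rcpp::export]]
List cpp_run_until_fixed(IntegerVector cell_state, IntegerVector allele,
                         int nrow, int ncol, IntegerVector open,
                         IntegerVector comp, int steps_per_gen,
                         int max_generations, double mu, int next_allele_id,
                         double noop_count, int start_generation) {
  if (open.size() == 0) stop("no non-barrier cells to simulate");
  std::vector<int> cs = to_std(cell_state), al = to_std(allele),
                   op = to_std(open), cp = to_std(comp);
  int K = 0;
  for (size_t i = 0; i < cp.size(); ++i)
    if (cp[i] != NA_INTEGER && cp[i] > K) K = cp[i];
  std::vector<int> fixed_gen(K + 1, NA_INTEGER);
  int next_id = next_allele_id;
  double noop = noop_count;
  int gens_run = 0;
  check_fixed(cs, al, op, cp, K, start_generation, fixed_gen);
  auto all_done = [&]() {
    for (int k = 1; k <= K; ++k)
      if (fixed_gen[k] == NA_INTEGER) return false;
    return true;
  };
  while (!all_done() && gens_run < max_generations) {
    for (int s = 0; s < steps_per_gen; ++s)
      one_step(cs, al, nrow, ncol, op, mu, next_id, noop);
    ++gens_run;
    check_fixed(cs, al, op, cp, K, start_generation + gens_run, fixed_gen);
    if (gens_run % 256 == 0) checkUserInterrupt();
  }
  IntegerVector fg(K);
  for (int k = 1; k <= K; ++k) fg[k - 1] = fixed_gen[k];
  return List::create(
      _["cell_state"] = IntegerVector(cs.begin(), cs.end()),
      _["allele"] = IntegerVector(al.begin(), al.end()),
      _["next_allele_id"] = next_id, _["noop_count"] = noop,
      _["fixed_generation"] = fg, _["generations_run"] = gens_run,
      _["cap_hit"] = !all_done());
}
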