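#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted sampling without replacement via the exponential race: unit i gets
// an arrival time Exp(rate = w_i); sorting arrival times ascending reproduces
// sequential sampling with probabilities proportional to the weights,
// renormalized among the units not yet drawn. Uses R's RNG so that all
// determinism flows from set.seed() on the R side.
static void race_order(const NumericVector& weights,
                       std::vector<int>& idx, std::vector<double>& keys) {
  const int n = weights.size();
  for (int i = 0; i < n; ++i) {
    keys[i] = R::exp_rand() / weights[i];
    idx[i] = i;
  }
  std::sort(idx.begin(), idx.end(),
            [&keys](int a, int b) { return keys[a] < keys[b]; });
}

// Recruit units in race order, accumulating twitch force, until the
// accumulated force meets the load (Eq. 1 as a stopping condition).
// Returns the recruited count k; the first k entries of idx are the
// recruited units in sampling order. load <= 0 recruits nothing.
static int recruit_until(const NumericVector& forces, double load,
                         const std::vector<int>& idx, double& total) {
  const int n = forces.size();
  total = 0.0;
  if (load <= 0.0) return 0;
  int k = 0;
  while (k < n) {
    total += forces[idx[k]];
    ++k;
    if (total >= load) break;
  }
  // floating-point shortfall at full recruitment is treated as full load
  return k;
}

// [[Rcpp::export]]
List draw_shift_core(NumericVector forces, NumericVector weights, double load) {
  const int n = forces.size();
  std::vector<int> idx(n);
  std::vector<double> keys(n);
  race_order(weights, idx, keys);
  double total = 0.0;
  const int k = recruit_until(forces, load, idx, total);
  IntegerVector recruited(k);
  for (int j = 0; j < k; ++j) recruited[j] = idx[j] + 1;  // 1-based
  return List::create(_["recruited"] = recruited,
                      _["total_force"] = total);
}

// [[Rcpp::export]]
List sim_rotation_core(NumericVector forces, NumericVector weights,
                       double load, int n_shifts) {
  const int n = forces.size();
  IntegerVector contraction_shifts(n);
  NumericVector shift_R(n_shifts);
  std::vector<int> idx(n);
  std::vector<double> keys(n);
  double total = 0.0;
  for (int s = 0; s < n_shifts; ++s) {
    race_order(weights, idx, keys);
    const int k = recruit_until(forces, load, idx, total);
    for (int j = 0; j < k; ++j) ++contraction_shifts[idx[j]];
    shift_R[s] = static_cast<double>(k) / n;
  }
  return List::create(_["contraction_shifts"] = contraction_shifts,
                      _["shift_R"] = shift_R);
}
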