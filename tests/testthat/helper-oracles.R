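# Fixtures and independent oracles used across test files.

# A pool with prescribed twitch forces (bypasses the power-form generator,
# e.g. for equal-force pools where stopping counts are deterministic).
make_pool <- function(forces) {
  forces <- sort(forces)
  out <- tibble::tibble(unit = seq_along(forces), twitch_force = forces)
  class(out) <- c("mu_pool", class(out))
  out
}

# Exact expected recruitment ratio by exhaustive enumeration of sampling
# orders. Sequential sampling without replacement: the next unit is drawn
# from the remaining ones with probability weight/sum(remaining weights);
# recruitment stops once the accumulated force reaches the load. Branches
# are pruned at the stopping point, so this is exact, not Monte Carlo.
enum_expected_R <- function(forces, weights, load) {
  n <- length(forces)
  if (load <= 0) return(0)
  rec <- function(remaining, acc, count) {
    if (acc >= load) return(count / n)
    w <- weights[remaining]
    w <- w / sum(w)
    s <- 0
    for (j in seq_along(remaining)) {
      i <- remaining[j]
      s <- s + w[j] * rec(remaining[-j], acc + forces[i], count + 1)
    }
    s
  }
  rec(seq_len(n), 0, 0)
}

uniform_policy <- recruitment_policy("uniform")
biased_policy <- function(b = 1) recruitment_policy("small_biased", b)
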