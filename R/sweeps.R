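#' Load sweep: relaxation/contraction ratio vs relative muscle load
#'
#' For each load fraction, runs `n_replicates` independent rotation
#' simulations at `load = fraction * max_strength(pool)` and records the mean
#' and standard deviation, across replicates, of the per-replicate mean
#' relaxation/contraction ratio. Reproduces the falling ratio-vs-load curve
#' of a single muscle loaded ever more heavily.
#'
#' Replicate `k` uses seed `base_seed + k` at every grid point, so grid
#' points share common random numbers: the recruitment order in shift `s` of
#' replicate `k` is identical across loads, and each replicate's ratio curve
#' is exactly non-increasing in load.
#'
#' @param pool a `mu_pool` data frame.
#' @param load_fractions loads as fractions of the pool's maximum strength,
#'   each in `(0, 1]`. Default `seq(0.05, 0.95, by = 0.05)`.
#' @param policy a [recruitment_policy()].
#' @param n_replicates replicate simulations per grid point (default 100).
#' @param n_shifts shift epochs per replicate (default 1000).
#' @param base_seed integer; replicate `k` is seeded with `base_seed + k`.
#' @return A tibble of class `mu_sweep`, one row per grid point, with columns
#'   `condition`, `value`, `mean_ratio`, `sd_ratio`, `feasible`, `policy`,
#'   `n_replicates`, `n_shifts`, `base_seed`; the full parameter record is in
#'   `attr(, "config")`.
#' @examples
#' pool <- mu_pool(50, seed = 1)
#' sweep_load(pool, c(0.2, 0.5, 0.8), n_replicates = 5, n_shifts = 200)
#' @export
sweep_load <- function(pool, load_fractions = seq(0.05, 0.95, by = 0.05),
                       policy = recruitment_policy("uniform"),
                       n_replicates = 100, n_shifts = 1000, base_seed = 1) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  if (!is.numeric(load_fractions) || length(load_fractions) == 0 ||
      any(is.na(load_fractions)) ||
      any(load_fractions <= 0 | load_fractions > 1))
    stop("`load_fractions` must all lie in (0, 1]", call. = FALSE)
  total <- max_strength(pool)
  rows <- purrr::map_dfr(load_fractions, function(fr) {
    ratios <- replicate_mean_ratios(pool, fr * total, policy,
                                    n_replicates, n_shifts, base_seed)
    tibble::tibble(value = fr,
                   mean_ratio = mean(ratios),
                   sd_ratio = if (n_replicates > 1) sd(ratios) else 0,
                   feasible = TRUE)
  })
  new_mu_sweep(rows, "load_fraction", policy, n_replicates, n_shifts,
               base_seed,
               config = list(condition = "load_fraction",
                             grid = load_fractions,
                             policy = unclass(policy),
                             n_units = nrow(pool),
                             max_strength = total,
                             n_replicates = n_replicates,
                             n_shifts = n_shifts,
                             base_seed = base_seed))
}

#' Strength sweep: ratio vs maximum muscle strength at constant load
#'
#' Scales a reference pool by each multiplier and simulates every scaled
#' muscle under one constant absolute load, fixed at
#' `fixed_load_fraction * max_strength(reference_pool)` (20% of the reference
#' muscle by default). Reproduces the rising ratio-vs-strength curve: the
#' weaker the muscle, the more of it must work at once, and the less each
#' unit rests. At `multiplier = fixed_load_fraction` the muscle can only just
#' carry the load, every unit contracts in every shift, and the ratio is
#' exactly 0.
#'
#' Multipliers too small to carry the load are flagged `feasible = FALSE`
#' (with `NA` ratios) rather than dropped.
#'
#' @inheritParams sweep_load
#' @param reference_pool the reference `mu_pool`; the fixed load is a
#'   fraction of this pool's maximum strength.
#' @param strength_multipliers positive scale factors applied to the
#'   reference pool. Default `seq(0.2, 2, by = 0.1)`.
#' @param fixed_load_fraction the constant load as a fraction of the
#'   reference maximum strength (default 0.2).
#' @return A `mu_sweep` tibble with `condition = "strength_multiplier"`.
#' @examples
#' pool <- mu_pool(50, seed = 1)
#' sweep_strength(pool, c(0.3, 1, 2), n_replicates = 5, n_shifts = 200)
#' @export
sweep_strength <- function(reference_pool,
                           strength_multipliers = seq(0.2, 2, by = 0.1),
                           fixed_load_fraction = 0.2,
                           policy = recruitment_policy("uniform"),
                           n_replicates = 100, n_shifts = 1000,
                           base_seed = 1) {
  validate_mu_pool(reference_pool)
  policy <- as_mu_policy(policy)
  if (!is.numeric(strength_multipliers) || length(strength_multipliers) == 0 ||
      any(is.na(strength_multipliers)) || any(strength_multipliers <= 0))
    stop("`strength_multipliers` must all be positive", call. = FALSE)
  if (!is.numeric(fixed_load_fraction) || length(fixed_load_fraction) != 1 ||
      is.na(fixed_load_fraction) || fixed_load_fraction <= 0 ||
      fixed_load_fraction > 1)
    stop("`fixed_load_fraction` must lie in (0, 1]", call. = FALSE)
  ref_strength <- max_strength(reference_pool)
  load <- fixed_load_fraction * ref_strength
  rows <- purrr::map_dfr(strength_multipliers, function(m) {
    scaled <- mu_scale(reference_pool, m)
    if (load > sum(scaled$twitch_force) * (1 + 1e-9)) {
      return(tibble::tibble(value = m, mean_ratio = NA_real_,
                            sd_ratio = NA_real_, feasible = FALSE))
    }
    ratios <- replicate_mean_ratios(scaled, load, policy,
                                    n_replicates, n_shifts, base_seed)
    tibble::tibble(value = m,
                   mean_ratio = mean(ratios),
                   sd_ratio = if (n_replicates > 1) sd(ratios) else 0,
                   feasible = TRUE)
  })
  new_mu_sweep(rows, "strength_multiplier", policy, n_replicates, n_shifts,
               base_seed,
               config = list(condition = "strength_multiplier",
                             grid = strength_multipliers,
                             fixed_load_fraction = fixed_load_fraction,
                             policy = unclass(policy),
                             n_units = nrow(reference_pool),
                             reference_max_strength = ref_strength,
                             n_replicates = n_replicates,
                             n_shifts = n_shifts,
                             base_seed = base_seed))
}

replicate_mean_ratios <- function(pool, load, policy, n_replicates, n_shifts,
                                  base_seed) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 1)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  if (!is.numeric(base_seed) || length(base_seed) != 1 || is.na(base_seed))
    stop("`base_seed` must be a single integer", call. = FALSE)
  purrr::map_dbl(seq_len(n_replicates), function(k) {
    simulate_rotation(pool, load, policy, n_shifts,
                      seed = as.integer(base_seed) + k)$mean_ratio
  })
}

new_mu_sweep <- function(rows, condition, policy, n_replicates, n_shifts,
                         base_seed, config) {
  out <- tibble::tibble(
    condition = condition,
    rows,
    policy = policy$kind,
    n_replicates = as.integer(n_replicates),
    n_shifts = as.integer(n_shifts),
    base_seed = as.integer(base_seed)
  )
  attr(out, "config") <- config
  class(out) <- c("mu_sweep", class(out))
  out
}

#' One-row summary of a sweep
#'
#' @param x a `mu_sweep` tibble.
#' @param ... unused.
#' @return A one-row tibble: condition name, grid size, number of feasible
#'   points, the ratio range, and `trend` — the sign of the Spearman
#'   correlation between condition value and mean ratio (-1 falling,
#'   +1 rising).
#' @export
glance.mu_sweep <- function(x, ...) {
  ok <- x$feasible & is.finite(x$mean_ratio)
  trend <- if (sum(ok) > 2) {
    sign(cor(x$value[ok], x$mean_ratio[ok], method = "spearman"))
  } else NA_real_
  tibble::tibble(
    condition = x$condition[1],
    n_points = nrow(x),
    n_feasible = sum(x$feasible),
    min_ratio = min(x$mean_ratio[ok]),
    max_ratio = max(x$mean_ratio[ok]),
    trend = trend
  )
}

#' Compare uniform and small-unit-biased recruitment
#'
#' Runs the designated sweep twice — once under the uniform policy and once
#' under the small-unit-biased policy — with matched seeds (common random
#' numbers), and stacks the two results. The claim under test is qualitative
#' similarity: both curves move in the same direction, with high rank
#' correlation between them.
#'
#' @inheritParams sweep_load
#' @param sweep `"load"` or `"strength"`.
#' @param grid condition values; defaults to the corresponding sweep's
#'   default grid.
#' @param bias_strength bias exponent of the small-biased policy (default 1).
#' @param fixed_load_fraction constant-load fraction for the strength sweep.
#' @return A tibble of class `mu_bias_comparison`: the two `mu_sweep` results
#'   stacked, distinguished by the `policy` column. Summarize with
#'   [glance.mu_bias_comparison()].
#' @examples
#' pool <- mu_pool(50, seed = 1)
#' cmp <- compare_bias(pool, "load", grid = c(0.2, 0.5, 0.8),
#'                     n_replicates = 5, n_shifts = 200)
#' glance(cmp)
#' @export
compare_bias <- function(pool, sweep = c("load", "strength"), grid = NULL,
                         bias_strength = 1, fixed_load_fraction = 0.2,
                         n_replicates = 100, n_shifts = 1000, base_seed = 1) {
  sweep <- match.arg(sweep)
  policies <- list(uniform = recruitment_policy("uniform"),
                   small_biased = recruitment_policy("small_biased",
                                                     bias_strength))
  run_one <- function(policy) {
    if (sweep == "load") {
      sweep_load(pool, grid %||% seq(0.05, 0.95, by = 0.05), policy,
                 n_replicates, n_shifts, base_seed)
    } else {
      sweep_strength(pool, grid %||% seq(0.2, 2, by = 0.1),
                     fixed_load_fraction, policy,
                     n_replicates, n_shifts, base_seed)
    }
  }
  results <- purrr::map(policies, run_one)
  out <- dplyr::bind_rows(results)
  attr(out, "config") <- list(sweep = sweep,
                              bias_strength = bias_strength,
                              uniform = attr(results$uniform, "config"),
                              small_biased = attr(results$small_biased,
                                                  "config"))
  class(out) <- c("mu_bias_comparison", class(out))
  out
}

#' Qualitative similarity of the two policy curves
#'
#' @param x a `mu_bias_comparison` tibble.
#' @param ... unused.
#' @return A one-row tibble: per-policy trend signs, whether they agree, and
#'   the Spearman rank correlation between the two mean-ratio curves over
#'   grid points feasible under both policies.
#' @export
glance.mu_bias_comparison <- function(x, ...) {
  u <- x[x$policy == "uniform", ]
  b <- x[x$policy == "small_biased", ]
  ok <- u$feasible & b$feasible & is.finite(u$mean_ratio) &
    is.finite(b$mean_ratio)
  trend_sign <- function(s) {
    if (sum(ok) > 2) sign(cor(s$value[ok], s$mean_ratio[ok],
                              method = "spearman")) else NA_real_
  }
  tu <- trend_sign(u); tb <- trend_sign(b)
  tibble::tibble(
    trend_uniform = tu,
    trend_small_biased = tb,
    same_direction = identical(tu, tb),
    rank_correlation = cor(u$mean_ratio[ok], b$mean_ratio[ok],
                           method = "spearman")
  )
}

#' Write sweep results to CSV (and the config snapshot to JSON)
#'
#' @param x a `mu_sweep` or `mu_bias_comparison` tibble.
#' @param csv_path output CSV path.
#' @param json_path optional path for the JSON config snapshot.
#' @return `csv_path`, invisibly.
#' @export
write_sweep <- function(x, csv_path, json_path = NULL) {
  stopifnot(inherits(x, "mu_sweep") || inherits(x, "mu_bias_comparison"))
  readr::write_csv(as.data.frame(x), csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(attr(x, "config"), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(csv_path)
}
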