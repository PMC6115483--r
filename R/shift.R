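#' Draw one recruitment shift
#'
#' Samples motor units one at a time without replacement, with probabilities
#' proportional to the policy weights renormalized among the remaining units,
#' accumulating twitch force and stopping as soon as the accumulated force
#' meets the load (the force-balance condition `F = sum of recruited f_i`).
#' The recruited set is therefore minimal under the sampling order: dropping
#' the last-sampled unit would leave the load unmet.
#'
#' A zero load recruits nothing and has recruitment ratio 0 by convention;
#' the relaxation/contraction ratio is undefined there.
#'
#' Randomness is taken from R's global RNG unless `seed` is supplied, in
#' which case the draw is performed under that seed without disturbing the
#' global RNG state.
#'
#' @param pool a `mu_pool` data frame.
#' @param load demanded force, in the pool's force units; must lie in
#'   `[0, max_strength(pool)]` (up to a 1e-9 relative tolerance).
#' @param policy a [recruitment_policy()].
#' @param seed optional integer seed.
#' @return An object of class `mu_shift`: a list with `recruited` (unit
#'   identifiers in sampling order), `recruitment_ratio` (count fraction
#'   `|recruited| / n`), `total_force`, `load`, and `n_units`.
#' @examples
#' pool <- mu_pool(10, seed = 1)
#' draw_shift(pool, 0.5 * max_strength(pool), seed = 7)
#' @export
draw_shift <- function(pool, load, policy = recruitment_policy("uniform"),
                       seed = NULL) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  total <- sum(pool$twitch_force)
  check_load(load, total)
  w <- selection_weights(pool, policy)
  core <- function() draw_shift_core(pool$twitch_force, w, load)
  res <- if (is.null(seed)) core() else withr::with_seed(as.integer(seed), core())
  structure(
    list(recruited = res$recruited,
         recruitment_ratio = length(res$recruited) / nrow(pool),
         total_force = res$total_force,
         load = load,
         n_units = nrow(pool)),
    class = "mu_shift"
  )
}

check_load <- function(load, max_strength, allow_zero = TRUE) {
  if (!is.numeric(load) || length(load) != 1 || is.na(load))
    stop("`load` must be a single number", call. = FALSE)
  if (load < 0 || (!allow_zero && load == 0))
    stop("`load` must be ", if (allow_zero) "non-negative" else "positive",
         call. = FALSE)
  if (load > max_strength * (1 + 1e-9))
    stop(sprintf(
      "infeasible load: %g exceeds the muscle's maximum strength %g",
      load, max_strength), call. = FALSE)
  invisible(load)
}

#' @export
print.mu_shift <- function(x, ...) {
  cat(sprintf(
    "<shift: %d/%d units recruited (R = %.3f), force %.4g for load %.4g>\n",
    length(x$recruited), x$n_units, x$recruitment_ratio, x$total_force,
    x$load))
  invisible(x)
}

#' Monte-Carlo recruitment ratio for a given load
#'
#' Draws `n_draws` independent shifts and summarizes the recruitment ratio R,
#' the fraction of units that must contract simultaneously to carry the load.
#'
#' @inheritParams draw_shift
#' @param n_draws number of independent shifts (default 100).
#' @param seed optional integer seed for the whole set of draws.
#' @return A one-row tibble with columns `mean_R`, `sd_R`, and `n_draws`.
#' @examples
#' pool <- mu_pool(100, seed = 1)
#' expected_recruitment_ratio(pool, 0.5 * max_strength(pool), seed = 2)
#' @export
expected_recruitment_ratio <- function(pool, load,
                                       policy = recruitment_policy("uniform"),
                                       n_draws = 100, seed = NULL) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  if (!is.numeric(n_draws) || length(n_draws) != 1 || is.na(n_draws) ||
      n_draws < 1)
    stop("`n_draws` must be a positive integer", call. = FALSE)
  n_draws <- as.integer(n_draws)
  check_load(load, sum(pool$twitch_force))
  w <- selection_weights(pool, policy)
  core <- function() sim_rotation_core(pool$twitch_force, w, load, n_draws)
  res <- if (is.null(seed)) core() else withr::with_seed(as.integer(seed), core())
  R <- res$shift_R
  tibble::tibble(mean_R = mean(R),
                 sd_R = if (n_draws > 1) sd(R) else 0,
                 n_draws = n_draws)
}
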