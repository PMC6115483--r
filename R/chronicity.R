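#' Energy-crisis threshold load of a muscle
#'
#' The energy crisis is modelled as a threshold phenomenon: it looms once a
#' unit's relaxation/contraction ratio falls below a critical value. This
#' function finds the load at which the simulated mean ratio equals
#' `critical_ratio`, by monotone bisection on the load fraction over
#' `(0, 1]`. Every bisection evaluation reuses the same seed, so the
#' simulated ratio is exactly non-increasing in load (common random numbers)
#' and the bracket shrinks cleanly; the analytic inverse of the rotation
#' relation, `R* = 1/(1 + critical_ratio)` (so load fraction near `R*` under
#' the uniform policy), initializes the bracket.
#'
#' Because recruitment depends on the load only through the load fraction,
#' `threshold_load(pool)/max_strength(pool)` is invariant to pool scaling:
#' with the same seed, a muscle scaled by `m` has exactly `m` times the
#' threshold load.
#'
#' @inheritParams simulate_rotation
#' @param critical_ratio the critical relaxation/contraction ratio; positive.
#'   There is no physiological default — it is a model parameter.
#' @param tolerance bisection half-width on the load *fraction* at which to
#'   stop (default 0.005, i.e. 0.5% of maximum strength).
#' @param n_shifts shift epochs per ratio evaluation (default 2000).
#' @param seed integer seed shared by all bisection evaluations (default 1).
#' @param max_iter iteration cap; exceeded brackets raise an error carrying
#'   the bracket.
#' @return The threshold load in the pool's force units, with attributes
#'   `fraction` (load fraction), `achieved_ratio` (simulated mean ratio at
#'   the threshold), `critical_ratio`, and `iterations`.
#' @examples
#' pool <- mu_pool(100, seed = 1)
#' threshold_load(pool, critical_ratio = 1, n_shifts = 500)
#' @export
threshold_load <- function(pool, critical_ratio,
                           policy = recruitment_policy("uniform"),
                           tolerance = 0.005, n_shifts = 2000, seed = 1,
                           max_iter = 60) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  if (!is.numeric(critical_ratio) || length(critical_ratio) != 1 ||
      is.na(critical_ratio) || critical_ratio <= 0)
    stop("`critical_ratio` must be a single positive number", call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1 || is.na(tolerance) ||
      tolerance <= 0)
    stop("`tolerance` must be a single positive number", call. = FALSE)
  total <- max_strength(pool)
  ratio_at <- function(fraction) {
    simulate_rotation(pool, fraction * total, policy, n_shifts,
                      seed = as.integer(seed))$mean_ratio
  }

  # analytic initializer: under uniform rotation, ratio(fraction) is near
  # (1 - fraction)/fraction, so the root is near R* = 1/(1 + critical_ratio)
  r_star <- 1 / (1 + critical_ratio)
  lo <- max(1e-6, 0.5 * r_star)
  hi <- min(1, 2 * r_star)
  # widen until the bracket straddles the critical ratio (ratio decreasing)
  iter <- 0
  while (ratio_at(lo) < critical_ratio && lo > 1e-9) {
    lo <- lo / 2; iter <- iter + 1
    if (iter > max_iter)
      stop(sprintf("no bracket: ratio at fraction %g is below %g",
                   lo, critical_ratio), call. = FALSE)
  }
  while (ratio_at(hi) > critical_ratio && hi < 1) {
    hi <- min(1, hi * 1.5); iter <- iter + 1
    if (iter > max_iter)
      stop(sprintf("no bracket: ratio at fraction %g is above %g",
                   hi, critical_ratio), call. = FALSE)
  }

  while (hi - lo > tolerance) {
    iter <- iter + 1
    if (iter > max_iter)
      stop(sprintf(
        "threshold bisection did not converge: bracket [%g, %g] after %d iterations",
        lo, hi, iter), call. = FALSE)
    mid <- (lo + hi) / 2
    if (ratio_at(mid) > critical_ratio) lo <- mid else hi <- mid
  }
  fraction <- (lo + hi) / 2
  structure(fraction * total,
            fraction = fraction,
            achieved_ratio = ratio_at(fraction),
            critical_ratio = critical_ratio,
            iterations = iter)
}

#' Simulate the gradual transition of myofascial pain to chronicity
#'
#' Illustrative trajectory of a weakening muscle: total strength declines
#' over time, the energy-crisis threshold load declines in proportion (a
#' weaker muscle has a lower threshold — the threshold is a fixed fraction of
#' current strength, by scale invariance of the recruitment model), and the
#' day-to-day applied load fluctuates around a stationary level. A pain
#' episode is flagged whenever the applied load exceeds the current
#' threshold; as the muscle weakens, episodes become more frequent until
#' everyday loads exceed the threshold and chronicity ensues.
#'
#' The threshold fraction is computed once from the initial pool via
#' [threshold_load()] (or supplied directly) and propagated by scale
#' invariance, rather than re-simulated at every time step.
#'
#' @inheritParams threshold_load
#' @param pool the initial `mu_pool` (the healthy muscle).
#' @param decline_rate per-time-unit strength decline; `>= 0`.
#' @param critical_ratio critical relaxation/contraction ratio (required; no
#'   physiological default exists).
#' @param n_steps number of time steps (default 200).
#' @param decay `"exponential"` (`strength = S0 * exp(-rate * t)`) or
#'   `"linear"` (`strength = S0 * (1 - rate * t)`, which must stay positive
#'   over the trajectory).
#' @param load_series optional numeric vector of applied loads (length
#'   `n_steps`, force units). If `NULL`, loads are drawn i.i.d. lognormal
#'   with mean `load_mean_fraction * max_strength(pool)` and coefficient of
#'   variation `load_cv`.
#' @param load_mean_fraction mean applied load as a fraction of the initial
#'   maximum strength (default 0.3).
#' @param load_cv coefficient of variation of the lognormal load (default
#'   0.4).
#' @param threshold_fraction optional known threshold fraction (load/strength
#'   at the critical ratio); skips the bisection when supplied.
#' @param seed integer seed for the load draws and the threshold bisection.
#' @return A tibble of class `mu_chronicity` with columns `time`, `strength`,
#'   `threshold_load`, `applied_load`, `episode`; parameters are kept in
#'   `attr(, "config")`.
#' @examples
#' pool <- mu_pool(50, seed = 1)
#' traj <- simulate_chronicity(pool, decline_rate = 0.005, critical_ratio = 1,
#'                             n_steps = 50, n_shifts = 300, seed = 2)
#' glance(traj)
#' @export
simulate_chronicity <- function(pool, decline_rate, critical_ratio,
                                n_steps = 200,
                                decay = c("exponential", "linear"),
                                load_series = NULL,
                                load_mean_fraction = 0.3, load_cv = 0.4,
                                policy = recruitment_policy("uniform"),
                                threshold_fraction = NULL,
                                tolerance = 0.005, n_shifts = 2000,
                                seed = 1) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  decay <- match.arg(decay)
  if (!is.numeric(decline_rate) || length(decline_rate) != 1 ||
      is.na(decline_rate) || decline_rate < 0)
    stop("`decline_rate` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || is.na(n_steps) ||
      n_steps < 1)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  n_steps <- as.integer(n_steps)

  s0 <- max_strength(pool)
  time <- seq_len(n_steps) - 1
  strength <- switch(decay,
    exponential = s0 * exp(-decline_rate * time),
    linear = s0 * (1 - decline_rate * time)
  )
  if (any(strength <= 0))
    stop("linear decline reaches zero strength within the trajectory; ",
         "reduce `decline_rate` or `n_steps`", call. = FALSE)

  if (is.null(threshold_fraction)) {
    thr <- threshold_load(pool, critical_ratio, policy,
                          tolerance = tolerance, n_shifts = n_shifts,
                          seed = seed)
    threshold_fraction <- attr(thr, "fraction")
  }
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("`threshold_fraction` must lie in (0, 1]", call. = FALSE)
  threshold <- threshold_fraction * strength

  if (is.null(load_series)) {
    if (load_mean_fraction <= 0)
      stop("`load_mean_fraction` must be positive", call. = FALSE)
    m <- load_mean_fraction * s0
    sdlog <- sqrt(log(1 + load_cv^2))
    meanlog <- log(m) - sdlog^2 / 2
    load_series <- withr::with_seed(as.integer(seed),
                                    rlnorm(n_steps, meanlog, sdlog))
  }
  if (!is.numeric(load_series) || length(load_series) != n_steps ||
      any(is.na(load_series)) || any(load_series < 0))
    stop("`load_series` must be ", n_steps,
         " non-negative loads in force units", call. = FALSE)

  out <- tibble::tibble(
    time = time,
    strength = strength,
    threshold_load = threshold,
    applied_load = load_series,
    episode = load_series > threshold
  )
  attr(out, "config") <- list(
    decline_rate = decline_rate, critical_ratio = critical_ratio,
    decay = decay, threshold_fraction = threshold_fraction,
    load_mean_fraction = load_mean_fraction, load_cv = load_cv,
    policy = unclass(policy), n_steps = n_steps, seed = seed,
    initial_strength = s0
  )
  class(out) <- c("mu_chronicity", class(out))
  out
}

#' One-row summary of a chronicity trajectory
#'
#' @param x a `mu_chronicity` tibble.
#' @param ... unused.
#' @return A one-row tibble: episode count, episode frequency in the first
#'   and last quartile of the trajectory, and the first time at which every
#'   subsequent step is an episode (`NA` if chronicity is never reached).
#' @export
glance.mu_chronicity <- function(x, ...) {
  n <- nrow(x)
  q <- max(1L, floor(n / 4))
  chronic_from <- if (x$episode[n]) {
    last_ok <- max(which(!x$episode), -Inf)
    if (is.infinite(last_ok)) x$time[1] else x$time[last_ok + 1]
  } else NA_real_
  tibble::tibble(
    n_steps = n,
    n_episodes = sum(x$episode),
    freq_first_quartile = mean(x$episode[seq_len(q)]),
    freq_last_quartile = mean(x$episode[seq.int(n - q + 1, n)]),
    chronic_from = chronic_from
  )
}

#' Write a chronicity trajectory to CSV
#'
#' @param x a `mu_chronicity` tibble.
#' @param csv_path output CSV path.
#' @param json_path optional path for the JSON config snapshot.
#' @return `csv_path`, invisibly.
#' @export
write_chronicity <- function(x, csv_path, json_path = NULL) {
  stopifnot(inherits(x, "mu_chronicity"))
  readr::write_csv(as.data.frame(x), csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(attr(x, "config"), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(csv_path)
}
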