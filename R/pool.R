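#' Generate a motor-unit pool with power-distributed twitch forces
#'
#' Builds the model muscle: `n` motor units whose twitch forces span
#' `[1, force_range_ratio]` force units on a power-form curve with many small
#' units and few large ones, the standard construction for motor-unit pool
#' models. Unit `i` receives force
#' `force_range_ratio ^ (((i-1)/(n-1))^shape_exponent)`, i.e. exponential
#' spacing when `shape_exponent = 1`; larger exponents concentrate the pool
#' further towards small units. Optional multiplicative lognormal jitter
#' breaks the deterministic spacing while preserving the skew.
#'
#' Force units are arbitrary: loads elsewhere in the package are expressed as
#' fractions of a pool's maximum strength, so the units cancel.
#'
#' @param n number of motor units (default 100).
#' @param force_range_ratio ratio of the largest to the smallest attainable
#'   twitch force; must exceed 1. Default 100, the typical hundred-fold range
#'   in pool models.
#' @param shape_exponent positive curvature parameter of the power form;
#'   1 gives exponential spacing.
#' @param jitter_sd standard deviation (log scale) of multiplicative
#'   lognormal jitter applied to each force; 0 (default) disables jitter.
#' @param seed optional integer seed used for the jitter draw, so that the
#'   same arguments always yield the same pool.
#'
#' @return A tibble of class `mu_pool` with columns `unit` (1..n, unique and
#'   contiguous) and `twitch_force`, sorted ascending by `twitch_force`.
#' @examples
#' pool <- mu_pool(100, seed = 1)
#' max_strength(pool)
#' @export
mu_pool <- function(n = 100, force_range_ratio = 100, shape_exponent = 1,
                    jitter_sd = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(force_range_ratio) || length(force_range_ratio) != 1 ||
      is.na(force_range_ratio) || force_range_ratio <= 1)
    stop("`force_range_ratio` must be a single number > 1", call. = FALSE)
  if (!is.numeric(shape_exponent) || length(shape_exponent) != 1 ||
      is.na(shape_exponent) || shape_exponent <= 0)
    stop("`shape_exponent` must be a single positive number", call. = FALSE)
  if (!is.numeric(jitter_sd) || length(jitter_sd) != 1 || is.na(jitter_sd) ||
      jitter_sd < 0)
    stop("`jitter_sd` must be a single non-negative number", call. = FALSE)

  u <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  forces <- force_range_ratio^(u^shape_exponent)
  if (jitter_sd > 0) {
    jit <- if (is.null(seed)) {
      rlnorm(n, 0, jitter_sd)
    } else {
      withr::with_seed(as.integer(seed), rlnorm(n, 0, jitter_sd))
    }
    forces <- forces * jit
  }
  new_mu_pool(sort(forces))
}

new_mu_pool <- function(forces) {
  out <- tibble::tibble(unit = seq_along(forces), twitch_force = forces)
  class(out) <- c("mu_pool", class(out))
  out
}

#' Validate a motor-unit pool
#'
#' Checks the `mu_pool` contract: columns `unit` and `twitch_force`, strictly
#' positive forces, unique contiguous unit identifiers, ascending force order.
#'
#' @param pool object to validate.
#' @return `pool`, invisibly, if valid; otherwise an error.
#' @export
validate_mu_pool <- function(pool) {
  if (!is.data.frame(pool) ||
      !all(c("unit", "twitch_force") %in% names(pool)))
    stop("a motor-unit pool needs columns `unit` and `twitch_force`",
         call. = FALSE)
  if (nrow(pool) < 1) stop("a motor-unit pool must contain at least one unit",
                           call. = FALSE)
  if (any(!is.finite(pool$twitch_force)) || any(pool$twitch_force <= 0))
    stop("all twitch forces must be finite and positive", call. = FALSE)
  if (!identical(as.integer(pool$unit), seq_len(nrow(pool))))
    stop("unit identifiers must be 1..n in order", call. = FALSE)
  if (is.unsorted(pool$twitch_force))
    stop("pool must be sorted ascending by twitch_force", call. = FALSE)
  invisible(pool)
}

#' Maximum strength of a pool
#'
#' The maximum force the muscle can generate, i.e. the sum of all twitch
#' forces (full recruitment).
#'
#' @param pool a `mu_pool` data frame.
#' @return A single positive number in the pool's force units.
#' @export
max_strength <- function(pool) {
  validate_mu_pool(pool)
  sum(pool$twitch_force)
}

#' Scale a pool's strength
#'
#' Multiplies every twitch force by `multiplier`, producing a weaker or
#' stronger copy of the same muscle: the maximum strength scales by exactly
#' `multiplier`, and pairwise force ratios between units are preserved.
#'
#' @param pool a `mu_pool` data frame.
#' @param multiplier positive scale factor.
#' @return A `mu_pool` tibble with the same units in the same order.
#' @examples
#' weak <- mu_scale(mu_pool(50), 0.5)
#' @export
mu_scale <- function(pool, multiplier) {
  validate_mu_pool(pool)
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      is.na(multiplier) || multiplier <= 0)
    stop("`multiplier` must be a single positive number", call. = FALSE)
  out <- pool
  out$twitch_force <- pool$twitch_force * multiplier
  out
}

#' Read and write pools as CSV
#'
#' Two-column CSV (`unit`, `twitch_force`) with a header. `write_pool()`
#' prints forces at full precision so that a write/read round trip reproduces
#' the pool exactly.
#'
#' @param pool a `mu_pool` data frame.
#' @param path file path.
#' @return `read_pool()` returns a `mu_pool` tibble; `write_pool()` returns
#'   `path` invisibly.
#' @export
write_pool <- function(pool, path) {
  validate_mu_pool(pool)
  out <- data.frame(unit = pool$unit,
                    # 17 significant digits: lossless for IEEE doubles
                    twitch_force = sprintf("%.17g", pool$twitch_force))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  # base-R parsing (strtod) is correctly rounded, so the round trip is exact
  raw <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  pool <- tibble::tibble(unit = raw$unit, twitch_force = raw$twitch_force)
  class(pool) <- c("mu_pool", class(pool))
  validate_mu_pool(pool)
  pool
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf("<motor-unit pool: %d units, max strength %.4g>\n",
              nrow(x), sum(x$twitch_force)))
  NextMethod()
}
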