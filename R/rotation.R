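#' Analytic relaxation/contraction ratio implied by a recruitment ratio
#'
#' Under rotation, a muscle that keeps a fraction `R` of its units contracted
#' at all times gives each unit, on average, `(1 - R)/R` time units of
#' relaxation per time unit of contraction. The ratio is 1 at `R = 0.5`
#' (one second of rest per second of work) and 0 at full recruitment.
#'
#' @param R recruitment ratio(s) in `(0, 1]`; vectorized.
#' @return `(1 - R)/R`, a non-negative numeric vector.
#' @examples
#' analytic_ratio(c(0.25, 0.5, 1))
#' @export
analytic_ratio <- function(R) {
  if (!is.numeric(R) || length(R) == 0 || any(is.na(R)))
    stop("`R` must be numeric without missing values", call. = FALSE)
  if (any(R <= 0 | R > 1))
    stop("`R` must lie in (0, 1]: the ratio is undefined for an idle muscle",
         call. = FALSE)
  (1 - R) / R
}

#' Simulate rotation recruitment over many shifts
#'
#' Runs `n_shifts` successive shift epochs. In each epoch an independent
#' recruited set is drawn with [draw_shift()]'s sampling scheme; units in the
#' set accrue one `shift_duration` of contraction time and all other units
#' accrue one `shift_duration` of relaxation time (memoryless rotation). The
#' per-unit relaxation/contraction time ratio `t_r/t_c` is then tallied; its
#' mean over units is the headline statistic plotted against load and
#' strength.
#'
#' Units never recruited during the run have infinite ratio; they are
#' excluded from `mean_ratio` and counted in `n_never_contracted`. All
#' reported ratios are dimensionless and invariant to `shift_duration`.
#'
#' @inheritParams draw_shift
#' @param load demanded force in `(0, max_strength]`.
#' @param n_shifts number of shift epochs (default 1000).
#' @param shift_duration duration of one epoch in arbitrary time units
#'   (default 1); a pure scale factor on the reported times.
#' @param seed optional integer seed; the run is reproducible given the seed.
#' @return An object of class `mu_rotation`: a list with a per-unit tibble
#'   `units` (`unit`, `twitch_force`, `contraction_time`, `relaxation_time`,
#'   `ratio`), the summary scalars `mean_ratio` (mean of per-unit ratios over
#'   units with nonzero contraction time), `pooled_ratio` (ratio of summed
#'   relaxation to summed contraction time, the ratio-of-means alternative),
#'   `mean_R`, `n_never_contracted`, and the run parameters.
#' @examples
#' pool <- mu_pool(100, seed = 1)
#' rot <- simulate_rotation(pool, 0.5 * max_strength(pool), seed = 2)
#' glance(rot)
#' @export
simulate_rotation <- function(pool, load,
                              policy = recruitment_policy("uniform"),
                              n_shifts = 1000, shift_duration = 1,
                              seed = NULL) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  if (!is.numeric(n_shifts) || length(n_shifts) != 1 || is.na(n_shifts) ||
      n_shifts < 1)
    stop("`n_shifts` must be a positive integer", call. = FALSE)
  n_shifts <- as.integer(n_shifts)
  if (!is.numeric(shift_duration) || length(shift_duration) != 1 ||
      is.na(shift_duration) || shift_duration <= 0)
    stop("`shift_duration` must be a single positive number", call. = FALSE)
  check_load(load, sum(pool$twitch_force), allow_zero = FALSE)

  w <- selection_weights(pool, policy)
  core <- function() sim_rotation_core(pool$twitch_force, w, load, n_shifts)
  res <- if (is.null(seed)) core() else withr::with_seed(as.integer(seed), core())

  cont_shifts <- res$contraction_shifts
  t_c <- cont_shifts * shift_duration
  t_r <- (n_shifts - cont_shifts) * shift_duration
  ratio <- ifelse(cont_shifts > 0, t_r / t_c, Inf)
  units <- tibble::tibble(
    unit = pool$unit,
    twitch_force = pool$twitch_force,
    contraction_time = t_c,
    relaxation_time = t_r,
    ratio = ratio
  )
  contracted <- cont_shifts > 0
  structure(
    list(units = units,
         mean_ratio = mean(ratio[contracted]),
         pooled_ratio = sum(t_r[contracted]) / sum(t_c[contracted]),
         mean_R = mean(res$shift_R),
         n_never_contracted = sum(!contracted),
         n_shifts = n_shifts,
         shift_duration = shift_duration,
         load = load,
         policy = policy,
         seed = seed),
    class = "mu_rotation"
  )
}

#' @export
print.mu_rotation <- function(x, ...) {
  cat(sprintf(
    paste0("<rotation run: %d shifts, load %.4g, %s policy>\n",
           "  mean R = %.4f,  mean t_r/t_c = %.4f",
           "  (%d unit(s) never contracted)\n"),
    x$n_shifts, x$load, x$policy$kind, x$mean_R, x$mean_ratio,
    x$n_never_contracted))
  invisible(x)
}

#' Per-unit tallies of a rotation run
#'
#' @param x a `mu_rotation` object.
#' @param ... unused.
#' @return A tibble with one row per motor unit: identifier, twitch force,
#'   contraction and relaxation time, and the ratio `t_r/t_c` (infinite for
#'   units never recruited in the run).
#' @export
tidy.mu_rotation <- function(x, ...) x$units

#' One-row summary of a rotation run
#'
#' @param x a `mu_rotation` object.
#' @param ... unused.
#' @return A one-row tibble: `mean_ratio`, `pooled_ratio`, `mean_R`,
#'   `n_never_contracted`, `n_shifts`, `load`, `policy`.
#' @export
glance.mu_rotation <- function(x, ...) {
  tibble::tibble(
    mean_ratio = x$mean_ratio,
    pooled_ratio = x$pooled_ratio,
    mean_R = x$mean_R,
    n_never_contracted = x$n_never_contracted,
    n_shifts = x$n_shifts,
    load = x$load,
    policy = x$policy$kind
  )
}

#' Export a rotation run to CSV and JSON
#'
#' Writes the per-unit table (one row per unit) to `csv_path` and, when
#' `json_path` is given, a run summary (mean R, mean ratio, shift count,
#' seed) as JSON.
#'
#' @param x a `mu_rotation` object.
#' @param csv_path output CSV path.
#' @param json_path optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_rotation <- function(x, csv_path, json_path = NULL) {
  stopifnot(inherits(x, "mu_rotation"))
  readr::write_csv(tidy(x), csv_path)
  if (!is.null(json_path)) {
    summary <- list(mean_R = x$mean_R, mean_ratio = x$mean_ratio,
                    pooled_ratio = x$pooled_ratio, n_shifts = x$n_shifts,
                    n_never_contracted = x$n_never_contracted,
                    load = x$load, policy = x$policy$kind,
                    seed = x$seed)
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}
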