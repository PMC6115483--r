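#' Build a run configuration
#'
#' A `run_config` gathers every knob of a simulation experiment into one
#' serializable record: pool parameters, recruitment policy, the experiment
#' selector and its grid, replication settings, and the base seed. All
#' randomness in a run flows from `base_seed` (plus the pool's own `seed`).
#'
#' @param experiment one of `"load_sweep"`, `"strength_sweep"`,
#'   `"bias_comparison"`, `"chronicity"`, `"single_run"`.
#' @param pool list of [mu_pool()] arguments
#'   (`n`, `force_range_ratio`, `shape_exponent`, `jitter_sd`, `seed`).
#' @param policy list of [recruitment_policy()] arguments
#'   (`kind`, `bias_strength`).
#' @param load_fractions grid for the load sweep (and the `"load"` bias
#'   comparison).
#' @param strength_multipliers grid for the strength sweep (and the
#'   `"strength"` bias comparison).
#' @param fixed_load_fraction constant-load fraction for the strength sweep.
#' @param sweep `"load"` or `"strength"`: which sweep the bias comparison
#'   runs.
#' @param bias_strength bias exponent used by the bias comparison.
#' @param load_fraction load fraction for a single rotation run.
#' @param n_replicates,n_shifts,base_seed replication settings.
#' @param chronicity list of [simulate_chronicity()] arguments
#'   (`decline_rate`, `critical_ratio`, `n_steps`, `decay`,
#'   `load_mean_fraction`, `load_cv`, `threshold_fraction`).
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config("load_sweep", load_fractions = c(0.2, 0.5, 0.8),
#'                   n_replicates = 5, n_shifts = 200)
#' @export
run_config <- function(experiment = c("load_sweep", "strength_sweep",
                                      "bias_comparison", "chronicity",
                                      "single_run"),
                       pool = list(), policy = list(),
                       load_fractions = seq(0.05, 0.95, by = 0.05),
                       strength_multipliers = seq(0.2, 2, by = 0.1),
                       fixed_load_fraction = 0.2,
                       sweep = "load", bias_strength = 1,
                       load_fraction = 0.5,
                       n_replicates = 100, n_shifts = 1000, base_seed = 1,
                       chronicity = list()) {
  experiment <- match.arg(experiment)
  pool_defaults <- list(n = 100, force_range_ratio = 100, shape_exponent = 1,
                        jitter_sd = 0, seed = 1)
  policy_defaults <- list(kind = "uniform", bias_strength = 1)
  # threshold_fraction is intentionally absent by default: when present it
  # short-circuits the bisection in simulate_chronicity()
  chron_defaults <- list(decline_rate = 0.005, critical_ratio = 1,
                         n_steps = 200, decay = "exponential",
                         load_mean_fraction = 0.3, load_cv = 0.4)
  cfg <- structure(list(
    experiment = experiment,
    pool = modifyList(pool_defaults, pool),
    policy = modifyList(policy_defaults, policy),
    load_fractions = load_fractions,
    strength_multipliers = strength_multipliers,
    fixed_load_fraction = fixed_load_fraction,
    sweep = sweep,
    bias_strength = bias_strength,
    load_fraction = load_fraction,
    n_replicates = n_replicates,
    n_shifts = n_shifts,
    base_seed = base_seed,
    chronicity = modifyList(chron_defaults, chronicity)
  ), class = "run_config")
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every numeric field against the preconditions of the operation it
#' feeds; errors name the offending field.
#'
#' @param cfg a `run_config`.
#' @return `cfg`, invisibly annotated, if valid.
#' @export
validate_run_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid config field `%s`: %s", field, why), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  if (!is.list(cfg) || is.null(cfg$experiment)) fail("experiment", "missing")
  if (!cfg$experiment %in% c("load_sweep", "strength_sweep",
                             "bias_comparison", "chronicity", "single_run"))
    fail("experiment", "unknown experiment")
  p <- cfg$pool
  if (!num1(p$n) || p$n < 1 || p$n != floor(p$n))
    fail("pool.n", "must be a positive integer")
  if (!num1(p$force_range_ratio) || p$force_range_ratio <= 1)
    fail("pool.force_range_ratio", "must exceed 1")
  if (!num1(p$shape_exponent) || p$shape_exponent <= 0)
    fail("pool.shape_exponent", "must be positive")
  if (!num1(p$jitter_sd) || p$jitter_sd < 0)
    fail("pool.jitter_sd", "must be non-negative")
  if (!cfg$policy$kind %in% c("uniform", "small_biased"))
    fail("policy.kind", "must be 'uniform' or 'small_biased'")
  if (!num1(cfg$policy$bias_strength) || cfg$policy$bias_strength < 0)
    fail("policy.bias_strength", "must be non-negative")
  if (any(!is.finite(cfg$load_fractions)) ||
      any(cfg$load_fractions <= 0 | cfg$load_fractions > 1))
    fail("load_fractions", "must all lie in (0, 1]")
  if (any(!is.finite(cfg$strength_multipliers)) ||
      any(cfg$strength_multipliers <= 0))
    fail("strength_multipliers", "must all be positive")
  if (!num1(cfg$fixed_load_fraction) || cfg$fixed_load_fraction <= 0 ||
      cfg$fixed_load_fraction > 1)
    fail("fixed_load_fraction", "must lie in (0, 1]")
  if (!cfg$sweep %in% c("load", "strength"))
    fail("sweep", "must be 'load' or 'strength'")
  if (!num1(cfg$bias_strength) || cfg$bias_strength < 0)
    fail("bias_strength", "must be non-negative")
  if (!num1(cfg$load_fraction) || cfg$load_fraction <= 0 ||
      cfg$load_fraction > 1)
    fail("load_fraction", "must lie in (0, 1]")
  if (!num1(cfg$n_replicates) || cfg$n_replicates < 1)
    fail("n_replicates", "must be a positive integer")
  if (!num1(cfg$n_shifts) || cfg$n_shifts < 1)
    fail("n_shifts", "must be a positive integer")
  if (!num1(cfg$base_seed)) fail("base_seed", "must be an integer")
  ch <- cfg$chronicity
  if (!num1(ch$decline_rate) || ch$decline_rate < 0)
    fail("chronicity.decline_rate", "must be non-negative")
  if (!num1(ch$critical_ratio) || ch$critical_ratio <= 0)
    fail("chronicity.critical_ratio", "must be positive")
  if (!num1(ch$n_steps) || ch$n_steps < 1)
    fail("chronicity.n_steps", "must be a positive integer")
  if (!ch$decay %in% c("exponential", "linear"))
    fail("chronicity.decay", "must be 'exponential' or 'linear'")
  invisible(cfg)
}

#' Read and write run configurations as YAML
#'
#' The round trip `write_run_config()` then `read_run_config()` is lossless.
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    list(experiment = raw$experiment %||% "load_sweep"),
    raw[setdiff(names(raw), "experiment")]
  ))
}

#' Execute a configured experiment and write its results
#'
#' Builds the pool and policy from the config, runs the selected experiment,
#' and writes three files into `out_dir`: `results.csv` (the tidy result
#' table), `summary.json` (one-row summary plus the config snapshot), and
#' `config.yaml` (the config as run). The seed, a config hash, and the wall
#' time are logged to stderr; result files depend only on the config, so a
#' rerun reproduces them byte for byte.
#'
#' @param cfg a `run_config` (or a path to a YAML config file).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress the stderr log.
#' @return The experiment's result object, invisibly, with the output paths
#'   in `attr(, "paths")`.
#' @export
run_experiment <- function(cfg, out_dir = ".", quiet = FALSE) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pool <- mu_pool(cfg$pool$n, cfg$pool$force_range_ratio,
                  cfg$pool$shape_exponent, cfg$pool$jitter_sd,
                  cfg$pool$seed)
  policy <- recruitment_policy(cfg$policy$kind, cfg$policy$bias_strength)

  result <- switch(cfg$experiment,
    load_sweep = sweep_load(pool, cfg$load_fractions, policy,
                            cfg$n_replicates, cfg$n_shifts, cfg$base_seed),
    strength_sweep = sweep_strength(pool, cfg$strength_multipliers,
                                    cfg$fixed_load_fraction, policy,
                                    cfg$n_replicates, cfg$n_shifts,
                                    cfg$base_seed),
    bias_comparison = compare_bias(
      pool, cfg$sweep,
      grid = if (cfg$sweep == "load") cfg$load_fractions
             else cfg$strength_multipliers,
      bias_strength = cfg$bias_strength,
      fixed_load_fraction = cfg$fixed_load_fraction,
      n_replicates = cfg$n_replicates, n_shifts = cfg$n_shifts,
      base_seed = cfg$base_seed),
    chronicity = {
      ch <- cfg$chronicity
      simulate_chronicity(pool, ch$decline_rate, ch$critical_ratio,
                          ch$n_steps, ch$decay,
                          load_mean_fraction = ch$load_mean_fraction,
                          load_cv = ch$load_cv, policy = policy,
                          threshold_fraction = ch$threshold_fraction,
                          n_shifts = cfg$n_shifts, seed = cfg$base_seed)
    },
    single_run = simulate_rotation(
      pool, cfg$load_fraction * max_strength(pool), policy,
      cfg$n_shifts, seed = cfg$base_seed)
  )

  csv_path <- file.path(out_dir, "results.csv")
  json_path <- file.path(out_dir, "summary.json")
  cfg_path <- file.path(out_dir, "config.yaml")
  result_table <- if (inherits(result, "mu_rotation")) tidy(result)
                  else as.data.frame(result)
  readr::write_csv(result_table, csv_path)
  jsonlite::write_json(
    list(experiment = cfg$experiment,
         summary = as.list(glance(result)),
         config = unclass(cfg)),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  write_run_config(cfg, cfg_path)

  if (!quiet) {
    message(sprintf(
      "murotation: %s done in %.1f s (base_seed %d, config hash %s)",
      cfg$experiment, proc.time()[["elapsed"]] - t0,
      as.integer(cfg$base_seed), rlang::hash(unclass(cfg))))
  }
  attr(result, "paths") <- c(results = csv_path, summary = json_path,
                             config = cfg_path)
  invisible(result)
}
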