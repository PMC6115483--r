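test_that("the analytic rotation relation (1 - R)/R behaves", {
  expect_equal(analytic_ratio(0.5), 1)
  expect_equal(analytic_ratio(1), 0)
  expect_equal(analytic_ratio(0.25), 3)
  expect_equal(analytic_ratio(c(0.2, 0.4)), c(4, 1.5))
  expect_error(analytic_ratio(0), "\\(0, 1\\]")
  expect_error(analytic_ratio(-0.1), "\\(0, 1\\]")
  expect_error(analytic_ratio(1.2), "\\(0, 1\\]")
})

test_that("maximal load keeps every unit contracted: ratio exactly zero", {
  pool <- mu_pool(100, seed = 1)
  for (pol in list(uniform_policy, biased_policy(1))) {
    rot <- simulate_rotation(pool, max_strength(pool), pol,
                             n_shifts = 200, seed = 2)
    expect_identical(rot$mean_ratio, 0)
    expect_identical(unique(tidy(rot)$ratio), 0)
    expect_identical(rot$mean_R, 1)
    expect_identical(rot$n_never_contracted, 0L)
  }
})

test_that("equal-force units share the load symmetrically", {
  # 4 equal units, load 2.5: every shift recruits exactly 3, so each unit
  # is contracted with probability 3/4 and its ratio converges to 1/3
  eq4 <- make_pool(rep(1, 4))
  rot <- simulate_rotation(eq4, 2.5, n_shifts = 4000, seed = 5)
  expect_equal(rot$mean_R, 0.75)
  expect_true(all(abs(tidy(rot)$ratio - 1 / 3) < 0.05))
})

test_that("contraction and relaxation time partition total time exactly", {
  for (seed in 1:8) {
    n <- sample(3:40, 1)
    pool <- mu_pool(n, force_range_ratio = 50, jitter_sd = 0.1, seed = seed)
    pol <- if (seed %% 2) uniform_policy else biased_policy(0.8)
    # dyadic durations keep count-to-time conversion exact in floating point
    dur <- sample(c(0.5, 1, 2), 1)
    n_shifts <- sample(50:300, 1)
    rot <- simulate_rotation(pool, 0.6 * max_strength(pool), pol,
                             n_shifts = n_shifts, shift_duration = dur,
                             seed = seed)
    u <- tidy(rot)
    expect_identical(u$contraction_time + u$relaxation_time,
                     rep(n_shifts * dur, n))
    ok <- u$contraction_time > 0
    expect_equal(u$ratio[ok], u$relaxation_time[ok] / u$contraction_time[ok])
    expect_true(all(is.infinite(u$ratio[!ok])))
    expect_gte(rot$mean_R, 0)
    expect_lte(rot$mean_R, 1)
  }
})

test_that("per-unit ratios converge to the analytic relation under uniform rotation", {
  pool <- mu_pool(100, seed = 1)
  rot <- simulate_rotation(pool, 0.5 * max_strength(pool), uniform_policy,
                           n_shifts = 5000, seed = 31)
  u <- tidy(rot)
  target <- analytic_ratio(rot$mean_R)
  # per-unit contraction probability p implies ratio (1-p)/p; the standard
  # error of the empirical ratio follows by the delta method
  p_hat <- u$contraction_time / (rot$n_shifts * rot$shift_duration)
  se <- sqrt(p_hat * (1 - p_hat) / rot$n_shifts) / p_hat^2
  z <- abs(u$ratio - target) / se
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 6))
  expect_lt(abs(rot$mean_ratio - target), 0.02)
})

test_that("reported ratios are invariant to shift duration", {
  pool <- mu_pool(60, seed = 2)
  load <- 0.4 * max_strength(pool)
  a <- simulate_rotation(pool, load, n_shifts = 400, shift_duration = 1,
                         seed = 8)
  b <- simulate_rotation(pool, load, n_shifts = 400, shift_duration = 2.5,
                         seed = 8)
  expect_identical(tidy(a)$ratio, tidy(b)$ratio)
  expect_identical(a$mean_ratio, b$mean_ratio)
  expect_equal(tidy(b)$contraction_time, 2.5 * tidy(a)$contraction_time)
})

test_that("small-unit bias shifts contraction time onto small units", {
  pool <- mu_pool(100, seed = 1)
  rot <- simulate_rotation(pool, 0.4 * max_strength(pool), biased_policy(1),
                           n_shifts = 2000, seed = 13)
  u <- tidy(rot)
  expect_lt(cor(u$twitch_force, u$contraction_time, method = "spearman"), 0)
})

test_that("a one-shift simulation agrees with a single drawn shift", {
  pool <- mu_pool(80, seed = 6)
  load <- 0.35 * max_strength(pool)
  s <- draw_shift(pool, load, biased_policy(1), seed = 21)
  rot <- simulate_rotation(pool, load, biased_policy(1), n_shifts = 1,
                           seed = 21)
  u <- tidy(rot)
  expect_setequal(u$unit[u$contraction_time > 0], s$recruited)
  expect_equal(rot$mean_R, s$recruitment_ratio)
})

test_that("rotation results tidy, glance, and export coherently", {
  pool <- mu_pool(30, seed = 3)
  rot <- simulate_rotation(pool, 0.5 * max_strength(pool), n_shifts = 100,
                           seed = 4)
  u <- tidy(rot)
  expect_named(u, c("unit", "twitch_force", "contraction_time",
                    "relaxation_time", "ratio"))
  g <- glance(rot)
  expect_equal(nrow(g), 1)
  expect_equal(g$mean_ratio, rot$mean_ratio)

  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_rotation(rot, csv, json)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 30)
  expect_equal(jsonlite::read_json(json)$mean_R, rot$mean_R)
})
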