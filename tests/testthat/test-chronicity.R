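pool100 <- mu_pool(100, seed = 1)

test_that("the threshold load inverts the ratio-load relation", {
  thr <- threshold_load(pool100, critical_ratio = 1, n_shifts = 1000,
                        seed = 2)
  # ratio 1 needs R = 1/2, reached near half the maximum strength
  expect_lt(abs(attr(thr, "fraction") - 0.5), 0.05)
  expect_lt(abs(attr(thr, "achieved_ratio") - 1), 0.1)

  # a vanishing critical ratio pushes the threshold towards full strength
  thr0 <- threshold_load(pool100, critical_ratio = 0.02, n_shifts = 500,
                         seed = 2)
  expect_gt(attr(thr0, "fraction"), 0.9)

  expect_error(threshold_load(pool100, critical_ratio = -1), "positive")
})

test_that("threshold load scales exactly with muscle strength", {
  base <- threshold_load(pool100, critical_ratio = 1.5, n_shifts = 800,
                         seed = 3)
  for (m in c(0.25, 0.5, 2, 4)) {
    scaled <- threshold_load(mu_scale(pool100, m), critical_ratio = 1.5,
                             n_shifts = 800, seed = 3)
    # recruitment depends only on the load fraction, and the common seed
    # makes the bisection path identical, so scaling is exact
    expect_equal(as.numeric(scaled), m * as.numeric(base))
    expect_identical(attr(scaled, "fraction"), attr(base, "fraction"))
  }
})

test_that("bisection lands where the simulated ratio meets the critical value", {
  for (crit in c(0.5, 2)) {
    thr <- threshold_load(pool100, critical_ratio = crit, tolerance = 0.005,
                          n_shifts = 2000, seed = 4)
    check <- simulate_rotation(pool100, as.numeric(thr), n_shifts = 4000,
                               seed = 99)$mean_ratio
    # the ratio curve has slope ~ -1/fraction^2; allow tolerance * slope
    # plus Monte-Carlo noise
    fr <- attr(thr, "fraction")
    slack <- 0.005 / fr^2 + 6 * crit / sqrt(4000)
    expect_lt(abs(check - crit), slack + 0.05)
  }
})

test_that("constant-strength trajectories cross the threshold all or never", {
  none <- simulate_chronicity(pool100, decline_rate = 0, critical_ratio = 1,
                              n_steps = 50, threshold_fraction = 0.5,
                              load_series = rep(0.3 * max_strength(pool100),
                                                50),
                              seed = 5)
  expect_equal(sum(none$episode), 0)

  all_ep <- simulate_chronicity(pool100, decline_rate = 0, critical_ratio = 1,
                                n_steps = 50, threshold_fraction = 0.5,
                                load_series = rep(0.7 * max_strength(pool100),
                                                  50),
                                seed = 5)
  expect_equal(sum(all_ep$episode), 50)
  expect_true(all(all_ep$episode == (all_ep$applied_load >
                                       all_ep$threshold_load)))
})

test_that("linear decline under constant load has a sharp chronicity onset", {
  s0 <- max_strength(pool100)
  rate <- 1 / 128  # dyadic rate keeps the crossover time away from integers
  phi <- 0.5
  L <- 0.3 * s0
  # threshold(t) = phi * s0 * (1 - rate t) < L  <=>  t > (1 - L/(phi s0))/rate
  t_star <- (1 - L / (phi * s0)) / rate
  traj <- simulate_chronicity(pool100, decline_rate = rate,
                              critical_ratio = 1, n_steps = 80,
                              decay = "linear", threshold_fraction = phi,
                              load_series = rep(L, 80), seed = 6)
  expect_identical(traj$episode, traj$time > t_star)
  expect_equal(glance(traj)$chronic_from, floor(t_star) + 1)
})

test_that("episodes become more frequent as the muscle weakens", {
  diffs <- vapply(1:10, function(seed) {
    traj <- simulate_chronicity(pool100, decline_rate = 0.008,
                                critical_ratio = 1, n_steps = 200,
                                threshold_fraction = 0.5,
                                load_mean_fraction = 0.3, load_cv = 0.4,
                                seed = seed)
    g <- glance(traj)
    g$freq_last_quartile - g$freq_first_quartile
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # strength declines monotonically, and the threshold with it
  traj <- simulate_chronicity(pool100, decline_rate = 0.008,
                              critical_ratio = 1, n_steps = 200,
                              threshold_fraction = 0.5, seed = 1)
  expect_true(all(diff(traj$strength) < 0))
  expect_true(all(diff(traj$threshold_load) < 0))
  expect_s3_class(autoplot(traj), "ggplot")
})

test_that("chronicity trajectories validate inputs and serialize", {
  expect_error(simulate_chronicity(pool100, -0.1, 1), "non-negative")
  expect_error(simulate_chronicity(pool100, 0.1, 1, n_steps = 30,
                                   decay = "linear",
                                   threshold_fraction = 0.5),
               "zero strength")
  traj <- simulate_chronicity(pool100, 0.005, 1, n_steps = 20,
                              threshold_fraction = 0.5, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_chronicity(traj, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 20)
  expect_equal(back$episode, traj$episode)
})
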