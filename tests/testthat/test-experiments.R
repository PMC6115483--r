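pool40 <- mu_pool(40, seed = 1)

test_that("load sweep boundaries, validation, and monotone trend", {
  sw1 <- sweep_load(pool40, 1.0, n_replicates = 3, n_shifts = 100,
                    base_seed = 1)
  expect_equal(sw1$mean_ratio, 0)
  expect_equal(sw1$sd_ratio, 0)

  expect_error(sweep_load(pool40, c(0.5, 1.2)), "load_fractions")
  expect_error(sweep_load(pool40, 0), "load_fractions")

  sw <- sweep_load(pool40, c(0.2, 0.5, 0.8), n_replicates = 5,
                   n_shifts = 300, base_seed = 2)
  expect_true(all(diff(sw$mean_ratio) < 0))
  expect_true(all(sw$feasible))
  expect_equal(glance(sw)$trend, -1)
})

test_that("strength sweep pins zero at the matching multiplier and flags infeasible points", {
  sw <- sweep_strength(pool40, c(0.1, 0.2, 0.5, 1), fixed_load_fraction = 0.2,
                       n_replicates = 4, n_shifts = 200, base_seed = 3)
  # multiplier below the load fraction cannot carry the load
  expect_false(sw$feasible[sw$value == 0.1])
  expect_true(is.na(sw$mean_ratio[sw$value == 0.1]))
  # muscle strength equal to the load: constant full recruitment
  expect_equal(sw$mean_ratio[sw$value == 0.2], 0)
  expect_equal(sw$sd_ratio[sw$value == 0.2], 0)
  # the stronger the muscle, the longer the rest
  ok <- sw$feasible
  expect_true(all(diff(sw$mean_ratio[ok]) > 0))
  expect_equal(glance(sw)$n_feasible, 3L)
})

test_that("a strength multiplier of 1 reproduces the load-sweep point", {
  # identical pool, load, and replicate seeds on both routes
  a <- sweep_load(pool40, 0.2, n_replicates = 6, n_shifts = 250,
                  base_seed = 7)
  b <- sweep_strength(pool40, 1, fixed_load_fraction = 0.2,
                      n_replicates = 6, n_shifts = 250, base_seed = 7)
  expect_identical(a$mean_ratio, b$mean_ratio)
  expect_identical(a$sd_ratio, b$sd_ratio)
})

test_that("sweeps are reproducible and serializable", {
  run <- function() sweep_load(pool40, c(0.3, 0.6), n_replicates = 4,
                               n_shifts = 150, base_seed = 5)
  expect_equal(run(), run())
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sweep(run(), p1)
  write_sweep(run(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("between-replicate spread shrinks with longer runs", {
  short <- sweep_load(pool40, 0.5, n_replicates = 20, n_shifts = 100,
                      base_seed = 11)
  long <- sweep_load(pool40, 0.5, n_replicates = 20, n_shifts = 2000,
                     base_seed = 11)
  expect_lt(long$sd_ratio, short$sd_ratio)
})

test_that("zero bias makes the two comparison arms identical", {
  cmp <- compare_bias(pool40, "load", grid = c(0.3, 0.6), bias_strength = 0,
                      n_replicates = 3, n_shifts = 150, base_seed = 4)
  u <- cmp[cmp$policy == "uniform", c("value", "mean_ratio", "sd_ratio")]
  b <- cmp[cmp$policy == "small_biased", c("value", "mean_ratio", "sd_ratio")]
  expect_equal(as.data.frame(u), as.data.frame(b), ignore_attr = TRUE)
  g <- glance(cmp)
  expect_true(g$same_direction)
  expect_equal(g$rank_correlation, 1)
})

test_that("both policies give the same qualitative trends", {
  cl <- compare_bias(pool40, "load", grid = c(0.2, 0.4, 0.6, 0.8),
                     n_replicates = 5, n_shifts = 300, base_seed = 6)
  gl <- glance(cl)
  expect_equal(gl$trend_uniform, -1)
  expect_equal(gl$trend_small_biased, -1)
  expect_gt(gl$rank_correlation, 0.9)

  cs <- compare_bias(pool40, "strength", grid = c(0.4, 0.8, 1.2, 1.6),
                     fixed_load_fraction = 0.2,
                     n_replicates = 5, n_shifts = 300, base_seed = 6)
  gs <- glance(cs)
  expect_equal(gs$trend_uniform, 1)
  expect_equal(gs$trend_small_biased, 1)
  expect_gt(gs$rank_correlation, 0.9)
})

test_that("sweep plots build without error", {
  sw <- sweep_load(pool40, c(0.3, 0.7), n_replicates = 3, n_shifts = 100)
  expect_s3_class(autoplot(sw), "ggplot")
  cmp <- compare_bias(pool40, "load", grid = c(0.3, 0.7), n_replicates = 2,
                      n_shifts = 100)
  expect_s3_class(autoplot(cmp), "ggplot")
  rot <- simulate_rotation(pool40, 0.5 * max_strength(pool40),
                           n_shifts = 100, seed = 1)
  expect_s3_class(autoplot(rot), "ggplot")
})
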