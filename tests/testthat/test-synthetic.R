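test_that("OU generator matches the stationary closed forms", {
  # noise-free degenerate case
  expect_equal(as.numeric(sim_ou_residual(-2, 0, n_steps = 50, seed = 1)),
               rep(0, 50))

  # pooled variance over an ensemble vs -sigma^2/(2*lambda) = 0.0025
  xs <- unlist(lapply(1:12, function(s)
    as.numeric(sim_ou_residual(-2, 0.1, 1 / 24, 10000, seed = s))))
  expect_gt(length(xs), 1e5)
  expect_lt(abs(var(xs) - 0.0025) / 0.0025, 0.05)

  # sample AC1 vs exp(lambda*dt) = exp(-2/24)
  x <- sim_ou_residual(-2, 0.1, 1 / 24, 10000, seed = 42)
  expect_lt(abs(estimate_ac1(as.numeric(x)) - exp(-2 / 24)), 0.02)
})

test_that("OU generator is reproducible and validates its parameters", {
  a <- sim_ou_residual(-1, 0.2, 1 / 24, 100, seed = 7)
  b <- sim_ou_residual(-1, 0.2, 1 / 24, 100, seed = 7)
  c <- sim_ou_residual(-1, 0.2, 1 / 24, 100, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))

  expect_error(sim_ou_residual(0.5, 0.1, n_steps = 10), "negative")
  expect_error(sim_ou_residual(-1, 0.1, dt = 0, n_steps = 10), "dt")
  expect_error(sim_ou_residual(-1, 0.1, n_steps = 1), "n_steps")
})

test_that("vegetation composer reproduces its deterministic skeleton", {
  n <- 240
  v <- sim_vegetation_series(-2, 0, 1 / 24, n, seasonal_amplitude = 0.3,
                             trend_slope = 0.05)
  tt <- (0:(n - 1)) / 24
  expect_equal(v$values, 0.3 * sin(2 * pi * tt) + 0.05 * tt)

  # an injected drop is the global minimum of the perturbation-only signal
  pt <- data.frame(time_index = 100, amplitude = -0.5, recovery_rate = -2)
  v2 <- sim_vegetation_series(-2, 0.001, 1 / 24, n, seasonal_amplitude = 0,
                              trend_slope = 0, perturbations = pt, seed = 3)
  expect_lte(abs(which.min(v2$values) - 100), 1)

  # noise-free recovery is exactly log-linear with slope r_true
  v3 <- sim_vegetation_series(-2, 0, 1 / 24, n, seasonal_amplitude = 0,
                              trend_slope = 0, perturbations = pt)
  idx <- 100:180
  sl <- coef(lm(log(abs(v3$values[idx])) ~ tt[idx]))[[2]]
  expect_equal(sl, -2, tolerance = 1e-10)

  bad <- data.frame(time_index = 500, amplitude = -0.5, recovery_rate = -2)
  expect_error(sim_vegetation_series(-2, 0, 1 / 24, n, perturbations = bad),
               "out of range")
  pos <- data.frame(time_index = 10, amplitude = 0.5, recovery_rate = -2)
  expect_error(sim_vegetation_series(-2, 0, 1 / 24, n, perturbations = pos),
               "negative")
})

test_that("precipitation generator hits its moment targets", {
  # fully deterministic limit: every month = map/12
  p <- sim_precip_monthly(1200, rep(1 / 12, 12), 0, n_years = 3)
  expect_equal(as.numeric(p), rep(100, 36))

  # single-month concentration drives SI to its maximum downstream
  w1 <- c(1, rep(0, 11))
  p1 <- sim_precip_monthly(600, w1, 0, n_years = 4)
  expect_equal(as.numeric(walsh_lawler_si(p1)), 11 / 6)

  # interannual_cv is recovered by the downstream variability metric
  p2 <- sim_precip_monthly(800, rep(1 / 12, 12), interannual_cv = 0.2,
                           n_years = 1000, seed = 5)
  expect_lt(abs(as.numeric(interannual_variability(p2)) - 0.2), 0.02)

  expect_error(sim_precip_monthly(800, rep(0.1, 12), 0, n_years = 2), "sum to 1")
  expect_true(all(sim_precip_monthly(50, w1, 0.8, n_years = 50, seed = 1) >= 0))
})

test_that("precipitation scaling changes sums but not the shape metrics", {
  w <- month_weights <- c(0.2, 0.15, 0.1, 0.05, 0.05, 0.05,
                          0.05, 0.05, 0.05, 0.05, 0.1, 0.1)
  p1 <- sim_precip_monthly(700, w, 0.3, n_years = 20, month_noise_cv = 0.1,
                           seed = 9)
  p3 <- 3 * p1
  expect_equal(sum(p3), 3 * sum(p1))
  expect_equal(as.numeric(walsh_lawler_si(p3)),
               as.numeric(walsh_lawler_si(p1)))
  expect_equal(as.numeric(interannual_variability(p3)),
               as.numeric(interannual_variability(p1)))
})

test_that("landscape generator books pixels and encodes the truth gradient", {
  cfg <- landscape_config(classes = list(
    a = list(n_pixels = 600, aridity_range = c(0.5, 2)),
    b = list(n_pixels = 600, aridity_range = c(1, 4))),
    n_years = 4, n_perturb = 0)
  ls <- sim_landscape(cfg, seed = 2)
  expect_equal(nrow(ls$pixels), 1200)
  expect_equal(unname(table(ls$pixels$landcover)[c("a", "b")]),
               c(600L, 600L), ignore_attr = TRUE)
  expect_true(all(ls$pixels$lambda_true < 0))
  # drier pixels have lambda closer to zero: |lambda| shrinks with aridity
  expect_gt(cor(ls$pixels$aridity, ls$pixels$lambda_true,
                method = "spearman"), 0)

  # empty landscape
  cfg0 <- landscape_config(classes = list(
    a = list(n_pixels = 0, aridity_range = c(0.5, 2))), n_years = 2)
  ls0 <- sim_landscape(cfg0, seed = 1)
  expect_equal(nrow(ls0$pixels), 0)
  expect_equal(nrow(ls0$perturbations), 0)
  expect_error(sim_landscape(landscape_config(classes = list()), seed = 1),
               "at least one")

  # determinism + truth completeness
  ls2 <- sim_landscape(cfg, seed = 2)
  expect_identical(ls$pixels, ls2$pixels)
  expect_identical(ls$veg, ls2$veg)
  expect_equal(nrow(ls$labels), nrow(ls$pixels))
})
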