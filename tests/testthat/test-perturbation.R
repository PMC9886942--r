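test_that("rolling slopes reproduce linear and step references", {
  dt <- 1 / 24
  x <- 3 * (0:99) * dt          # slope 3 per year
  sl <- rolling_slopes(x, window = 18, dt = dt)
  expect_equal(length(sl$slopes), 100 - 18 + 1)
  expect_equal(sl$slopes, rep(3, length(sl$slopes)), tolerance = 1e-10)

  step <- c(rep(0, 50), rep(-1, 50))
  sl2 <- rolling_slopes(step, window = 18, dt = dt)
  # steepest slope where the window straddles the step
  expect_lte(abs(sl2$center[which.min(sl2$slopes)] - 50), 2)

  wn <- withr::with_seed(4, rnorm(1e4))
  sl3 <- rolling_slopes(wn, 18, dt)
  expect_lt(abs(mean(sl3$slopes)), 0.5)
  expect_lt(abs(mean(sl3$slopes > 0) - 0.5), 0.05)  # symmetric

  expect_error(rolling_slopes(rnorm(10), window = 18), "longer")
})

test_that("percentile detection finds injected drops and respects its budget", {
  s <- injected_drop_series(seed = 5)
  sl <- rolling_slopes(s$residual)
  det <- detect_perturbations(sl)
  expect_gte(nrow(det), 1)
  expect_true(any(abs(det$peak_index - 300) <= 18))

  # at most 1% of slope samples can exceed the threshold
  thr_hits <- sum(sl$slopes < -quantile(-sl$slopes[sl$slopes < 0], 0.99))
  expect_lte(thr_hits / length(sl$slopes), 0.01)

  # two well-separated drops give two regions (longer record, so the
  # adaptive threshold leaves room for both)
  sd_stat <- 0.1 / sqrt(4)
  pts <- data.frame(time_index = c(600, 1600), amplitude = -8 * sd_stat,
                    recovery_rate = -2)
  v <- sim_vegetation_series(-2, 0.1, 1 / 24, 2400, seasonal_amplitude = 0,
                             perturbations = pts, seed = 6)
  det2 <- detect_perturbations(rolling_slopes(v$residual + v$perturb))
  for (tr in c(600, 1600))
    expect_true(any(abs(det2$peak_index - tr) <= 18))

  expect_warning(detect_perturbations(rolling_slopes(rep(1, 100))),
                 "degenerate")
})

test_that("validation retains genuine drops and discards jumps", {
  withr::with_seed(9, {
    x <- c(rnorm(100), rnorm(100, -5))   # -5 sigma level shift
    p <- data.frame(region_start = 98, region_end = 102, peak_index = 100,
                    slope_at_peak = -1)
    out <- validate_perturbation(x, p)
    expect_true(out$drop_ok)
    expect_lt(out$ks_p, 0.05)
    expect_true(out$retained)

    up <- validate_perturbation(-x, p)   # upward jump
    expect_false(up$drop_ok)
    expect_false(up$retained)
    expect_identical(up$reason, "no_drop")

    edge <- validate_perturbation(x[1:30],
                                  data.frame(region_start = 3, region_end = 5,
                                             peak_index = 4, slope_at_peak = -1))
    expect_false(edge$retained)
    expect_identical(edge$reason, "insufficient_context")
  })
})

test_that("exponential recovery fit is exact on its generative model", {
  dt <- 1 / 24
  tt <- (0:239) * dt
  x <- c(rep(0, 60), -0.3 * exp(-1.2 * (tt[1:180] - 0)))
  p <- data.frame(region_start = 58, region_end = 62, peak_index = 60,
                  slope_at_peak = -1)
  fit <- fit_recovery(x, p, dt = dt, min_search = 3)
  expect_equal(fit$r, -1.2, tolerance = 1e-7)
  expect_equal(fit$x0, -0.3, tolerance = 1e-7)
  expect_gt(fit$r2, 1 - 1e-10)
  expect_true(fit$accepted)

  # flat-zero window cannot be fit
  flat <- fit_recovery(rep(0, 240), p, dt = dt)
  expect_false(flat$accepted)

  # a second event inside the fit window voids the fit
  overlap <- fit_recovery(x, p, dt = dt, min_search = 3, other_peaks = 120L)
  expect_false(overlap$accepted)
  expect_identical(overlap$reason, "overlaps_other_event")
})

test_that("the full event chain recovers an injected event near truth", {
  hits <- sapply(1:10, function(s) {
    ser <- injected_drop_series(seed = 100 + s)
    ev <- recovery_events(ser$residual)
    acc <- ev[ev$accepted %in% TRUE & abs(ev$peak_index - 300) <= 18, ]
    if (nrow(acc)) acc$r[1] else NA_real_
  })
  expect_gte(sum(!is.na(hits)), 7)
  expect_lt(abs(median(hits, na.rm = TRUE) - (-2)) / 2, 0.35)

  # every accepted fit passed the whole filter chain
  ser <- injected_drop_series(seed = 103)
  ev <- recovery_events(ser$residual)
  acc <- ev[ev$accepted %in% TRUE, ]
  if (nrow(acc)) {
    expect_true(all(acc$retained))
    expect_true(all(acc$drop_ok))
    expect_true(all(acc$ks_p < 0.05))
    expect_true(all(acc$r2 >= 0.5))
  }
})
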