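test_that("binned medians enforce the 50-member and 10-bin rules", {
  withr::with_seed(1, {
    x <- runif(1200)
    y <- x
    edges <- seq(0, 1, length.out = 13)
    b <- bin_medians(x, y, edges)
    expect_equal(sum(b$eligible), 12)
    expect_true(b$reportable)
    expect_true(all(diff(b$median) > 0))
    expect_true(all(b$q25 <= b$median & b$median <= b$q75))
  })

  # a 49-member bin is ineligible
  x2 <- c(rep(0.5, 49), rep(1.5, 50))
  b2 <- bin_medians(x2, x2, c(0, 1, 2))
  expect_identical(b2$eligible, c(FALSE, TRUE))

  # nine eligible bins: flagged non-reportable, not an exception
  x3 <- rep(seq(0.5, 8.5), each = 60)
  b3 <- bin_medians(x3, x3, 0:9)
  expect_equal(sum(b3$eligible), 9)
  expect_false(b3$reportable)
  expect_error(kendall_tau_binned(b3), "not reportable")

  expect_error(bin_medians(1:5, 1:5, c(1, 1, 2)), "strictly increasing")
})

test_that("adding points to one bin leaves other bins' medians alone", {
  withr::with_seed(7, {
    x <- runif(600); y <- rnorm(600)
    edges <- seq(0, 1, length.out = 7)
    b <- bin_medians(x, y, edges, min_count = 10, min_bins = 3)
    xx <- c(x, rep(0.05, 40)); yy <- c(y, rnorm(40, 5))
    b2 <- bin_medians(xx, yy, edges, min_count = 10, min_bins = 3)
    expect_equal(b2$median[-1], b$median[-1])
    expect_equal(b2$count[-1], b$count[-1])
  })
})

test_that("Kendall tau of the median line matches a brute-force oracle", {
  mk <- function(meds) {
    n <- length(meds)
    x <- rep(seq_len(n) - 0.5, each = 50)
    y <- rep(meds, each = 50)
    bin_medians(x, y, 0:n, min_count = 50, min_bins = 10)
  }
  up <- kendall_tau_binned(mk(1:12))
  expect_equal(up$tau, 1)
  expect_lt(up$p, 0.05)
  expect_equal(kendall_tau_binned(mk(12:1))$tau, -1)

  withr::with_seed(5, {
    for (i in 1:5) {
      meds <- sample(10)            # known permutation of 10 values
      kt <- kendall_tau_binned(mk(meds))
      expect_equal(kt$tau, kendall_tau_bruteforce(seq_len(10), meds))
    }
    # with ties in the medians, still the tie-aware pair-count value
    meds <- c(1, 2, 2, 3, 4, 4, 5, 6, 7, 7)
    expect_equal(kendall_tau_binned(mk(meds))$tau,
                 kendall_tau_bruteforce(seq_len(10), meds))
  })
})

test_that("surrogate taus are reproducible and collapse for singleton bins", {
  # degenerate sampling: one point per bin reproduces the median line
  x <- seq(0.5, 11.5); y <- c(3, 1, 4, 1, 5, 9, 2, 6, 8, 7, 10, 11)
  b <- bin_medians(x, y, 0:12, min_count = 1, min_bins = 10)
  st <- surrogate_taus(b, n_iter = 200, seed = 3)
  expect_true(all(st$taus == st$tau_median_line))
  expect_equal(st$sign_fraction, 1)

  withr::with_seed(13, {
    x2 <- runif(1200); y2 <- x2 + rnorm(1200, 0, 0.5)
    b2 <- bin_medians(x2, y2, seq(0, 1, length.out = 13))
    s1 <- surrogate_taus(b2, n_iter = 100, seed = 17)
    s2 <- surrogate_taus(b2, n_iter = 100, seed = 17)
    expect_identical(s1$taus, s2$taus)
    expect_false(identical(surrogate_taus(b2, 100, seed = 18)$taus, s1$taus))
    # sign_fraction is exactly the empirical frequency
    expect_equal(s1$sign_fraction,
                 mean(sign(s1$taus) == sign(s1$tau_median_line)))
    expect_equal(length(s1$taus), 100)
  })
  expect_error(surrogate_taus(b, n_iter = 0), "at least 1")
})

test_that("relate applies the 1000-point rule and the bin-width sweep", {
  withr::with_seed(23, {
    mk_class <- function(name, n) {
      x <- runif(n)
      data.frame(landcover = name, pred = x, met = x + rnorm(n, 0, 0.3))
    }
    tab <- rbind(mk_class("big", 1400), mk_class("small", 999))
    out <- relate(tab, "pred", "met", n_bins = 12, bin_sweep = c(12, 16, 20),
                  seed = 2)
    small <- out[out$landcover == "small", ]
    expect_true(small$omitted)
    expect_identical(small$reason, "too_few_points")
    big <- out[out$landcover == "big", ]
    expect_false(big$omitted)
    expect_gt(big$tau, 0)
    expect_lt(big$p, 0.05)
    # direction is stable across the three bin widths
    sweep <- unlist(big[paste0("tau_sweep_", c(12, 16, 20))])
    expect_true(all(sign(sweep[!is.na(sweep)]) == sign(big$tau)))
    expect_gte(sum(!is.na(sweep)), 2)
    # surrogate smoothing: the median line is at least as monotone
    expect_gte(abs(big$tau), abs(big$surrogate_q50))
  })
})
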