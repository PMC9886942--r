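# Independent oracles used to freeze expected values; these deliberately
# avoid the package's own code paths.

# Tie-aware Kendall tau-b by brute-force enumeration of all pairs.
kendall_tau_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
      else if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# AR(1) realization with prescribed coefficient and innovation sd,
# independent of sim_ou_residual.
ar1_series <- function(phi, innov_sd, n, seed) {
  withr::with_seed(seed, {
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                             method = "recursive"))
  })
}

# One pixel's residual with an injected drop + exponential recovery.
injected_drop_series <- function(lambda = -2, sigma = 0.1, n = 720,
                                 drop_index = 300, sd_mult = 8,
                                 r_true = -2, seed = 1) {
  sd_stat <- sigma / sqrt(-2 * lambda)
  pt <- data.frame(time_index = drop_index, amplitude = -sd_mult * sd_stat,
                   recovery_rate = r_true)
  v <- sim_vegetation_series(lambda, sigma, 1 / 24, n,
                             seasonal_amplitude = 0, trend_slope = 0,
                             perturbations = pt, seed = seed)
  list(residual = v$residual + v$perturb, truth = pt)
}
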