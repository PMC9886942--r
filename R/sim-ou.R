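#' Simulate an Ornstein-Uhlenbeck residual series
#'
#' Generates a stationary realization of the linearized vegetation-anomaly
#' model \eqn{d\bar{x} = \lambda \bar{x}\, dt + \sigma\, dW}, discretized
#' exactly as an AR(1) process: the autoregressive coefficient is
#' \eqn{e^{\lambda \Delta t}} and the innovation variance is
#' \eqn{\sigma^2 (1 - e^{2\lambda\Delta t}) / (-2\lambda)}, so that the
#' stationary variance equals the continuous-time value
#' \eqn{-\sigma^2/(2\lambda)} with no discretization bias. The initial value
#' is drawn from the stationary distribution.
#'
#' @param lambda Restoring rate, 1/year; must be strictly negative for a
#'   stable (stationary) simulation.
#' @param sigma Continuous-time noise amplitude, index units per sqrt(year).
#' @param dt Sampling step in years (default `1/24`, bi-weekly).
#' @param n_steps Number of samples to generate (at least 2).
#' @param seed Optional integer seed; when supplied the realization is
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return Numeric vector of length `n_steps` with attribute `dt`.
#'
#' @details The lag-one autocorrelation of the generated process is
#' \eqn{e^{\lambda\Delta t}} and its variance is \eqn{-\sigma^2/(2\lambda)};
#' both identities are used by the resilience estimators to invert sample
#' statistics back to \eqn{\lambda}.
#'
#' @examples
#' x <- sim_ou_residual(lambda = -2, sigma = 0.1, n_steps = 720, seed = 1)
#' var(x)            # close to 0.1^2 / 4 = 0.0025
#' @export
sim_ou_residual <- function(lambda, sigma, dt = 1 / 24, n_steps, seed = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda >= 0) stop("`lambda` must be strictly negative for a stable simulation")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("`dt` must be a positive scalar")
  if (!is.numeric(n_steps) || n_steps < 2) stop("`n_steps` must be at least 2")
  if (sigma < 0) stop("`sigma` must be nonnegative")
  n_steps <- as.integer(n_steps)

  gen <- function() {
    if (sigma == 0) return(numeric(n_steps))
    phi <- exp(lambda * dt)
    stat_var <- -sigma^2 / (2 * lambda)
    innov_sd <- sqrt(stat_var * (1 - phi^2))
    x0 <- stats::rnorm(1L, 0, sqrt(stat_var))
    eps <- stats::rnorm(n_steps, 0, innov_sd)
    as.numeric(stats::filter(eps, phi, method = "recursive", init = x0))
  }
  x <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(x, "dt") <- dt
  x
}

#' Compose a synthetic vegetation index series with known truth
#'
#' Builds a vegetation series as the sum of a sinusoidal seasonal cycle,
#' a linear trend, a stationary Ornstein-Uhlenbeck residual, and optional
#' abrupt negative perturbations each followed by deterministic exponential
#' relaxation \eqn{x(t) = x_0 e^{rt}}. This is the literal generative model
#' that STL decomposition and recovery-rate fitting are later asked to
#' invert, so every injected quantity serves as ground truth.
#'
#' @param lambda,sigma,dt,n_steps,seed Passed to [sim_ou_residual()].
#' @param seasonal_amplitude Amplitude of the annual sinusoid (index units).
#' @param trend_slope Linear trend, index units per year.
#' @param perturbations `NULL` or a data.frame with columns `time_index`
#'   (1-based sample index), `amplitude` (negative, index units) and
#'   `recovery_rate` (1/year, negative for a recovering system).
#'
#' @return A list with components `values` (the composite series),
#'   `seasonal`, `trend`, `residual` (OU part), `perturb` (injected
#'   drop-and-recovery component), `dt`, and `truth` (the perturbation
#'   table as supplied).
#' @export
sim_vegetation_series <- function(lambda, sigma, dt = 1 / 24, n_steps,
                                  seasonal_amplitude = 0.2, trend_slope = 0,
                                  perturbations = NULL, seed = NULL) {
  resid <- sim_ou_residual(lambda, sigma, dt, n_steps, seed)
  tt <- (seq_len(n_steps) - 1L) * dt
  seasonal <- seasonal_amplitude * sin(2 * pi * tt)
  trend <- trend_slope * tt
  perturb <- numeric(n_steps)
  if (!is.null(perturbations) && nrow(perturbations) > 0L) {
    req <- c("time_index", "amplitude", "recovery_rate")
    if (!all(req %in% names(perturbations)))
      stop("`perturbations` needs columns time_index, amplitude, recovery_rate")
    if (any(perturbations$time_index < 1L | perturbations$time_index > n_steps))
      stop("perturbation time_index out of range")
    if (any(perturbations$amplitude >= 0))
      stop("perturbation amplitudes must be negative (drops)")
    for (i in seq_len(nrow(perturbations))) {
      i0 <- perturbations$time_index[i]
      idx <- i0:n_steps
      perturb[idx] <- perturb[idx] + perturbations$amplitude[i] *
        exp(perturbations$recovery_rate[i] * (tt[idx] - tt[i0]))
    }
  }
  values <- seasonal + trend + as.numeric(resid) + perturb
  list(values = values, seasonal = seasonal, trend = trend,
       residual = as.numeric(resid), perturb = perturb, dt = dt,
       truth = perturbations)
}

#' Simulate monthly precipitation with controlled variability structure
#'
#' Generates a monthly precipitation series whose expected annual sum is
#' `map_mm`, whose annual sums fluctuate multiplicatively with a
#' gamma-distributed year factor of unit mean and standard deviation
#' `interannual_cv` (gamma keeps totals nonnegative without truncation),
#' and whose within-year split follows `month_weights`, optionally jittered
#' by multiplicative gamma noise and renormalized so the annual total is
#' preserved.
#'
#' @param map_mm Mean annual precipitation, mm/yr, positive.
#' @param month_weights 12 nonnegative weights summing to 1.
#' @param interannual_cv Target coefficient of variation of annual sums
#'   (std of annual sums / MAP), nonnegative.
#' @param n_years Number of whole years to generate.
#' @param month_noise_cv Within-month multiplicative noise level (cv of the
#'   gamma jitter applied to each month's weight); 0 disables it.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of length `12 * n_years` (mm per month), with
#'   attribute `start_year = 1`.
#' @export
sim_precip_monthly <- function(map_mm, month_weights = rep(1 / 12, 12),
                               interannual_cv = 0, n_years,
                               month_noise_cv = 0, seed = NULL) {
  if (!is.numeric(map_mm) || map_mm <= 0) stop("`map_mm` must be positive")
  if (length(month_weights) != 12L || any(month_weights < 0))
    stop("`month_weights` must be 12 nonnegative values")
  if (abs(sum(month_weights) - 1) > 1e-8)
    stop("`month_weights` must sum to 1")
  if (interannual_cv < 0) stop("`interannual_cv` must be nonnegative")
  if (n_years < 1) stop("`n_years` must be at least 1")
  n_years <- as.integer(n_years)

  gen <- function() {
    fac <- if (interannual_cv > 0) {
      sh <- 1 / interannual_cv^2
      stats::rgamma(n_years, shape = sh, rate = sh)
    } else rep(1, n_years)
    out <- numeric(12L * n_years)
    for (y in seq_len(n_years)) {
      w <- month_weights
      if (month_noise_cv > 0) {
        sh <- 1 / month_noise_cv^2
        w <- w * stats::rgamma(12L, shape = sh, rate = sh)
        if (sum(w) == 0) w <- month_weights
        w <- w / sum(w)
      }
      out[(y - 1L) * 12L + 1:12] <- map_mm * fac[y] * w
    }
    out
  }
  p <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(p, "start_year") <- 1L
  p
}
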