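#' Default configuration for the synthetic landscape generator
#'
#' Encodes the study conditions the analysis is validated against: a grid of
#' pixels split across natural land-cover classes, each pixel carrying a
#' stationary Ornstein-Uhlenbeck vegetation anomaly with a restoring rate
#' `lambda_true` mapped monotonically from its water covariates. Drier
#' pixels (higher PET/MAP aridity), pixels with larger inter-annual
#' precipitation variability, and pixels with more concentrated seasonal
#' rainfall all receive `lambda_true` closer to zero, i.e. lower resilience,
#' so the qualitative resilience-water relationships are encoded as ground
#' truth and must be recovered by the pipeline.
#'
#' @param classes Named list: per land-cover class, a list with `n_pixels`
#'   and `aridity_range` (PET/MAP, higher = drier).
#' @param n_years Length of each pixel's record in years.
#' @param dt Vegetation sampling step, years (1/24 = bi-weekly).
#' @param sigma OU noise amplitude (index units / sqrt(year)).
#' @param seasonal_amplitude,trend_slope Deterministic signal components of
#'   the vegetation series (index units; index units / year).
#' @param pet_mm Potential evapotranspiration, mm/yr, shared by all pixels;
#'   MAP is derived per pixel as `pet_mm / aridity`.
#' @param cv_range Range of per-pixel inter-annual precipitation coefficient
#'   of variation (std of annual sums / MAP).
#' @param seasonality_range Range of the per-pixel rainfall-concentration
#'   parameter in `[0, 1]`; 0 gives uniform months, 1 a strongly peaked
#'   monsoonal regime (weights follow a von-Mises-shaped kernel).
#' @param lambda_base Restoring rate (1/yr) of the wettest, most stable
#'   pixel; all `lambda_true` stay strictly negative.
#' @param beta_aridity,beta_cv,beta_seasonality Positive increments (1/yr)
#'   added to `lambda_base` as each normalized covariate goes from 0 to 1,
#'   moving `lambda_true` toward zero (less resilient).
#' @param n_perturb Number of abrupt drops injected per pixel.
#' @param perturb_sd_mult Drop amplitude as a multiple of the residual's
#'   stationary standard deviation.
#'
#' @return A list usable as the `config` argument of [sim_landscape()].
#' @export
landscape_config <- function(classes = list(
                               forest    = list(n_pixels = 1500, aridity_range = c(0.4, 1.6)),
                               savanna   = list(n_pixels = 1500, aridity_range = c(0.8, 2.8)),
                               grassland = list(n_pixels = 1500, aridity_range = c(1.2, 4.0))
                             ),
                             n_years = 30, dt = 1 / 24, sigma = 0.1,
                             seasonal_amplitude = 0.2, trend_slope = 0.01,
                             pet_mm = 1400,
                             cv_range = c(0.05, 0.45),
                             seasonality_range = c(0, 1),
                             lambda_base = -6.5,
                             beta_aridity = 3.5, beta_cv = 1.5,
                             beta_seasonality = 0.8,
                             n_perturb = 2, perturb_sd_mult = 8) {
  cfg <- as.list(environment())
  stopifnot(beta_aridity >= 0, beta_cv >= 0, beta_seasonality >= 0)
  if (lambda_base + beta_aridity + beta_cv + beta_seasonality >= 0)
    stop("lambda mapping must keep lambda_true strictly negative")
  cfg
}

month_weights_from_seasonality <- function(s, peak_month = 7, kappa_max = 6) {
  m <- 1:12
  w <- exp(s * kappa_max * cos(2 * pi * (m - peak_month) / 12))
  w / sum(w)
}

# Walsh-Lawler SI of the weight kernel is concave in the concentration
# parameter; invert it on a grid so a uniform draw u in [0,1] yields an
# (approximately) uniformly spread SI between 0 and the kernel's maximum.
seasonality_from_si_fraction <- function(u) {
  grid <- seq(0, 1, length.out = 201)
  si <- vapply(grid, function(s) {
    w <- month_weights_from_seasonality(s)
    sum(abs(w - 1 / 12))
  }, numeric(1))
  stats::approx(si / max(si), grid, xout = u, rule = 2)$y
}

# n sorted perturbation times in [lo, hi] (sample indices), pairwise at
# least `sep` apart, by rejection with an evenly spaced fallback
draw_perturbation_times <- function(n, lo, hi, sep) {
  if (n == 1L) return(sample(lo:hi, 1L))
  for (try in 1:50) {
    t <- sort(sample(lo:hi, n))
    if (all(diff(t) >= sep)) return(t)
  }
  as.integer(round(seq(lo, hi, length.out = n)))
}

#' Generate a synthetic landscape with ground truth
#'
#' Draws per-pixel covariates (aridity, inter-annual precipitation cv,
#' rainfall seasonality) uniformly over the configured class ranges, maps
#' them to a true restoring rate, and simulates each pixel's vegetation
#' series (seasonal cycle + trend + OU residual + injected abrupt drops
#' recovering at rate `lambda_true`) and monthly precipitation series.
#' Deterministic under a fixed seed.
#'
#' @param config Output of [landscape_config()].
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_landscape` with components
#'   \describe{
#'     \item{pixels}{data.frame of per-pixel parameters and truth
#'       (`lambda_true`, covariates, MAP, PET).}
#'     \item{veg}{matrix, pixels x time, vegetation index series.}
#'     \item{precip}{matrix, pixels x months, monthly precipitation (mm).}
#'     \item{labels}{matrix, pixels x years, land-cover label per year
#'       (constant over time in this generator).}
#'     \item{perturbations}{data.frame of injected drops (pixel,
#'       time_index, amplitude, recovery_rate).}
#'     \item{config, seed}{the resolved generator inputs.}
#'   }
#' @export
sim_landscape <- function(config = landscape_config(), seed = 1) {
  if (length(config$classes) == 0L) stop("config must declare at least one land-cover class")
  n_steps <- as.integer(round(config$n_years / config$dt))
  classes <- config$classes
  n_total <- sum(vapply(classes, function(cl) cl$n_pixels, numeric(1)))

  if (n_total == 0L) {
    empty <- data.frame(pixel = integer(), landcover = character(),
                        pet_mm = numeric(), map_mm = numeric(),
                        aridity = numeric(), interannual_cv = numeric(),
                        seasonality = numeric(), lambda_true = numeric(),
                        sigma = numeric())
    return(structure(list(pixels = empty,
                          veg = matrix(numeric(), 0L, n_steps),
                          precip = matrix(numeric(), 0L, 12L * config$n_years),
                          labels = matrix(character(), 0L, config$n_years),
                          perturbations = data.frame(pixel = integer(),
                                                     time_index = integer(),
                                                     amplitude = numeric(),
                                                     recovery_rate = numeric()),
                          config = config, seed = seed),
                     class = "synthetic_landscape"))
  }

  all_arid <- unlist(lapply(classes, function(cl) cl$aridity_range))
  a_min <- min(all_arid); a_max <- max(all_arid)

  withr::with_seed(seed, {
    rows <- list(); veg <- list(); precip <- list(); perts <- list()
    pix <- 0L
    for (cl_name in names(classes)) {
      cl <- classes[[cl_name]]
      for (k in seq_len(cl$n_pixels)) {
        pix <- pix + 1L
        aridity <- stats::runif(1, cl$aridity_range[1], cl$aridity_range[2])
        cv <- stats::runif(1, config$cv_range[1], config$cv_range[2])
        u_s <- stats::runif(1, config$seasonality_range[1],
                            config$seasonality_range[2])
        s <- seasonality_from_si_fraction(u_s)  # u_s is the target SI fraction
        u_a <- (aridity - a_min) / (a_max - a_min)
        u_cv <- (cv - config$cv_range[1]) / diff(config$cv_range)
        lambda_true <- config$lambda_base + config$beta_aridity * u_a +
          config$beta_cv * u_cv + config$beta_seasonality * u_s
        map_mm <- config$pet_mm / aridity

        pt <- NULL
        if (config$n_perturb > 0L) {
          stat_sd <- config$sigma / sqrt(-2 * lambda_true)
          margin <- as.integer(round(6 / config$dt))  # keep fit window inside record
          lo <- min(margin, n_steps - margin)
          idx <- draw_perturbation_times(config$n_perturb, lo,
                                         max(lo + 1L, n_steps - margin),
                                         sep = as.integer(round(6 / config$dt)))
          pt <- data.frame(time_index = idx,
                           amplitude = -config$perturb_sd_mult * stat_sd,
                           recovery_rate = lambda_true)
        }
        vs <- sim_vegetation_series(lambda_true, config$sigma, config$dt, n_steps,
                                    seasonal_amplitude = config$seasonal_amplitude,
                                    trend_slope = config$trend_slope,
                                    perturbations = pt)
        pr <- sim_precip_monthly(map_mm,
                                 month_weights_from_seasonality(s),
                                 interannual_cv = cv, n_years = config$n_years,
                                 month_noise_cv = 0.05)
        rows[[pix]] <- data.frame(pixel = pix, landcover = cl_name,
                                  pet_mm = config$pet_mm, map_mm = map_mm,
                                  aridity = aridity, interannual_cv = cv,
                                  seasonality = s, si_fraction = u_s,
                                  lambda_true = lambda_true,
                                  sigma = config$sigma)
        veg[[pix]] <- vs$values
        precip[[pix]] <- as.numeric(pr)
        if (!is.null(pt)) perts[[pix]] <- cbind(pixel = pix, pt)
      }
    }
    pixels <- do.call(rbind, rows)
    structure(list(
      pixels = pixels,
      veg = do.call(rbind, veg),
      precip = do.call(rbind, precip),
      labels = matrix(rep(pixels$landcover, config$n_years),
                      nrow = nrow(pixels), ncol = config$n_years),
      perturbations = if (length(perts)) do.call(rbind, perts) else
        data.frame(pixel = integer(), time_index = integer(),
                   amplitude = numeric(), recovery_rate = numeric()),
      config = config, seed = seed), class = "synthetic_landscape")
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("Synthetic landscape:", nrow(x$pixels), "pixels,",
      length(unique(x$pixels$landcover)), "land-cover classes,",
      x$config$n_years, "years at dt =", format(x$config$dt), "yr\n")
  invisible(x)
}

#' Write a synthetic landscape to plain-text files
#'
#' Writes long-format CSV tables: the pixel/truth table, the injected
#' perturbation table, the vegetation cube and the precipitation cube
#' (one row per pixel-time sample), plus a JSON sidecar with the resolved
#' generator configuration and seed.
#'
#' @param landscape A `synthetic_landscape`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("pixels.csv", "perturbations.csv",
                            "vegetation.csv", "precipitation.csv",
                            "generator.json"))
  utils::write.csv(landscape$pixels, paths[1], row.names = FALSE)
  utils::write.csv(landscape$perturbations, paths[2], row.names = FALSE)
  nv <- ncol(landscape$veg)
  utils::write.csv(data.frame(
    pixel = rep(landscape$pixels$pixel, each = nv),
    time_index = rep(seq_len(nv), nrow(landscape$veg)),
    value = as.numeric(t(landscape$veg))), paths[3], row.names = FALSE)
  np <- ncol(landscape$precip)
  utils::write.csv(data.frame(
    pixel = rep(landscape$pixels$pixel, each = np),
    month_index = rep(seq_len(np), nrow(landscape$precip)),
    precip_mm = as.numeric(t(landscape$precip))), paths[4], row.names = FALSE)
  cfg <- landscape$config
  cfg$classes <- lapply(cfg$classes, function(cl) cl[c("n_pixels", "aridity_range")])
  jsonlite::write_json(list(config = cfg, seed = landscape$seed),
                       paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
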