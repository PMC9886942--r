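#' Walsh-Lawler seasonality index
#'
#' Quantifies intra-annual rainfall concentration as
#' \eqn{SI = (1/R) \sum_{i=1}^{12} | \bar m_i - R/12 |}, where
#' \eqn{\bar m_i} are the long-term mean monthly totals and \eqn{R} their
#' annual sum (the MAP). SI is 0 for perfectly uniform rainfall and reaches
#' its analytic maximum 11/6 when all rain falls in a single month. The
#' climatological form (deviations of the mean monthly cycle) is the
#' default; `per_year = TRUE` instead computes SI within each year and
#' averages, the other published usage of the index.
#'
#' @param precip Monthly precipitation vector (mm), whole years
#'   (length a multiple of 12, January first).
#' @param per_year Average of per-year indices instead of the
#'   climatological index.
#' @return Scalar SI in `[0, 11/6]`; `NA` (flagged) when MAP is zero.
#' @export
walsh_lawler_si <- function(precip, per_year = FALSE) {
  m <- precip_matrix(precip)
  si_one <- function(mon) {
    R <- sum(mon)
    if (R == 0) return(flagged_na("zero_map"))
    sum(abs(mon - R / 12)) / R
  }
  if (per_year) {
    v <- apply(m, 1L, si_one)
    if (all(is.na(v))) return(flagged_na("zero_map"))
    mean(v, na.rm = TRUE)
  } else {
    si_one(colMeans(m))
  }
}

precip_matrix <- function(precip) {
  if (length(precip) %% 12L != 0L || length(precip) == 0L)
    stop("monthly precipitation must cover whole years")
  if (any(is.na(precip)) || any(precip < 0))
    stop("precipitation must be nonnegative and complete")
  matrix(precip, ncol = 12L, byrow = TRUE)
}

#' Inter-annual precipitation variability
#'
#' Sample standard deviation of calendar-year precipitation sums, by
#' default normalized by the mean annual precipitation. The normalization
#' removes the strong linear dependence of the raw standard deviation on
#' the absolute precipitation amount (precipitation is nonnegative, so
#' wetter places have a wider possible range), making the metric
#' scale-invariant. At least three complete years are required for a
#' meaningful sample standard deviation.
#'
#' @param precip Monthly precipitation vector (mm), whole years.
#' @param normalize Divide by MAP (default `TRUE`).
#' @return Scalar: normalized (dimensionless) or raw (mm) inter-annual
#'   variability; flagged `NA` if MAP is zero under normalization.
#' @export
interannual_variability <- function(precip, normalize = TRUE) {
  m <- precip_matrix(precip)
  if (nrow(m) < 3) stop("need at least 3 complete years")
  annual <- rowSums(m)
  s <- stats::sd(annual)
  if (!normalize) return(s)
  map <- mean(annual)
  if (map == 0) return(flagged_na("zero_map"))
  s / map
}

#' Aridity index (PET / MAP)
#'
#' Ratio of potential evapotranspiration to mean annual precipitation, so
#' that higher values correspond to drier conditions: values above 1 denote
#' water deficit, and values above about 2 roughly demarcate semi-arid
#' environments. Use [aridity_from_wetness()] to convert the inverse
#' (MAP/PET, higher = wetter) convention.
#'
#' @param pet_mm Potential evapotranspiration, mm/yr.
#' @param map_mm Mean annual precipitation, mm/yr, strictly positive.
#' @return Aridity, dimensionless.
#' @export
aridity_index <- function(pet_mm, map_mm) {
  if (any(map_mm <= 0)) stop("`map_mm` must be strictly positive")
  pet_mm / map_mm
}

#' Convert a MAP/PET wetness index to PET/MAP aridity
#' @param wetness MAP/PET (higher = wetter), strictly positive.
#' @return PET/MAP aridity (higher = drier).
#' @export
aridity_from_wetness <- function(wetness) {
  if (any(wetness <= 0)) stop("wetness index must be strictly positive")
  1 / wetness
}

#' MAP percentile-band mask within land-cover classes
#'
#' Keeps only pixels whose mean annual precipitation lies within a closed
#' percentile band of the MAP distribution of their own land-cover class.
#' Restricting each class to a narrow MAP band (default the 40th-60th
#' percentiles) is a robustness check that relationships with normalized
#' variability metrics are not driven by MAP itself.
#'
#' @param map_values Numeric vector of per-pixel MAP.
#' @param labels Land-cover class per pixel.
#' @param band Two percentiles in `[0, 100]`.
#' @return Logical vector: pixel inside its class band.
#' @export
percentile_band_mask <- function(map_values, labels, band = c(40, 60)) {
  stopifnot(length(map_values) == length(labels), length(band) == 2L,
            band[1] <= band[2])
  keep <- logical(length(map_values))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    q <- stats::quantile(map_values[i], band / 100, names = FALSE, na.rm = TRUE)
    keep[i] <- !is.na(map_values[i]) & map_values[i] >= q[1] & map_values[i] <= q[2]
  }
  keep
}

#' All water covariates for one pixel
#'
#' @param precip Monthly precipitation vector (mm), whole years.
#' @param pet_mm Potential evapotranspiration, mm/yr.
#' @return One-row data.frame: `map_mm`, `pet_mm`, `aridity`, `si`,
#'   `interannual_norm`.
#' @export
climate_metrics <- function(precip, pet_mm) {
  m <- precip_matrix(precip)
  map <- mean(rowSums(m))
  data.frame(map_mm = map, pet_mm = pet_mm,
             aridity = if (map > 0) aridity_index(pet_mm, map) else NA_real_,
             si = as.numeric(walsh_lawler_si(precip)),
             interannual_norm = as.numeric(interannual_variability(precip)))
}
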