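#' Despike a vegetation series with a running median/MAD filter
#'
#' Replaces points that deviate from the local running median by more than
#' `k` local median absolute deviations (MADs) with that local median.
#' The candidate point itself is excluded from its own window's median and
#' MAD, so a large spike cannot mask itself by inflating the local scale.
#' This is a generic spike filter for contamination artefacts (e.g. cloud
#' cover in optical indices); all non-flagged points pass through unchanged.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param window Odd window length in samples, at least 3.
#' @param k MAD multiplier above which a point is flagged.
#' @return A list with `values` (cleaned series) and `flagged`
#'   (logical vector marking replaced points).
#' @export
despike <- function(values, window = 7, k = 4) {
  n <- length(values)
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  if (window > n) stop("`window` longer than the series")
  half <- window %/% 2
  med <- numeric(n); madv <- numeric(n)
  for (i in seq_len(n)) {
    idx <- setdiff(max(1L, i - half):min(n, i + half), i)
    w <- values[idx]
    med[i] <- stats::median(w, na.rm = TRUE)
    madv[i] <- stats::mad(w, center = med[i], na.rm = TRUE)
  }
  dev <- abs(values - med)
  flagged <- !is.na(dev) & madv > 0 & dev > k * madv
  out <- values
  out[flagged] <- med[flagged]
  list(values = out, flagged = flagged)
}

#' Resample a series to bi-weekly (24/yr) medians
#'
#' Aggregates a finer-resolution series into half-open bi-weekly bins
#' anchored at the first timestamp, taking the median of non-missing values
#' in each bin; empty bins become `NA`. Bins are 1/24 year wide so that the
#' output carries exactly 24 samples per year.
#'
#' @param values Numeric vector.
#' @param times Numeric timestamps in years, strictly increasing, same
#'   length as `values`.
#' @return A list with `values` (bi-weekly medians), `times` (bin start
#'   times, years) and `dt = 1/24`.
#' @export
resample_biweekly <- function(values, times) {
  if (length(values) != length(times)) stop("values and times differ in length")
  if (is.unsorted(times, strictly = TRUE)) stop("timestamps must be strictly increasing")
  dt <- 1 / 24
  bin <- floor((times - times[1]) / dt)
  n_bins <- max(bin) + 1L
  out <- rep(NA_real_, n_bins)
  agg <- tapply(values, bin, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  })
  out[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  list(values = out, times = times[1] + (seq_len(n_bins) - 1L) * dt, dt = dt)
}

#' Extract the STL residual of a bi-weekly vegetation series
#'
#' Removes seasonality and long-term trend by seasonal-trend decomposition
#' using Loess and returns only the residual, the substrate for all
#' resilience estimation. Defaults follow the standard parameter choice for
#' bi-weekly satellite series: seasonal period 24 samples (1 year), trend
#' smoother 47 (just under 2 years), low-pass 25 (just over 1 year), with
#' robust fitting enabled. Gaps up to `max_gap` samples are filled by
#' linear interpolation before decomposing; series with more than
#' `max_missing_frac` missing are refused, since Loess smoothing needs an
#' essentially complete series.
#'
#' @param values Numeric vector, 24 samples/year, length >= 2 periods.
#' @param period Samples per seasonal cycle (24 = one year at bi-weekly).
#' @param t_window Trend smoother span, samples (odd).
#' @param l_window Low-pass filter span, samples (odd).
#' @param s_window Seasonal smoother; `"periodic"` fits one fixed seasonal
#'   cycle, appropriate when a single annual harmonic dominates.
#' @param robust Use robust (outlier-downweighting) Loess iterations.
#' @param max_gap Longest run of missing samples to interpolate across.
#' @param max_missing_frac Maximum tolerated fraction of missing samples.
#' @return Numeric residual vector (same length as input; samples inside
#'   unfillable gaps are `NA`), with attribute `dt = 1/period`.
#' @export
stl_residual <- function(values, period = 24, t_window = 47, l_window = 25,
                         s_window = "periodic", robust = TRUE,
                         max_gap = 4, max_missing_frac = 0.2) {
  n <- length(values)
  if (n < 2 * period) stop("series shorter than two seasonal periods")
  miss <- is.na(values)
  if (mean(miss) > max_missing_frac)
    stop(sprintf("%.0f%% missing exceeds the %.0f%% limit",
                 100 * mean(miss), 100 * max_missing_frac))
  x <- values
  if (any(miss)) {
    x <- zoo::na.approx(x, maxgap = max_gap, na.rm = FALSE)
    # short edge runs carry the nearest observed value; anything longer
    # (edge or interior) cannot be filled honestly
    lead <- which(!is.na(x))[1] - 1L
    trail <- n - max(which(!is.na(x)))
    if (lead > 0 && lead <= max_gap) x[seq_len(lead)] <- x[lead + 1L]
    if (trail > 0 && trail <= max_gap) x[(n - trail + 1L):n] <- x[n - trail]
    if (anyNA(x)) stop("gaps longer than `max_gap` samples remain after interpolation")
  }
  fit <- stats::stl(stats::ts(x, frequency = period), s.window = s_window,
                    t.window = t_window, l.window = l_window, robust = robust)
  resid <- as.numeric(fit$time.series[, "remainder"])
  resid[miss] <- NA_real_  # gap-filled samples are not data
  attr(resid, "dt") <- 1 / period
  attr(resid, "components") <- list(
    seasonal = as.numeric(fit$time.series[, "seasonal"]),
    trend = as.numeric(fit$time.series[, "trend"]))
  resid
}

#' Land-cover eligibility mask
#'
#' A pixel is eligible when its land-cover class belongs to the configured
#' natural-vegetation set in every year of the masking period and has not
#' changed between years; anthropogenic or non-vegetated pixels and pixels
#' with land-cover transitions are excluded from the analysis.
#'
#' @param labels Character matrix, pixels x years: class label per year.
#' @param natural_classes Character vector of admissible classes.
#' @param known_classes Optional full vocabulary; labels outside it raise
#'   an error (guards against coding mistakes upstream).
#' @return Logical vector, one entry per pixel.
#' @export
landcover_mask <- function(labels,
                           natural_classes = c("forest", "woody_savanna",
                                               "savanna", "shrubland",
                                               "grassland", "wetland"),
                           known_classes = NULL) {
  labels <- as.matrix(labels)
  if (!is.null(known_classes)) {
    bad <- setdiff(unique(as.vector(labels)), known_classes)
    if (length(bad)) stop("unknown land-cover class code(s): ",
                          paste(bad, collapse = ", "))
  }
  apply(labels, 1L, function(r)
    all(r %in% natural_classes) && length(unique(r)) == 1L)
}
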