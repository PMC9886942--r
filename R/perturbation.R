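#' Rolling least-squares slopes of a residual series
#'
#' Ordinary least-squares slope of the residual against time (in years)
#' over a moving window, assigned to the window center. With equally
#' spaced samples this reduces to a fixed linear filter, so the whole
#' slope series is one convolution.
#'
#' @param values Numeric residual vector (no NAs within a window; windows
#'   touching an NA yield NA).
#' @param window Window length in samples (default 18 = 9 months at
#'   bi-weekly sampling).
#' @param dt Sampling step in years.
#' @return List with `slopes` (length `n - window + 1`, index units/year)
#'   and `center` (1-based series index of each window's center).
#' @export
rolling_slopes <- function(values, window = 18, dt = 1 / 24) {
  n <- length(values)
  if (window > n) stop("`window` longer than the series")
  if (window < 2) stop("`window` must be at least 2")
  j <- seq_len(window)
  cj <- j - mean(j)
  w <- cj / sum(cj^2) / dt          # OLS slope weights, per year
  slopes <- as.numeric(stats::filter(values, rev(w), method = "convolution",
                                     sides = 1))
  slopes <- slopes[window:n]        # slope for windows starting at 1..n-window+1
  list(slopes = slopes, center = seq_len(n - window + 1L) + window %/% 2L)
}

#' Detect abrupt negative perturbations from a slope series
#'
#' Thresholds the pixel's own slope distribution: the cutoff is the given
#' percentile of the magnitudes of negative slopes, so at most 1% of
#' drop-slope samples exceed it at the default 99th percentile. Contiguous
#' runs of slopes below minus the cutoff form connected regions, and the
#' sample of largest slope magnitude within each region (earliest on ties)
#' is labeled the disturbance peak.
#'
#' @param sl Output of [rolling_slopes()].
#' @param percentile Percentile (0-100) of negative-slope magnitudes.
#' @return data.frame with one row per detected region: `region_start`,
#'   `region_end` (series indices, inclusive), `peak_index`,
#'   `slope_at_peak`. Zero rows (with a warning) for degenerate input.
#' @export
detect_perturbations <- function(sl, percentile = 99) {
  s <- sl$slopes
  ok <- !is.na(s)
  neg <- -s[ok & s < 0]
  if (length(neg) < 2 || stats::sd(s[ok]) == 0) {
    warning("degenerate slope series: no detections")
    return(data.frame(region_start = integer(), region_end = integer(),
                      peak_index = integer(), slope_at_peak = numeric()))
  }
  thr <- stats::quantile(neg, percentile / 100, names = FALSE)
  above <- !is.na(s) & s < -thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    pk <- i[which.min(s[i])]        # earliest index on exact ties
    data.frame(region_start = sl$center[starts[k]],
               region_end = sl$center[ends[k]],
               peak_index = sl$center[pk],
               slope_at_peak = s[pk])
  })
  if (!length(out))
    return(data.frame(region_start = integer(), region_end = integer(),
                      peak_index = integer(), slope_at_peak = numeric()))
  do.call(rbind, out)
}

#' Validate a candidate perturbation against false positives
#'
#' Requires (i) that the series actually drops: the mean over a window
#' after the transition region is below the mean over a window before it,
#' and (ii) that the pre- and post-transition distributions differ by a
#' two-sample Kolmogorov-Smirnov test at level `alpha`. The windows play
#' different roles, so they are placed asymmetrically: the pre window must
#' represent the undisturbed pre-transition state, and therefore also
#' excludes a buffer of half the slope window before the region (samples
#' inside the selected above-threshold slope windows are biased high by
#' the selection itself, which would inflate false drops on stationary
#' series); the post window starts directly at the region end because the
#' post-transition state includes the recovery transient that the
#' empirical fit targets.
#'
#' @param values Residual vector.
#' @param p One row of the [detect_perturbations()] table.
#' @param pre_win,post_win Window lengths in samples (default 24 = 1 year).
#' @param alpha KS significance level.
#' @param pre_buffer Samples excluded between the pre window and the
#'   region start (default 9 = half the default 18-sample slope window).
#' @param post_buffer Samples excluded after the region end (default 0).
#' @return `p` with added columns `ks_p`, `drop_ok`, `retained`, `reason`.
#' @export
validate_perturbation <- function(values, p, pre_win = 24, post_win = 24,
                                  alpha = 0.05, pre_buffer = 9,
                                  post_buffer = 0) {
  n <- length(values)
  lo <- p$region_start - pre_buffer
  hi <- p$region_end + post_buffer
  pre_idx <- intersect(seq_len(n), (lo - pre_win):(lo - 1L))
  post_idx <- intersect(seq_len(n), (hi + 1L):(hi + post_win))
  pre <- values[pre_idx]
  post <- values[post_idx]
  pre <- pre[!is.na(pre)]; post <- post[!is.na(post)]
  if (length(pre) < pre_win / 2 || length(post) < post_win / 2) {
    p$ks_p <- NA_real_; p$drop_ok <- NA; p$retained <- FALSE
    p$reason <- "insufficient_context"
    return(p)
  }
  ks <- suppressWarnings(stats::ks.test(pre, post))
  p$ks_p <- ks$p.value
  p$drop_ok <- mean(post) < mean(pre)
  p$retained <- isTRUE(p$drop_ok) && ks$p.value < alpha
  p$reason <- if (p$retained) NA_character_
    else if (!p$drop_ok) "no_drop" else "ks_not_significant"
  p
}

#' Fit an exponential recovery to a validated perturbation
#'
#' Locates the post-transition minimum of the residual within a short
#' search window after the disturbance peak, then fits
#' \eqn{x(t) = x_0 e^{rt}} (t in years from the minimum) over the
#' following `fit_years` by nonlinear least squares, seeded by a log-linear
#' regression on sign-consistent points. Negative fitted `r` means the
#' system relaxes back to its previous state at rate `|r|`; positive `r`
#' (an amplifying, non-resilient response) is permitted and reported.
#' The fit is rejected when the window overlaps another detected peak,
#' has under half of its samples, fails to converge, or explains too
#' little variance (`r2 < r2_min`).
#'
#' @param values Residual vector.
#' @param p Validated perturbation row (needs `peak_index`).
#' @param dt Sampling step, years.
#' @param fit_years Length of the fit window, years.
#' @param min_search Samples after the peak searched for the minimum.
#' @param r2_min Acceptance threshold on the coefficient of determination.
#' @param other_peaks Integer vector of peak indices of all other detected
#'   perturbations on this pixel (compound events are rejected).
#' @return One-row data.frame: `min_index`, `x0`, `r`, `r2`, `accepted`,
#'   `reason`.
#' @export
fit_recovery <- function(values, p, dt = 1 / 24, fit_years = 5,
                         min_search = 12, r2_min = 0.5,
                         other_peaks = integer()) {
  n <- length(values)
  out <- data.frame(min_index = NA_integer_, x0 = NA_real_, r = NA_real_,
                    r2 = NA_real_, accepted = FALSE, reason = NA_character_)
  search <- p$peak_index:min(n, p$peak_index + min_search)
  vals_search <- values[search]
  if (all(is.na(vals_search))) { out$reason <- "no_minimum"; return(out) }
  m <- search[which.min(vals_search)]
  out$min_index <- m
  win_len <- as.integer(round(fit_years / dt))
  idx <- m:min(n, m + win_len - 1L)
  if (any(other_peaks > m & other_peaks <= m + win_len - 1L)) {
    out$reason <- "overlaps_other_event"; return(out)
  }
  x <- values[idx]
  keep <- !is.na(x)
  if (sum(keep) < win_len / 2) { out$reason <- "insufficient_window"; return(out) }
  tt <- (idx - m) * dt
  x <- x[keep]; tt <- tt[keep]
  if (stats::var(x) == 0) { out$reason <- "degenerate_window"; return(out) }

  # log-linear seed on points sharing the sign of the minimum value
  s0 <- sign(values[m])
  if (s0 == 0) s0 <- -1
  cons <- which(sign(x) == s0 & x != 0)
  start <- if (length(cons) >= 3) {
    cf <- stats::coef(stats::lm(log(abs(x[cons])) ~ tt[cons]))
    list(x0 = s0 * exp(cf[[1]]), r = cf[[2]])
  } else list(x0 = values[m], r = -1)

  fit <- tryCatch(
    minpack.lm::nlsLM(x ~ x0 * exp(r * tt), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) { out$reason <- "fit_failed"; return(out) }
  cf <- stats::coef(fit)
  pred <- cf[["x0"]] * exp(cf[["r"]] * tt)
  ss_res <- sum((x - pred)^2)
  ss_tot <- sum((x - mean(x))^2)
  out$x0 <- cf[["x0"]]; out$r <- cf[["r"]]
  out$r2 <- 1 - ss_res / ss_tot
  out$accepted <- is.finite(out$r2) && out$r2 >= r2_min
  if (!out$accepted) out$reason <- "low_r2"
  out
}

#' Detect, validate and fit all perturbations on one pixel
#'
#' Runs the three-filter chain on a residual series: percentile-threshold
#' slope detection, drop + Kolmogorov-Smirnov validation, and exponential
#' recovery fitting with an R-squared screen. Every candidate appears in
#' the output with its filter outcome, so the per-stage attrition is
#' auditable.
#'
#' @param values Residual vector.
#' @param dt Sampling step, years.
#' @param slope_window,percentile,pre_win,post_win,alpha,fit_years,min_search,r2_min
#'   Stage parameters; see the individual stage functions.
#' @return data.frame, one row per candidate, combining detection,
#'   validation and fit columns.
#' @export
recovery_events <- function(values, dt = 1 / 24, slope_window = 18,
                            percentile = 99, pre_win = 24, post_win = 24,
                            alpha = 0.05, fit_years = 5, min_search = 12,
                            r2_min = 0.5) {
  sl <- rolling_slopes(values, slope_window, dt)
  cands <- withCallingHandlers(
    detect_perturbations(sl, percentile),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(cands) == 0L) {
    return(cbind(cands,
                 data.frame(ks_p = numeric(), drop_ok = logical(),
                            retained = logical(), reason = character(),
                            min_index = integer(), x0 = numeric(),
                            r = numeric(), r2 = numeric(),
                            accepted = logical())))
  }
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    p <- validate_perturbation(values, cands[i, , drop = FALSE],
                               pre_win, post_win, alpha,
                               pre_buffer = slope_window %/% 2L)
    if (isTRUE(p$retained)) {
      f <- fit_recovery(values, p, dt, fit_years, min_search, r2_min,
                        other_peaks = cands$peak_index[-i])
      if (!is.na(f$reason) && is.na(p$reason)) p$reason <- f$reason
      cbind(p, f[, c("min_index", "x0", "r", "r2", "accepted")])
    } else {
      cbind(p, data.frame(min_index = NA_integer_, x0 = NA_real_,
                          r = NA_real_, r2 = NA_real_, accepted = FALSE))
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
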