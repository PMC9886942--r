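#' Binned medians of a resilience metric along a predictor
#'
#' Half-open fixed binning `[e_i, e_{i+1})` of the predictor; within each
#' bin the median and 25th/75th percentiles of the response are recorded.
#' A bin is eligible only when it holds at least `min_count` members (so
#' the median is well supported), and the relationship as a whole is
#' reportable only when at least `min_bins` bins are eligible.
#'
#' @param x Predictor values.
#' @param y Response (resilience metric) values, same length.
#' @param edges Strictly increasing bin edges.
#' @param min_count Minimum members per eligible bin (default 50).
#' @param min_bins Minimum eligible bins for a reportable relationship
#'   (default 10).
#' @return An object of class `binned_relationship`: list with `edges`,
#'   `centers`, `count`, `median`, `q25`, `q75`, `eligible` (logical),
#'   `reportable` (scalar logical), `assignment` (bin index per point, NA
#'   outside the edges), and the inputs `x`, `y` (kept for surrogate
#'   resampling).
#' @export
bin_medians <- function(x, y, edges, min_count = 50, min_bins = 10) {
  stopifnot(length(x) == length(y))
  if (is.unsorted(edges, strictly = TRUE)) stop("`edges` must be strictly increasing")
  nb <- length(edges) - 1L
  ok <- !is.na(x) & !is.na(y)
  bin <- rep(NA_integer_, length(x))
  bin[ok] <- findInterval(x[ok], edges, rightmost.closed = FALSE,
                          left.open = FALSE)
  bin[!is.na(bin) & (bin < 1L | bin > nb)] <- NA_integer_
  count <- tabulate(bin, nbins = nb)
  med <- q25 <- q75 <- rep(NA_real_, nb)
  for (b in which(count > 0L)) {
    yy <- y[which(bin == b)]
    qs <- stats::quantile(yy, c(0.25, 0.5, 0.75), names = FALSE)
    q25[b] <- qs[1]; med[b] <- qs[2]; q75[b] <- qs[3]
  }
  eligible <- count >= min_count
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 count = count, median = med, q25 = q25, q75 = q75,
                 eligible = eligible,
                 reportable = sum(eligible) >= min_bins,
                 min_bins = min_bins,
                 assignment = bin, x = x, y = y),
            class = "binned_relationship")
}

#' @export
print.binned_relationship <- function(x, ...) {
  cat("Binned relationship:", sum(x$eligible), "eligible /",
      length(x$count), "bins;",
      if (x$reportable) "reportable" else "NOT reportable", "\n")
  invisible(x)
}

#' Kendall-tau of the binned median line
#'
#' Tie-aware Kendall rank correlation (tau-b) between the centers of the
#' eligible bins and their medians, with a two-sided p-value. The median
#' line is the smoothed summary of the raw scatter, so its tau measures
#' the monotonicity of the central tendency of the relationship.
#'
#' @param b A `binned_relationship`.
#' @return List with `tau` and `p`.
#' @export
kendall_tau_binned <- function(b) {
  stopifnot(inherits(b, "binned_relationship"))
  if (sum(b$eligible) < b$min_bins)
    stop("fewer than ", b$min_bins, " eligible bins: relationship not reportable")
  ct <- suppressWarnings(
    stats::cor.test(b$centers[b$eligible], b$median[b$eligible],
                    method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Monte-Carlo surrogate Kendall-tau distribution
#'
#' Repeatedly draws one raw data point uniformly at random from every
#' eligible bin and recomputes Kendall-tau between the bin centers and the
#' drawn responses. The resulting distribution shows how much of the
#' median line's monotonicity survives un-smoothed sampling: because
#' binned medians smooth out within-bin scatter, the tau of the median
#' line will almost always exceed the median of the surrogate taus in
#' magnitude. The fraction of surrogates sharing the sign of the
#' median-line tau is an additional robustness summary.
#'
#' @param b A `binned_relationship` (carries the raw points).
#' @param n_iter Number of surrogate draws (default 1000).
#' @param seed Integer seed; the surrogate vector is reproducible.
#' @return List with `taus` (length `n_iter`), `quartiles` (25/50/75th
#'   percentiles of the surrogate taus), `tau_median_line`, `p_median_line`
#'   and `sign_fraction`.
#' @export
surrogate_taus <- function(b, n_iter = 1000, seed = 1) {
  stopifnot(inherits(b, "binned_relationship"))
  if (n_iter < 1) stop("`n_iter` must be at least 1")
  kt <- kendall_tau_binned(b)
  elig <- which(b$eligible)
  members <- lapply(elig, function(bb) which(!is.na(b$assignment) &
                                               b$assignment == bb))
  centers <- b$centers[elig]
  taus <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      ys <- vapply(members, function(ix)
        b$y[if (length(ix) == 1L) ix else sample(ix, 1L)], numeric(1))
      suppressWarnings(stats::cor(centers, ys, method = "kendall"))
    }, numeric(1))
  })
  list(taus = taus,
       quartiles = stats::quantile(taus, c(0.25, 0.5, 0.75), names = FALSE,
                                   na.rm = TRUE),
       tau_median_line = kt$tau, p_median_line = kt$p,
       sign_fraction = mean(sign(taus) == sign(kt$tau), na.rm = FALSE))
}

default_edges <- function(x, n_bins) {
  r <- stats::quantile(x, c(0.01, 0.99), names = FALSE, na.rm = TRUE)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1L)
}

#' Resilience-predictor relationship per land-cover class
#'
#' For each land-cover class with at least `min_points` pixels, bins the
#' resilience metric along the predictor (fixed-width bins spanning the
#' class's 1st-99th predictor percentiles), computes the Kendall-tau of
#' the binned median line with its p-value, the Monte-Carlo surrogate tau
#' distribution and sign-agreement fraction, and repeats the tau
#' computation for a sweep of bin counts as a bin-size sensitivity check.
#' Classes below the point threshold or without ten eligible bins are
#' reported as omitted with a reason code rather than dropped silently.
#'
#' @param table data.frame with one row per pixel, holding at least the
#'   `landcover`, predictor and metric columns.
#' @param predictor,metric Column names.
#' @param n_bins Number of bins for the headline relationship.
#' @param bin_sweep Bin counts for the sensitivity sweep.
#' @param min_points Minimum pixels per class (default 1000).
#' @param min_count,min_bins Bin eligibility rules (see [bin_medians()]).
#' @param n_iter Surrogate iterations.
#' @param seed Base seed; each class gets a distinct derived seed,
#'   recorded in the output.
#' @return data.frame, one row per land-cover class: `tau`, `p`,
#'   surrogate quartiles, `sign_fraction`, the sweep taus
#'   (`tau_sweep_<k>`), `n_points`, `n_eligible_bins`, `omitted`,
#'   `reason`, `seed`.
#' @export
relate <- function(table, predictor, metric, n_bins = 15,
                   bin_sweep = c(10, 15, 20), min_points = 1000,
                   min_count = 50, min_bins = 10, n_iter = 1000, seed = 1) {
  stopifnot(all(c("landcover", predictor, metric) %in% names(table)))
  classes <- sort(unique(table$landcover))
  rows <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    sub <- table[table$landcover == cl &
                   !is.na(table[[predictor]]) & !is.na(table[[metric]]), ]
    cl_seed <- (seed + 7919L * ci) %% .Machine$integer.max
    base <- data.frame(landcover = cl, predictor = predictor,
                       metric = metric, n_points = nrow(sub),
                       n_eligible_bins = NA_integer_, tau = NA_real_,
                       p = NA_real_, surrogate_q25 = NA_real_,
                       surrogate_q50 = NA_real_, surrogate_q75 = NA_real_,
                       sign_fraction = NA_real_, omitted = TRUE,
                       reason = NA_character_, seed = cl_seed,
                       stringsAsFactors = FALSE)
    for (k in bin_sweep) base[[paste0("tau_sweep_", k)]] <- NA_real_
    if (nrow(sub) < min_points) {
      base$reason <- "too_few_points"
      return(base)
    }
    x <- sub[[predictor]]; y <- sub[[metric]]
    b <- bin_medians(x, y, default_edges(x, n_bins), min_count, min_bins)
    base$n_eligible_bins <- sum(b$eligible)
    if (!b$reportable) {
      base$reason <- "too_few_eligible_bins"
      return(base)
    }
    st <- surrogate_taus(b, n_iter = n_iter, seed = cl_seed)
    base$tau <- st$tau_median_line; base$p <- st$p_median_line
    base$surrogate_q25 <- st$quartiles[1]
    base$surrogate_q50 <- st$quartiles[2]
    base$surrogate_q75 <- st$quartiles[3]
    base$sign_fraction <- st$sign_fraction
    base$omitted <- FALSE
    for (k in bin_sweep) {
      bk <- bin_medians(x, y, default_edges(x, k), min_count, min_bins)
      if (bk$reportable)
        base[[paste0("tau_sweep_", k)]] <- kendall_tau_binned(bk)$tau
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
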