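#' Two-regime lasing-threshold fit
#'
#' Peak intensity versus pump power shows two linear regimes -- spontaneous
#' emission below threshold, stimulated above -- and the threshold is the
#' intersection of the two fitted lines.  Every admissible split with at
#' least 3 points per side is tried; the split minimizing the total
#' residual sum of squares wins.  An exhaustive search replaces the
#' by-eye choice of the two fitting regions, making the estimate
#' reproducible.
#'
#' @param powers_uW Strictly increasing pump powers (>= 6 points).
#' @param intensities Peak intensities (counts), same length.
#' @return Object of class `threshold_fit`: `slope_below`,
#'   `intercept_below`, `slope_above`, `intercept_above`,
#'   `breakpoint_index` (last point of the lower regime),
#'   `threshold_uW`, `residual_sse`, `degenerate`.
#'   When the two slopes agree within `1e-6 * intensity scale / power
#'   scale` the fit is flagged degenerate and the threshold is `NA`.
#'   An intersection outside the data range triggers an extrapolation
#'   warning.
#' @export
#' @examples
#' p <- seq(5, 100, length.out = 20)
#' i <- ifelse(p < 28, 2 * p, 2 * 28 + 40 * (p - 28))
#' fit_two_regime(p, i)$threshold_uW
fit_two_regime <- function(powers_uW, intensities) {
  n <- length(powers_uW)
  if (n < 6L) stop("need at least 6 points")
  if (length(intensities) != n) stop("length mismatch")
  if (is.unsorted(powers_uW, strictly = TRUE))
    stop("powers must be strictly increasing")

  ols <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    a <- my - b * mx
    c(intercept = a, slope = b, sse = sum((y - (a + b * x))^2))
  }
  best <- NULL
  for (k in 3:(n - 3)) {
    lo <- ols(powers_uW[1:k], intensities[1:k])
    hi <- ols(powers_uW[(k + 1):n], intensities[(k + 1):n])
    sse <- lo[["sse"]] + hi[["sse"]]
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, lo = lo, hi = hi, sse = sse)
  }
  dslope <- best$hi[["slope"]] - best$lo[["slope"]]
  scale_tol <- 1e-6 * diff(range(intensities)) /
    diff(range(powers_uW))
  degenerate <- abs(dslope) < max(scale_tol, .Machine$double.eps)
  threshold <- if (degenerate) NA_real_ else
    (best$lo[["intercept"]] - best$hi[["intercept"]]) / dslope
  if (!degenerate &&
      (threshold < min(powers_uW) || threshold > max(powers_uW)))
    warning("extrapolation: fitted threshold lies outside the data range")
  structure(
    list(slope_below = best$lo[["slope"]],
         intercept_below = best$lo[["intercept"]],
         slope_above = best$hi[["slope"]],
         intercept_above = best$hi[["intercept"]],
         breakpoint_index = best$k,
         threshold_uW = threshold,
         residual_sse = best$sse,
         degenerate = degenerate),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<threshold_fit> degenerate: single linear regime\n")
  else
    cat(sprintf(
      "<threshold_fit> threshold=%.3f uW, slopes %.4g -> %.4g, SSE=%.4g\n",
      x$threshold_uW, x$slope_below, x$slope_above, x$residual_sse))
  invisible(x)
}

#' Q-factor enhancement across the lasing threshold
#'
#' Ratio of the median Q factor of modes fitted above threshold to the
#' median below; lasing narrows the lines so the ratio exceeds 1.
#'
#' @param peaks_below,peaks_above data.frames of fitted peaks (from
#'   [fit_peaks()]) or lists of `resonance_peak` objects; non-empty.
#' @return Numeric ratio.
#' @export
q_enhancement <- function(peaks_below, peaks_above) {
  getq <- function(p) {
    if (is.data.frame(p)) p$q_factor
    else vapply(p, function(z) z$q_factor, numeric(1))
  }
  qb <- getq(peaks_below)
  qa <- getq(peaks_above)
  if (length(qb) == 0L || length(qa) == 0L) stop("empty peak list")
  stats::median(qa) / stats::median(qb)
}
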