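#' Detect candidate resonance peaks
#'
#' Local maxima whose topographic prominence exceeds a fraction of the
#' spectrum maximum, thinned so that retained peaks are at least
#' `min_separation_nm` apart (stronger peaks win).  Each peak is returned
#' with a fitting window extending towards its flanking valleys, capped at
#' the midpoint to the neighbouring retained peak.
#'
#' @param spectrum A [wgm_spectrum()] object.
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   intensity (default 0.05).
#' @param min_separation_nm Minimum spacing between retained peaks in nm
#'   (default 0.1, below the smallest physically expected mode spacing for
#'   20 um spheres).
#' @return data.frame with one row per candidate, in wavelength order:
#'   `index`, `wavelength_nm`, `intensity`, `prominence`,
#'   `window_lo_nm`, `window_hi_nm`.  May have zero rows.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05,
                         min_separation_nm = 0.1) {
  stopifnot(inherits(spectrum, "wgm_spectrum"))
  x <- spectrum$wavelength_nm
  y <- spectrum$intensity
  n <- length(y)
  empty <- data.frame(index = integer(0), wavelength_nm = numeric(0),
                      intensity = numeric(0), prominence = numeric(0),
                      window_lo_nm = numeric(0), window_hi_nm = numeric(0))
  if (max(y) == min(y)) return(empty)

  # strict local maxima (plateaus take their first sample)
  dy <- diff(y)
  sgn <- sign(dy)
  # carry the last nonzero slope sign across plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  cand <- which(diff(sgn) < 0) + 1L
  if (length(cand) == 0L) return(empty)

  # topographic prominence: lowest point on the path to higher terrain
  prom <- vapply(cand, function(i) {
    left <- if (i > 1) y[1:(i - 1)] else numeric(0)
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    base_side <- function(side) {
      # side is ordered moving away from the peak
      higher <- which(side >= y[i])
      if (length(higher) == 0L) min(c(side, y[i]))
      else if (higher[1] == 1L) y[i]
      else min(side[seq_len(higher[1] - 1)])
    }
    lmin <- base_side(rev(left))
    rmin <- base_side(right)
    y[i] - max(lmin, rmin)
  }, numeric(1))

  thresh <- min_prominence * max(y)
  keep <- cand[prom >= thresh]
  promk <- prom[prom >= thresh]
  if (length(keep) == 0L) return(empty)

  # enforce minimum separation, strongest first
  o <- order(y[keep], decreasing = TRUE)
  sel <- logical(length(keep))
  for (j in o) {
    if (!any(sel & abs(x[keep] - x[keep[j]]) < min_separation_nm))
      sel[j] <- TRUE
  }
  keep2 <- keep[sel]
  prom2 <- promk[sel]
  o2 <- order(x[keep2])
  keep2 <- keep2[o2]
  prom2 <- prom2[o2]

  # fitting windows: walk out to where the signal falls to the window
  # floor (5 % of the prominence above the base), extend 50 % for baseline
  # leverage, cap at neighbour midpoints; tolerant of point noise because
  # the walk only tests the floor level, not monotonicity
  m <- length(keep2)
  lo <- hi <- numeric(m)
  for (j in seq_len(m)) {
    i <- keep2[j]
    floor_lvl <- y[i] - 0.95 * prom2[j]
    il <- i
    while (il > 1 && y[il - 1] > floor_lvl) il <- il - 1
    ir <- i
    while (ir < n && y[ir + 1] > floor_lvl) ir <- ir + 1
    il <- max(1L, il - ceiling((i - il) / 2))
    ir <- min(n, ir + ceiling((ir - i) / 2))
    lo[j] <- x[il]
    hi[j] <- x[ir]
    if (j > 1) lo[j] <- max(lo[j], (x[keep2[j - 1]] + x[i]) / 2)
    if (j < m) hi[j] <- min(hi[j], (x[i] + x[keep2[j + 1]]) / 2)
  }
  data.frame(index = keep2, wavelength_nm = x[keep2], intensity = y[keep2],
             prominence = prom2, window_lo_nm = lo, window_hi_nm = hi)
}

#' Fit a single resonance peak with a Gaussian
#'
#' Nonlinear least squares of a Gaussian plus local constant baseline,
#' \eqn{I(\lambda) = b + A \exp(-(\lambda - c)^2 / 2 s^2)}, inside the given
#' window.  The local-constant baseline suffices because the dye envelope
#' varies slowly relative to a linewidth.
#'
#' @param spectrum A [wgm_spectrum()] object.
#' @param window_nm Length-2 wavelength interval containing the peak; must
#'   cover at least 5 samples.
#' @return Object of class `resonance_peak`: `center_nm`, `fwhm_nm`
#'   (\eqn{2\sqrt{2\ln 2}\, s}), `amplitude`, `baseline`, `center_se_nm`,
#'   `q_factor` (= center/fwhm), `residual_norm`, `n_points`.
#' @export
fit_peak <- function(spectrum, window_nm) {
  stopifnot(inherits(spectrum, "wgm_spectrum"), length(window_nm) == 2L)
  sel <- spectrum$wavelength_nm >= window_nm[1] &
    spectrum$wavelength_nm <= window_nm[2]
  x <- spectrum$wavelength_nm[sel]
  y <- spectrum$intensity[sel]
  if (length(x) < 5L) stop("window contains fewer than 5 samples")
  if (max(y) == min(y)) stop("window contains no peak (constant signal)")
  imax <- which.max(y)
  b0 <- min(y)
  a0 <- y[imax] - b0
  half <- b0 + a0 / 2
  l <- imax; while (l > 1 && y[l] > half) l <- l - 1
  r <- imax; while (r < length(y) && y[r] > half) r <- r + 1
  s0 <- max((x[r] - x[l]) / 2.3548, diff(range(x)) / length(x))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A * exp(-(x - c)^2 / (2 * s^2)),
      data = dat,
      start = list(b = b0, A = a0, c = x[imax], s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("peak fit did not converge (residual norm of start ",
           format(sqrt(sum((y - (b0 + a0 *
             exp(-(x - x[imax])^2 / (2 * s0^2))))^2))), "): ",
           conditionMessage(e))
    }
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["c", "Std. Error"],
                 error = function(e) NA_real_)
  fwhm <- 2 * sqrt(2 * log(2)) * abs(cf[["s"]])
  spacing <- stats::median(diff(x))
  if (fwhm < 2 * spacing)
    warning("under-resolved peak: fitted FWHM below 2 sample spacings")
  center <- cf[["c"]]
  if (center < min(spectrum$wavelength_nm) ||
      center > max(spectrum$wavelength_nm))
    warning("fitted center outside the spectrum window")
  structure(
    list(center_nm = center,
         fwhm_nm = fwhm,
         amplitude = cf[["A"]],
         baseline = cf[["b"]],
         center_se_nm = se,
         q_factor = center / fwhm,
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         n_points = length(x)),
    class = "resonance_peak"
  )
}

#' @export
print.resonance_peak <- function(x, ...) {
  cat(sprintf(
    "<resonance_peak> center=%.4f nm, FWHM=%.4g nm, Q=%.4g, A=%.4g\n",
    x$center_nm, x$fwhm_nm, x$q_factor, x$amplitude))
  invisible(x)
}

#' Detect and fit all peaks of a spectrum
#'
#' Convenience wrapper: [detect_peaks()] then [fit_peak()] per window.
#' Windows whose fit fails are dropped with a warning.
#'
#' @inheritParams detect_peaks
#' @return data.frame with one row per fitted peak: `center_nm`, `fwhm_nm`,
#'   `amplitude`, `baseline`, `center_se_nm`, `q_factor`.
#' @export
fit_peaks <- function(spectrum, min_prominence = 0.05,
                      min_separation_nm = 0.1) {
  cand <- detect_peaks(spectrum, min_prominence, min_separation_nm)
  rows <- lapply(seq_len(nrow(cand)), function(j) {
    pk <- tryCatch(
      fit_peak(spectrum, c(cand$window_lo_nm[j], cand$window_hi_nm[j])),
      error = function(e) {
        warning("dropping peak near ", format(cand$wavelength_nm[j]),
                " nm: ", conditionMessage(e))
        NULL
      })
    if (is.null(pk)) return(NULL)
    data.frame(center_nm = pk$center_nm, fwhm_nm = pk$fwhm_nm,
               amplitude = pk$amplitude, baseline = pk$baseline,
               center_se_nm = pk$center_se_nm, q_factor = pk$q_factor)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(center_nm = numeric(0), fwhm_nm = numeric(0),
                      amplitude = numeric(0), baseline = numeric(0),
                      center_se_nm = numeric(0), q_factor = numeric(0))
  out[order(out$center_nm), , drop = FALSE]
}

#' Track one resonance across a time series of spectra
#'
#' Fits the same mode in each spectrum, re-centering the fit window on the
#' previous center, and reports shifts relative to the first spectrum.
#' If `fsr_nm` is supplied, any step larger than half the free spectral
#' range aborts with a mode-hopping error, since the mode identity is then
#' ambiguous.
#'
#' @param spectra Time-ordered list of [wgm_spectrum()] objects (length
#'   >= 2).  Times are taken from `meta$time_s` when present, else 0,1,2,...
#' @param initial_window_nm Length-2 interval containing the peak in the
#'   first spectrum.
#' @param fsr_nm Optional free spectral range used for the ambiguity check.
#' @return Object of class `peak_track`: data.frame with `time_s`,
#'   `center_nm`, `center_se_nm`, `shift_nm`; attribute
#'   `reference_center_nm`.
#' @export
track_peak <- function(spectra, initial_window_nm, fsr_nm = NULL) {
  if (!is.list(spectra) || length(spectra) < 2L)
    stop("need a list of at least 2 spectra")
  width <- diff(initial_window_nm)
  win <- initial_window_nm
  centers <- ses <- times <- numeric(length(spectra))
  for (i in seq_along(spectra)) {
    pk <- fit_peak(spectra[[i]], win)
    centers[i] <- pk$center_nm
    ses[i] <- pk$center_se_nm
    tm <- spectra[[i]]$meta$time_s
    times[i] <- if (!is.null(tm)) tm else i - 1
    if (i > 1 && !is.null(fsr_nm) &&
        abs(centers[i] - centers[i - 1]) > fsr_nm / 2)
      stop("mode hopping: step of ",
           format(abs(centers[i] - centers[i - 1])),
           " nm between spectra ", i - 1, " and ", i,
           " exceeds FSR/2 = ", format(fsr_nm / 2), " nm")
    win <- centers[i] + c(-0.5, 0.5) * width
  }
  out <- data.frame(time_s = times, center_nm = centers,
                    center_se_nm = ses, shift_nm = centers - centers[1])
  attr(out, "reference_center_nm") <- centers[1]
  class(out) <- c("peak_track", class(out))
  out
}

#' Pair successive same-polarization modes
#'
#' The spectrum carries two interleaved mode combs (TE and TM).  Peaks are
#' partitioned by alternating assignment along the wavelength axis; the
#' interleaved partition is accepted only when it reduces the variance of
#' the within-comb spacings by at least a factor of 4 relative to treating
#' all peaks as one comb (otherwise a single comb explains the data and
#' splitting it would double the apparent FSR).  Polarization labels are
#' latent: pairing uses spacing regularity, not amplitude; score ties favour
#' the single-comb reading.
#'
#' @param peaks data.frame of fitted peaks as from [fit_peaks()] (needs
#'   `center_nm`; `amplitude` is used only for tie-breaks), with >= 3 rows.
#' @param expected_fsr_hint_nm Optional expected FSR; when supplied, the
#'   candidate partition whose median spacing is closest to the hint wins.
#' @return data.frame of successive same-comb pairs: `lambda_m_nm` (longer
#'   wavelength), `lambda_m1_nm` (shorter), `spacing_nm`, `comb` (1 or 2).
#' @export
pair_modes_fsr <- function(peaks, expected_fsr_hint_nm = NULL) {
  if (nrow(peaks) < 3L) stop("need at least 3 peaks to pair modes")
  cen <- sort(peaks$center_nm)
  n <- length(cen)

  partitions <- list(
    single = list(cen),
    interleaved = list(cen[seq(1, n, by = 2)], cen[seq(2, n, by = 2)])
  )
  score <- function(p) {
    sp <- unlist(lapply(p, function(v) if (length(v) >= 2) diff(v)))
    if (is.null(sp) || length(sp) < 2) Inf else stats::var(sp) / mean(sp)^2
  }
  s_single <- score(partitions$single)
  s_inter <- score(partitions$interleaved)
  if (!is.null(expected_fsr_hint_nm)) {
    med <- function(p) stats::median(unlist(lapply(p, function(v)
      if (length(v) >= 2) diff(v))))
    pick <- if (abs(med(partitions$interleaved) - expected_fsr_hint_nm) <
                abs(med(partitions$single) - expected_fsr_hint_nm))
      "interleaved" else "single"
  } else {
    pick <- if (is.finite(s_inter) && s_inter < s_single / 4)
      "interleaved" else "single"
  }
  combs <- partitions[[pick]]
  combs <- Filter(function(v) length(v) >= 2, combs)
  if (length(combs) == 0L)
    stop("insufficient modes: fewer than 2 peaks in every comb")
  rows <- lapply(seq_along(combs), function(ci) {
    v <- combs[[ci]]
    data.frame(lambda_m_nm = v[-1], lambda_m1_nm = v[-length(v)],
               spacing_nm = diff(v), comb = ci)
  })
  do.call(rbind, rows)
}

#' Estimate the resonator radius from a fitted mode comb
#'
#' Chains [pair_modes_fsr()], [mode_number()] and [radius_from_fsr()] and
#' reports the median over all same-polarization pairs.
#'
#' @param peaks data.frame of fitted peaks (>= 3 rows, `center_nm` column).
#' @param n_s Sphere refractive index.
#' @param expected_fsr_hint_nm Passed to [pair_modes_fsr()].
#' @return Object of class `radius_estimate`: list with `radius_um`
#'   (median), `pairs` (per-pair table with `m` and `radius_um`).
#' @export
estimate_radius <- function(peaks, n_s, expected_fsr_hint_nm = NULL) {
  pairs <- pair_modes_fsr(peaks, expected_fsr_hint_nm)
  pairs$m <- mode_number(pairs$lambda_m_nm, pairs$lambda_m1_nm)
  pairs$radius_um <- radius_from_fsr(pairs$lambda_m1_nm, pairs$m, n_s)
  structure(list(radius_um = stats::median(pairs$radius_um), pairs = pairs),
            class = "radius_estimate")
}

#' @export
print.radius_estimate <- function(x, ...) {
  cat(sprintf("<radius_estimate> R=%.4f um from %d mode pairs\n",
              x$radius_um, nrow(x$pairs)))
  invisible(x)
}
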