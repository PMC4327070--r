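#' @name mie
#' @title Electromagnetic resonance positions and bulk sensitivity
#' @description
#' Whispering-gallery resonances of a homogeneous dielectric sphere from
#' the real-wavelength characteristic (mode-matching) equation.  With
#' Riccati-Bessel functions \eqn{\psi_l(z) = z j_l(z)} and
#' \eqn{\chi_l(z) = -z y_l(z)}, size parameter \eqn{x = 2\pi R n_m/\lambda}
#' and relative index \eqn{m = n_s/n_m}, resonances are the roots of
#' \deqn{TE:\quad \psi_l(mx)\,\chi_l'(x) - m\,\chi_l(x)\,\psi_l'(mx) = 0}
#' \deqn{TM:\quad m\,\psi_l(mx)\,\chi_l'(x) - \chi_l(x)\,\psi_l'(mx) = 0}
#' i.e. the dominant (real) part of the Mie coefficient denominators.  TE
#' modes here have purely tangential electric field (Mie b_l); TM modes
#' (a_l) carry a radial electric-field component.  Only resonance
#' locations are computed; radiative linewidths are out of scope because
#' the measured Q of dye-doped polystyrene spheres is material- and
#' instrument-limited, orders of magnitude below the radiative limit.
NULL

# first Airy-function zeros (radial orders 1..3)
.airy_zeros <- c(2.33810741, 4.08794944, 5.52055983)

# --- spherical Bessel backends -------------------------------------------
# "bessel": half-integer-order cylindrical functions from base R.
# "recurrence": plain-arithmetic downward (Miller) recurrence for j and
# upward recurrence for y, independent of the base Bessel routines; serves
# as the second implementation in the two-implementation oracle.

# Riccati-Bessel psi_l, psi_l', chi_l, chi_l' at scalar z
.riccati_bessel <- function(l, z) {
  fac <- sqrt(pi * z / 2)
  psi  <- fac * besselJ(z, l + 0.5)
  psim <- fac * besselJ(z, l - 0.5)
  chi  <- -fac * besselY(z, l + 0.5)
  chim <- -fac * besselY(z, l - 0.5)
  list(psi = psi, dpsi = psim - l / z * psi,
       chi = chi, dchi = chim - l / z * chi)
}

.riccati_recurrence <- function(l, z) {
  # spherical j_0..j_{l} by downward recurrence with renormalization
  L <- l + 50L
  jp <- 0
  jc <- 1e-300
  out <- numeric(l + 1L)
  for (k in L:1) {
    jm <- (2 * k + 1) / z * jc - jp
    if (k - 1L <= l) out[k] <- jm
    jp <- jc
    jc <- jm
    if (abs(jc) > 1e250) {
      jc <- jc * 1e-250
      jp <- jp * 1e-250
      out <- out * 1e-250
    }
  }
  scale <- (sin(z) / z) / out[1]
  j_l <- out[l + 1L] * scale
  j_lm1 <- out[l] * scale
  # spherical y by (stable) upward recurrence
  ym <- -cos(z) / z
  yc <- -cos(z) / z^2 - sin(z) / z
  if (l == 0L) {
    y_l <- ym
    y_lm1 <- NA_real_ # unused: l >= 1 in practice
  } else {
    if (l >= 2L) for (k in 1:(l - 1L)) {
      yn <- (2 * k + 1) / z * yc - ym
      ym <- yc
      yc <- yn
    }
    y_l <- yc
    y_lm1 <- ym
  }
  psi <- z * j_l
  psim <- z * j_lm1
  chi <- -z * y_l
  chim <- -z * y_lm1
  list(psi = psi, dpsi = psim - l / z * psi,
       chi = chi, dchi = chim - l / z * chi)
}

#' Characteristic-equation residual
#'
#' Scale-free residual of the resonance condition at a trial wavelength:
#' the two terms of the characteristic function are normalized by the sum
#' of their magnitudes, so a root has residual 0 and the residual is O(1)
#' away from resonance.
#'
#' @param lambda_nm Trial vacuum wavelength, nm.
#' @param l Angular mode number (integer >= 1).
#' @param R_um Sphere radius, um.
#' @param n_s,n_m Sphere and medium refractive indices (n_s > n_m).
#' @param polarization `"TE"` or `"TM"`.
#' @param impl Bessel backend: `"bessel"` (base half-integer-order
#'   routines, default) or `"recurrence"` (independent plain-arithmetic
#'   recurrences, used as the cross-check oracle).
#' @return Normalized residual (signed), vectorised over `lambda_nm`.
#' @export
mie_char_residual <- function(lambda_nm, l, R_um, n_s, n_m,
                              polarization = c("TE", "TM"),
                              impl = c("bessel", "recurrence")) {
  polarization <- match.arg(polarization)
  impl <- match.arg(impl)
  rb <- if (impl == "bessel") .riccati_bessel else .riccati_recurrence
  vapply(lambda_nm, function(lam) {
    x <- 2 * pi * R_um * 1000 * n_m / lam
    mrel <- n_s / n_m
    inner <- rb(l, mrel * x)
    outer <- rb(l, x)
    if (polarization == "TE") {
      t1 <- inner$psi * outer$dchi
      t2 <- mrel * outer$chi * inner$dpsi
    } else {
      t1 <- mrel * inner$psi * outer$dchi
      t2 <- outer$chi * inner$dpsi
    }
    (t1 - t2) / (abs(t1) + abs(t2))
  }, numeric(1))
}

# asymptotic size-parameter estimate (in X = n_s k R) for mode (l, order);
# surface-term convention: P = m for TE, 1/m for TM. Used only to center
# the numerical bracket, which is wide enough to absorb either convention.
.mie_X_estimate <- function(l, order, n_s, n_m, polarization) {
  nu <- l + 0.5
  mrel <- n_s / n_m
  P <- if (polarization == "TE") mrel else 1 / mrel
  nu + 2^(-1 / 3) * .airy_zeros[order] * nu^(1 / 3) -
    P / sqrt(mrel^2 - 1)
}

# refine the root of mode (l, order); returns wavelength in nm or NA
.mie_root_for_l <- function(l, order, R_um, n_s, n_m, polarization,
                            impl = "bessel", tol = 1e-10) {
  C <- 2 * pi * R_um * 1000 * n_s # = X * lambda
  Xc <- .mie_X_estimate(l, order, n_s, n_m, polarization)
  # bracket +-2.2 in X: isolates the target radial order (orders are
  # separated by > 5 in X at these sizes) while covering the asymptotic
  # error of the estimate
  Xs <- seq(Xc - 2.2, Xc + 2.2, length.out = 180)
  lams <- C / rev(Xs)
  f <- mie_char_residual(lams, l, R_um, n_s, n_m, polarization, impl)
  sgn <- which(f[-1] * f[-length(f)] < 0)
  if (!length(sgn)) return(NA_real_)
  roots <- vapply(sgn, function(i) {
    stats::uniroot(function(lam)
      mie_char_residual(lam, l, R_um, n_s, n_m, polarization, impl),
      interval = c(lams[i], lams[i + 1]), tol = tol)$root
  }, numeric(1))
  roots[which.min(abs(roots - C / Xc))]
}

#' Resonance positions of a homogeneous dielectric sphere
#'
#' All modes of the requested polarization and radial order whose
#' wavelength lies inside the window, found by bracketing the
#' characteristic equation around an Airy-zero asymptotic estimate and
#' refining with Brent's method.
#'
#' @param R_um Sphere radius, um.
#' @param n_s,n_m Sphere and medium refractive indices (n_s > n_m).
#' @param window_nm Length-2 wavelength window.
#' @param polarization `"TE"` (default) or `"TM"`.
#' @param order Radial order (1 = fundamental, default; up to 3).
#' @param impl Bessel backend, see [mie_char_residual()].
#' @return Object of class `mie_mode_table`: data.frame with `l`, `order`,
#'   `polarization`, `wavelength_nm`, `size_parameter` (2 pi R / lambda)
#'   and `residual` (re-evaluated at the root), sorted by wavelength.
#'   Empty if no mode falls in the window.
#' @export
#' @examples
#' \donttest{
#' resonance_positions(10, 1.59, 1.33, c(615, 625))
#' }
resonance_positions <- function(R_um, n_s, n_m, window_nm,
                                polarization = c("TE", "TM"), order = 1L,
                                impl = c("bessel", "recurrence")) {
  polarization <- match.arg(polarization)
  impl <- match.arg(impl)
  if (n_s <= n_m) stop("need n_s > n_m")
  if (length(window_nm) != 2L || diff(window_nm) <= 0)
    stop("window must be a non-empty increasing range")
  if (!order %in% 1:3) stop("radial order must be 1, 2 or 3")
  C <- 2 * pi * R_um * 1000 * n_s
  # invert X(nu) ~ nu + a nu^(1/3) - p for the l range covering the window
  a <- 2^(-1 / 3) * .airy_zeros[order]
  nu_for <- function(lam) {
    X <- C / lam
    nu <- X
    for (i in 1:4) nu <- X - a * nu^(1 / 3) +
        (if (polarization == "TE") n_s / n_m else n_m / n_s) /
        sqrt((n_s / n_m)^2 - 1)
    nu
  }
  l_range <- (floor(nu_for(window_nm[2]) - 0.5) - 2L):
    (ceiling(nu_for(window_nm[1]) - 0.5) + 2L)
  l_range <- l_range[l_range >= 1L]
  rows <- lapply(l_range, function(l) {
    lam <- .mie_root_for_l(l, order, R_um, n_s, n_m, polarization, impl)
    if (is.na(lam) || lam < window_nm[1] || lam > window_nm[2]) return(NULL)
    data.frame(l = l, order = order, polarization = polarization,
               wavelength_nm = lam,
               size_parameter = 2 * pi * R_um * 1000 / lam,
               residual = mie_char_residual(lam, l, R_um, n_s, n_m,
                                            polarization, impl))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(l = integer(0), order = integer(0),
                      polarization = character(0),
                      wavelength_nm = numeric(0),
                      size_parameter = numeric(0), residual = numeric(0))
  out <- out[base::order(out$wavelength_nm), , drop = FALSE]
  class(out) <- c("mie_mode_table", class(out))
  out
}

#' Bulk refractive-index sensitivity of one mode
#'
#' Central difference of the resonance wavelength with respect to the
#' medium index, tracking the mode by its fixed (l, order, polarization)
#' identity -- never by nearest wavelength, which can slip one comb tooth
#' across the difference.
#'
#' @param R_um Sphere radius, um.
#' @param n_s,n_m Sphere and medium refractive indices.
#' @param lambda_near_nm Work near this wavelength; the mode of the
#'   requested polarization/order closest to it is selected.
#' @param polarization `"TE"` (default) or `"TM"`.
#' @param dn Index step for the central difference (default 1e-4).
#' @param order Radial order (default 1).
#' @return List with `sensitivity_nm_per_riu`, `l`, `order`,
#'   `polarization`, `wavelength_nm` (at the nominal index),
#'   `wavelength_plus_nm`, `wavelength_minus_nm`.
#' @export
#' @examples
#' \donttest{
#' bulk_sensitivity(10, 1.59, 1.33, 620)$sensitivity_nm_per_riu
#' }
bulk_sensitivity <- function(R_um, n_s, n_m, lambda_near_nm,
                             polarization = c("TE", "TM"), dn = 1e-4,
                             order = 1L) {
  polarization <- match.arg(polarization)
  fsr_geom <- lambda_near_nm^2 / (2 * pi * R_um * 1000 * n_s)
  win <- lambda_near_nm + c(-1.2, 1.2) * fsr_geom
  modes <- resonance_positions(R_um, n_s, n_m, win, polarization, order)
  if (nrow(modes) == 0L)
    stop("no ", polarization, " mode of order ", order, " found near ",
         lambda_near_nm, " nm")
  l0 <- modes$l[which.min(abs(modes$wavelength_nm - lambda_near_nm))]
  lam0 <- modes$wavelength_nm[modes$l == l0]
  lam_p <- .mie_root_for_l(l0, order, R_um, n_s, n_m + dn, polarization)
  lam_m <- .mie_root_for_l(l0, order, R_um, n_s, n_m - dn, polarization)
  if (is.na(lam_p) || is.na(lam_m))
    stop("mode-identity loss: root for l = ", l0,
         " not found at perturbed medium index")
  list(sensitivity_nm_per_riu = (lam_p - lam_m) / (2 * dn),
       l = l0, order = order, polarization = polarization,
       wavelength_nm = lam0, wavelength_plus_nm = lam_p,
       wavelength_minus_nm = lam_m)
}
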