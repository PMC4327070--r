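#' Resonator model
#'
#' Geometry and refractive indices of the sensing microsphere.  The sphere
#' index must exceed the medium index for guided whispering-gallery modes.
#'
#' @param radius_um Sphere radius in micrometres (> 0).
#' @param n_s Sphere refractive index (polystyrene: 1.59).
#' @param n_m Surrounding medium refractive index (PBS/water: 1.33).
#' @param n_L Adsorbed-layer refractive index (1.5 for polyelectrolytes and
#'   most proteins in solution).
#' @return Object of class `wgm_resonator`.
#' @export
#' @examples
#' resonator_model(10, 1.59, 1.33, 1.5)
resonator_model <- function(radius_um = 10, n_s = 1.59, n_m = 1.33,
                            n_L = 1.5) {
  if (!is.numeric(radius_um) || radius_um <= 0) stop("radius_um must be > 0")
  if (n_m < 1) stop("n_m must be >= 1")
  if (n_s <= n_m) stop("guided-mode condition violated: need n_s > n_m")
  if (n_L < 1) stop("n_L must be >= 1")
  structure(list(radius_um = radius_um, n_s = n_s, n_m = n_m, n_L = n_L),
            class = "wgm_resonator")
}

#' @export
print.wgm_resonator <- function(x, ...) {
  cat(sprintf("<wgm_resonator> R=%.3f um, n_s=%.3f, n_m=%.3f, n_L=%.3f\n",
              x$radius_um, x$n_s, x$n_m, x$n_L))
  invisible(x)
}

#' Mode number from two successive same-polarization resonances
#'
#' For two successive first-order modes of the same polarization at
#' `lambda_m` (longer) and `lambda_m1` (shorter), the mode number is
#' \deqn{m = \lambda_{m+1} / (\lambda_m - \lambda_{m+1}) + 1.}
#' The value is returned continuous, exactly as the formula yields it; use
#' `round_m = TRUE` for the nearest integer.
#'
#' @param lambda_m_nm Longer wavelength of the pair, nm.
#' @param lambda_m1_nm Shorter wavelength of the pair, nm.
#' @param round_m Round to the nearest integer? Default `FALSE`.
#' @return Mode number (vectorised).
#' @export
#' @examples
#' mode_number(624, 620) # 156
mode_number <- function(lambda_m_nm, lambda_m1_nm, round_m = FALSE) {
  if (any(lambda_m1_nm <= 0)) stop("wavelengths must be positive")
  if (any(lambda_m_nm <= lambda_m1_nm))
    stop("ordering error: need lambda_m > lambda_m1")
  m <- lambda_m1_nm / (lambda_m_nm - lambda_m1_nm) + 1
  if (round_m) round(m) else m
}

#' Sphere radius from the free spectral range
#'
#' Geometric-optics estimate \eqn{R = \lambda_{m+1} m / (2\pi n_s)}: the
#' round-trip optical path \eqn{2\pi R n_s} equals \eqn{m} wavelengths.
#'
#' @param lambda_m1_nm Shorter wavelength of the mode pair, nm.
#' @param m Mode number (from [mode_number()]).
#' @param n_s Sphere refractive index.
#' @return Radius in micrometres.
#' @export
#' @examples
#' radius_from_fsr(620, 156, 1.59) # ~9.68 um
radius_from_fsr <- function(lambda_m1_nm, m, n_s) {
  if (any(m <= 1)) stop("mode number must exceed 1")
  if (any(n_s <= 1)) stop("n_s must exceed 1")
  lambda_m1_nm * m / (2 * pi * n_s) * 1e-3
}

#' Effective radius increase from a resonance shift
#'
#' First-order resonance condition: \eqn{\Delta\lambda/\lambda = \Delta R/R},
#' so \eqn{\Delta R = R \, \Delta\lambda / \lambda}.
#'
#' @param dlambda_nm Resonance shift, nm.
#' @param lambda_nm Reference (pre-shift) resonance wavelength, nm.
#' @param radius_um Sphere radius, micrometres.
#' @return Effective radius increase in nm (vectorised; sign follows the
#'   shift).
#' @export
#' @examples
#' radius_increase(0.062, 620, 10) # 1 nm
radius_increase <- function(dlambda_nm, lambda_nm, radius_um) {
  if (any(lambda_nm <= 0) || any(radius_um <= 0))
    stop("lambda_nm and radius_um must be positive")
  radius_um * 1000 * dlambda_nm / lambda_nm
}

#' Deposited-layer thickness from a resonance shift
#'
#' The adlayer of index `n_L` acts as an effective radius increase scaled by
#' the index ratio: \eqn{\Delta\lambda/\lambda = n_L e / (n_s R)}, hence
#' \eqn{e = (\Delta\lambda/\lambda) R \, n_s / n_L}.
#'
#' @inheritParams radius_increase
#' @param n_L Layer refractive index.
#' @param n_s Sphere refractive index.
#' @return Layer thickness in nm.
#' @export
#' @examples
#' layer_thickness(0.1, 620, 10, 1.5, 1.59) # ~1.71 nm
layer_thickness <- function(dlambda_nm, lambda_nm, radius_um, n_L, n_s) {
  if (any(n_L < 1)) stop("n_L must be >= 1")
  radius_increase(dlambda_nm, lambda_nm, radius_um) * n_s / n_L
}

#' Sensor detection limit from resolution and sensitivity
#'
#' DL = R/S: the smallest refractive-index change resolvable given the
#' wavelength resolution of the detection system and the bulk sensitivity.
#'
#' @param resolution_nm Wavelength resolution, nm (e.g. 0.004).
#' @param sensitivity_nm_per_riu Bulk sensitivity, nm/RIU (> 0).
#' @return Detection limit in RIU.
#' @export
#' @examples
#' detection_limit(0.004, 25) # 1.6e-4 RIU
detection_limit <- function(resolution_nm, sensitivity_nm_per_riu) {
  if (any(sensitivity_nm_per_riu <= 0))
    stop("sensitivity must be positive")
  resolution_nm / sensitivity_nm_per_riu
}
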