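#' Molecular properties of the analyte
#'
#' Molar mass, mass density and refractive index of the adsorbing molecule;
#' the dielectric function is derived as \eqn{\varepsilon_r = n^2} and the
#' polarizability is computed on construction via [polarizability_cm()].
#' Defaults describe neutravidin with generic protein optical constants
#' (n = 1.5, 1.37 g/cm3).
#'
#' @param M_g_mol Molar mass, g/mol (neutravidin: 55 000).
#' @param rho_g_cm3 Mass density, g/cm3 (most proteins: 1.37).
#' @param n Refractive index of the molecular material (most proteins: 1.5).
#' @param alpha_ex_SI Optional true excess polarizability in SI units
#'   (C m^2/V).  If omitted, the bare Clausius-Mossotti polarizability is
#'   used as a first approximation and `alpha_provenance` records that.
#' @return Object of class `wgm_molecule` with fields `M_g_mol`,
#'   `rho_g_cm3`, `n`, `eps_r`, `alpha_ex_SI`, `alpha_provenance`
#'   (`"clausius_mossotti"` or `"supplied"`).
#' @export
#' @examples
#' neutravidin <- molecule_properties()
#' neutravidin$alpha_ex_SI
molecule_properties <- function(M_g_mol = 55000, rho_g_cm3 = 1.37, n = 1.5,
                                alpha_ex_SI = NULL) {
  if (M_g_mol <= 0 || rho_g_cm3 <= 0) stop("M and rho must be positive")
  if (n < 1) stop("refractive index must be >= 1")
  mol <- structure(
    list(M_g_mol = M_g_mol, rho_g_cm3 = rho_g_cm3, n = n, eps_r = n^2,
         alpha_ex_SI = NA_real_, alpha_provenance = NA_character_),
    class = "wgm_molecule"
  )
  if (is.null(alpha_ex_SI)) {
    mol$alpha_ex_SI <- polarizability_cm(mol)
    mol$alpha_provenance <- "clausius_mossotti"
  } else {
    if (alpha_ex_SI < 0) stop("alpha_ex must be >= 0")
    mol$alpha_ex_SI <- alpha_ex_SI
    mol$alpha_provenance <- "supplied"
  }
  mol
}

#' @export
print.wgm_molecule <- function(x, ...) {
  cat(sprintf(
    "<wgm_molecule> M=%.5g g/mol, rho=%.3g g/cm3, n=%.3g, alpha=%.4g SI (%s)\n",
    x$M_g_mol, x$rho_g_cm3, x$n, x$alpha_ex_SI, x$alpha_provenance))
  invisible(x)
}

#' Clausius-Mossotti molecular polarizability
#'
#' \deqn{\alpha = \frac{\varepsilon_r - 1}{\varepsilon_r + 2}
#'       \frac{3 M \varepsilon_0}{N_A \rho_m}}
#' with all quantities converted to coherent SI before evaluation.  This is
#' the bare polarizability of the molecular material, used as a first
#' approximation to the excess polarizability over the displaced medium.
#'
#' @param molecule A [molecule_properties()] object (its `eps_r`, `M_g_mol`
#'   and `rho_g_cm3` fields are used).
#' @return Polarizability in SI units (C m^2/V).
#' @export
#' @examples
#' polarizability_cm(molecule_properties()) # ~5.2e-37 for a 55 kDa protein
polarizability_cm <- function(molecule) {
  eps_r <- molecule$eps_r
  if (eps_r < 1) stop("eps_r must be >= 1")
  k <- wgm_constants()
  M_kg_mol <- molecule$M_g_mol * 1e-3
  rho_kg_m3 <- molecule$rho_g_cm3 * 1e3
  (eps_r - 1) / (eps_r + 2) * 3 * M_kg_mol * k$eps0 / (k$N_A * rho_kg_m3)
}

#' Projected area per adsorbed molecule from the radius increase
#'
#' \deqn{\sigma_p^{-1} = \frac{n_s}{n_L}
#'       \frac{\alpha_{ex}}{\varepsilon_0 (n_s^2 - n_m^2)}
#'       \frac{1}{\delta R}}
#' where \eqn{\delta R} is the effective radius increase of the resonator
#' (from [radius_increase()], i.e. \eqn{R\,\Delta\lambda/\lambda} without any
#' further index re-scaling -- the \eqn{n_s/n_L} factor appears explicitly
#' here, so applying it twice would double-count the index contrast).
#'
#' @param molecule A [molecule_properties()] object.
#' @param resonator A [resonator_model()] object (supplies n_s, n_m, n_L).
#' @param deltaR_nm Effective radius increase, nm (> 0).
#' @param eq5_variant Placement of the index ratio; `"ns_over_nl"` (default)
#'   multiplies by \eqn{n_s/n_L}, `"nl_over_ns"` by \eqn{n_L/n_s}.  The
#'   default is the only reading consistent with the effective-radius
#'   convention of [layer_thickness()]; the alternative is exposed for
#'   auditability.
#' @return Projected area per molecule, m^2.
#' @export
#' @examples
#' area_per_molecule(molecule_properties(), resonator_model(), 1.0)
area_per_molecule <- function(molecule, resonator, deltaR_nm,
                              eq5_variant = c("ns_over_nl", "nl_over_ns")) {
  eq5_variant <- match.arg(eq5_variant)
  if (any(deltaR_nm <= 0)) stop("deltaR_nm must be positive")
  n_s <- resonator$n_s
  n_m <- resonator$n_m
  n_L <- resonator$n_L
  if (n_s == n_m) stop("singular contrast: n_s equals n_m")
  ratio <- if (eq5_variant == "ns_over_nl") n_s / n_L else n_L / n_s
  eps0 <- wgm_constants()$eps0
  deltaR_m <- deltaR_nm * 1e-9
  ratio * molecule$alpha_ex_SI / (eps0 * (n_s^2 - n_m^2) * deltaR_m)
}

#' Surface mass density from the area per molecule
#'
#' \deqn{d = M / (N_A \, \sigma_p^{-1})} in g/m^2, together with the number
#' density \eqn{1/\sigma_p^{-1}} and pretty-printed ng/cm^2 and pg/mm^2
#' values (1 g/m^2 = 1e5 ng/cm^2 = 1e6 pg/mm^2).
#'
#' @param molecule A [molecule_properties()] object.
#' @param sigma_p_inv_m2 Projected area per molecule, m^2 (> 0).
#' @return Object of class `surface_loading`: list with `sigma_p_inv_m2`,
#'   `number_density_per_m2`, `d_g_m2`, `d_ng_cm2`, `d_pg_mm2`.
#' @export
#' @examples
#' mass_per_area(molecule_properties(), 8.2e-17)
mass_per_area <- function(molecule, sigma_p_inv_m2) {
  if (any(sigma_p_inv_m2 <= 0)) stop("sigma_p_inv must be positive")
  k <- wgm_constants()
  d <- molecule$M_g_mol / (k$N_A * sigma_p_inv_m2)
  structure(
    list(sigma_p_inv_m2 = sigma_p_inv_m2,
         number_density_per_m2 = 1 / sigma_p_inv_m2,
         d_g_m2 = d,
         d_ng_cm2 = d * 1e5,
         d_pg_mm2 = d * 1e6),
    class = "surface_loading"
  )
}

#' @export
print.surface_loading <- function(x, ...) {
  cat(sprintf(
    "<surface_loading> d=%.4g g/m2 (%.4g ng/cm2, %.4g pg/mm2), %.4g molecules/m2\n",
    x$d_g_m2[1], x$d_ng_cm2[1], x$d_pg_mm2[1], x$number_density_per_m2[1]))
  invisible(x)
}

#' Convert a molar concentration to a mass concentration
#'
#' c\[ug/mL\] = c\[nM\] x M\[g/mol\] x 1e-6.
#'
#' @param c_nM Concentration in nanomolar.
#' @param M_g_mol Molar mass in g/mol.
#' @return Concentration in micrograms per millilitre.
#' @export
#' @examples
#' concentration_nM_to_ug_per_mL(4, 55000)    # 0.22
#' concentration_nM_to_ug_per_mL(1600, 55000) # 88
concentration_nM_to_ug_per_mL <- function(c_nM, M_g_mol) {
  if (any(c_nM < 0) || any(M_g_mol < 0)) stop("inputs must be >= 0")
  c_nM * M_g_mol * 1e-6
}

#' Convert a surface number density to pg/mm^2
#'
#' d\[g/m^2\] = sigma x M / N_A, then 1 g/m^2 = 1e6 pg/mm^2.
#'
#' @param sigma_per_m2 Number density, molecules per m^2.
#' @param M_g_mol Molar mass, g/mol.
#' @return Surface mass density in pg/mm^2.
#' @export
#' @examples
#' number_density_to_pg_per_mm2(1.3e15, 55000) # ~119 -> 120 at 2 s.f.
number_density_to_pg_per_mm2 <- function(sigma_per_m2, M_g_mol) {
  if (any(sigma_per_m2 < 0) || any(M_g_mol < 0)) stop("inputs must be >= 0")
  sigma_per_m2 * M_g_mol / wgm_constants()$N_A * 1e6
}

#' Surface mass density per unit resonance shift
#'
#' Collapses the full transduction chain (shift -> effective radius increase
#' -> area per molecule -> mass per area) into its linear coefficient:
#' \eqn{d = C \,\Delta\lambda} with C in (g/m^2)/nm.  Used both to convert
#' measured shift series into densities and, inverted, by the binding-series
#' simulator.  The chain is homogeneous of degree 1 in the shift, so the
#' coefficient is exact, not a linearization.
#'
#' @param molecule A [molecule_properties()] object.
#' @param resonator A [resonator_model()] object.
#' @param lambda_nm Reference resonance wavelength, nm.
#' @param eq5_variant Passed to [area_per_molecule()].
#' @return Coefficient C in (g/m^2) per nm of shift.
#' @export
density_shift_coefficient <- function(molecule, resonator, lambda_nm,
                                      eq5_variant = "ns_over_nl") {
  dR <- radius_increase(1.0, lambda_nm, resonator$radius_um)
  sig <- area_per_molecule(molecule, resonator, dR, eq5_variant)
  mass_per_area(molecule, sig)$d_g_m2
}

#' Resonance shift produced by a surface mass density
#'
#' Exact inverse of the transduction chain: \eqn{\Delta\lambda = d / C}
#' with C from [density_shift_coefficient()].
#'
#' @inheritParams density_shift_coefficient
#' @param d_g_m2 Surface mass density, g/m^2 (vectorised).
#' @return Resonance shift in nm.
#' @export
density_to_shift <- function(d_g_m2, molecule, resonator, lambda_nm,
                             eq5_variant = "ns_over_nl") {
  d_g_m2 / density_shift_coefficient(molecule, resonator, lambda_nm,
                                     eq5_variant)
}
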