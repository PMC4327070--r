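#' Simulation scene for the forward spectrum model
#'
#' Describes everything needed to generate a dye-doped microsphere emission
#' spectrum: the resonator, the dye gain envelope, the below/above-threshold
#' Q factors, the lasing threshold, the noise model and the detector.
#' Defaults emulate a 20 um diameter Nile-red-doped polystyrene sphere:
#' emission peaked near 590 nm, lasing restricted to the modes near 620 nm
#' where polystyrene absorption is low, Q around 3e3 below threshold and
#' 1.5e4 above, threshold near 28 uW.
#'
#' @param resonator A [resonator_model()] (default 10 um polystyrene in
#'   water).
#' @param dye_peak_nm Center of the dye emission envelope (590).
#' @param dye_fwhm_nm FWHM of the (Gaussian) dye envelope (60).
#' @param gain_window_nm Interval of modes that lase above threshold
#'   (`c(615, 625)`); must lie within the envelope support (peak +- 4 sd).
#' @param q_below,q_above Mode Q factors below / above threshold
#'   (3e3, 1.5e4); must satisfy `q_above > q_below > 1`.
#' @param threshold_power_uW Lasing threshold pump power (28).
#' @param noise List: `additive_sd` (counts, default 5) and `shot`
#'   (logical, Poisson shot noise, default FALSE).
#' @param instrument An [instrument_model()].
#' @param te_tm_offset_frac TM comb offset as a fraction of the FSR (0.35).
#' @param te_amplitude,tm_amplitude Relative comb amplitudes (1, 0.6);
#'   amplitudes are phenomenological, not electromagnetic.
#' @param counts_scale Overall intensity scale in counts (1000).
#' @param background_frac Unmodulated fraction of the dye emission (0.2).
#' @param lineshape `"gaussian"` (default, what the analysis fits) or
#'   `"lorentzian"`.
#' @param seed Default RNG seed for generators using this scene (1).
#' @return Object of class `wgm_scene`.
#' @export
simulation_scene <- function(resonator = resonator_model(),
                             dye_peak_nm = 590,
                             dye_fwhm_nm = 60,
                             gain_window_nm = c(615, 625),
                             q_below = 3e3,
                             q_above = 1.5e4,
                             threshold_power_uW = 28,
                             noise = list(additive_sd = 5, shot = FALSE),
                             instrument = instrument_model(),
                             te_tm_offset_frac = 0.35,
                             te_amplitude = 1,
                             tm_amplitude = 0.6,
                             counts_scale = 1000,
                             background_frac = 0.2,
                             lineshape = c("gaussian", "lorentzian"),
                             seed = 1L) {
  lineshape <- match.arg(lineshape)
  if (!(q_above > q_below && q_below > 1))
    stop("need q_above > q_below > 1")
  if (threshold_power_uW <= 0) stop("threshold_power_uW must be > 0")
  dye_sd <- dye_fwhm_nm / (2 * sqrt(2 * log(2)))
  support <- dye_peak_nm + c(-4, 4) * dye_sd
  if (gain_window_nm[1] < support[1] || gain_window_nm[2] > support[2])
    stop("gain window must lie within the dye envelope support (peak +- 4 sd)")
  if (te_tm_offset_frac <= 0 || te_tm_offset_frac >= 1)
    stop("te_tm_offset_frac must be in (0, 1)")
  if (is.null(noise$additive_sd)) noise$additive_sd <- 0
  if (is.null(noise$shot)) noise$shot <- FALSE
  structure(
    list(resonator = resonator, dye_peak_nm = dye_peak_nm,
         dye_fwhm_nm = dye_fwhm_nm, dye_sd_nm = dye_sd,
         gain_window_nm = gain_window_nm, q_below = q_below,
         q_above = q_above, threshold_power_uW = threshold_power_uW,
         noise = noise, instrument = instrument,
         te_tm_offset_frac = te_tm_offset_frac,
         te_amplitude = te_amplitude, tm_amplitude = tm_amplitude,
         counts_scale = counts_scale, background_frac = background_frac,
         lineshape = lineshape, seed = seed),
    class = "wgm_scene"
  )
}

#' @export
print.wgm_scene <- function(x, ...) {
  cat(sprintf(
    "<wgm_scene> R=%.1f um, dye %g nm (FWHM %g), gain %g-%g nm, Q %g/%g, threshold %g uW\n",
    x$resonator$radius_um, x$dye_peak_nm, x$dye_fwhm_nm,
    x$gain_window_nm[1], x$gain_window_nm[2], x$q_below, x$q_above,
    x$threshold_power_uW))
  invisible(x)
}

#' Mode comb of a scene
#'
#' Geometric forward model: same-polarization first-order modes sit at
#' \eqn{\lambda_k = 2\pi R n_s / k} for integer k (so [mode_number()] and
#' [radius_from_fsr()] invert it exactly); the TM comb is offset from the TE
#' comb by a fixed fraction of the local FSR.  A uniform fractional shift
#' models a deposited layer via the effective-radius relation.
#'
#' @param scene A [simulation_scene()].
#' @param shift_frac Fractional resonance shift applied to every mode
#'   (default 0), e.g. `n_L * e / (n_s * R)` for a layer of thickness e.
#' @param pad_nm Margin beyond the instrument window in which modes are
#'   still generated (their tails matter), default 2.
#' @return data.frame: `center_nm`, `polarization` ("TE"/"TM"),
#'   `amplitude_rel`, `k` (TE comb integer it derives from).
#' @export
scene_mode_comb <- function(scene, shift_frac = 0, pad_nm = 2) {
  res <- scene$resonator
  C <- 2 * pi * res$radius_um * 1000 * res$n_s # optical path, nm
  win <- scene$instrument$wavelength_window_nm + c(-pad_nm, pad_nm)
  kmin <- max(2L, floor(C / win[2]) - 1L)
  kmax <- ceiling(C / win[1]) + 1L
  k <- kmin:kmax
  te <- C / k
  fsr <- te - C / (k + 1)
  tm <- te - scene$te_tm_offset_frac * fsr
  comb <- rbind(
    data.frame(center_nm = te, polarization = "TE",
               amplitude_rel = scene$te_amplitude, k = k),
    data.frame(center_nm = tm, polarization = "TM",
               amplitude_rel = scene$tm_amplitude, k = k)
  )
  comb$center_nm <- comb$center_nm * (1 + shift_frac)
  comb <- comb[comb$center_nm >= win[1] & comb$center_nm <= win[2], ]
  comb[order(comb$center_nm), ]
}

# dye envelope, unit peak
.dye_envelope <- function(scene, lambda_nm) {
  exp(-(lambda_nm - scene$dye_peak_nm)^2 / (2 * scene$dye_sd_nm^2))
}

#' Simulate one emission spectrum
#'
#' Forward model: dye envelope times mode comb, sampled on the instrument
#' grid, plus seeded noise.  Modes inside the gain window lase when the
#' pump exceeds the threshold: their linewidth narrows to `q_above` and
#' their amplitude grows with the excess pump; all other modes keep
#' `q_below`.  Spontaneous emission scales linearly with pump power.
#'
#' @param scene A [simulation_scene()].
#' @param pump_uW Pump power in microwatts (>= 0).
#' @param shift_frac Fractional resonance shift (see [scene_mode_comb()]).
#' @param seed RNG seed; defaults to `scene$seed`.  `NULL` leaves the RNG
#'   state alone.
#' @return A [wgm_spectrum()] with `meta$pump_power_uW` set.
#' @export
#' @examples
#' sc <- simulation_scene(noise = list(additive_sd = 0))
#' s <- simulate_spectrum(sc, pump_uW = 10)
simulate_spectrum <- function(scene, pump_uW, shift_frac = 0,
                              seed = scene$seed) {
  stopifnot(inherits(scene, "wgm_scene"))
  if (pump_uW < 0) stop("pump power must be >= 0")
  grid <- instrument_grid(scene$instrument)
  comb <- scene_mode_comb(scene, shift_frac)
  lasing_on <- pump_uW > scene$threshold_power_uW
  intensity <- rep(0, length(grid))
  for (i in seq_len(nrow(comb))) {
    c0 <- comb$center_nm[i]
    lases <- lasing_on && c0 >= scene$gain_window_nm[1] &&
      c0 <= scene$gain_window_nm[2]
    q <- if (lases) scene$q_above else scene$q_below
    fwhm <- c0 / q
    amp <- comb$amplitude_rel[i] * .dye_envelope(scene, c0)
    if (lases)
      amp <- amp * (1 + (scene$q_above / scene$q_below) *
                      (pump_uW - scene$threshold_power_uW) /
                      scene$threshold_power_uW)
    intensity <- intensity + amp * if (scene$lineshape == "gaussian") {
      s <- fwhm / (2 * sqrt(2 * log(2)))
      exp(-(grid - c0)^2 / (2 * s^2))
    } else {
      1 / (1 + ((grid - c0) / (fwhm / 2))^2)
    }
  }
  pump_norm <- pump_uW / scene$threshold_power_uW
  counts <- scene$counts_scale * pump_norm *
    (scene$background_frac * .dye_envelope(scene, grid) + intensity)
  counts <- with_seed(seed, {
    if (isTRUE(scene$noise$shot)) counts <- stats::rpois(length(counts),
                                                         pmax(counts, 0))
    if (scene$noise$additive_sd > 0)
      counts <- counts + stats::rnorm(length(counts),
                                      sd = scene$noise$additive_sd)
    counts
  })
  wgm_spectrum(grid, pmax(counts, 0),
               meta = list(pump_power_uW = pump_uW,
                           label = "simulated"))
}

#' Simulate a pump-power sweep
#'
#' Peak intensity versus pump power with the two-regime laser signature:
#' piecewise linear, continuous at the threshold, lower slope below
#' (spontaneous emission) and higher slope above (stimulated emission),
#' plus seeded relative noise.
#'
#' @param scene A [simulation_scene()] (supplies the threshold).
#' @param powers_uW Strictly positive vector of pump powers (non-empty).
#' @param slope_below,slope_above Counts per uW in the two regimes;
#'   `slope_above >= slope_below >= 0` (equality gives a degenerate single
#'   line, which the threshold fit must flag).
#' @param intercept_below Intensity at zero pump (default 0).
#' @param rel_noise_sd Relative (multiplicative) noise SD (default 0).
#' @param seed RNG seed; defaults to `scene$seed`.
#' @return data.frame with `power_uW`, `intensity`.
#' @export
simulate_power_sweep <- function(scene, powers_uW, slope_below, slope_above,
                                 intercept_below = 0, rel_noise_sd = 0,
                                 seed = scene$seed) {
  if (length(powers_uW) == 0L) stop("empty power list")
  if (!(slope_above >= slope_below && slope_below >= 0))
    stop("need slope_above >= slope_below >= 0")
  p0 <- scene$threshold_power_uW
  i0 <- intercept_below + slope_below * p0
  intensity <- ifelse(powers_uW <= p0,
                      intercept_below + slope_below * powers_uW,
                      i0 + slope_above * (powers_uW - p0))
  intensity <- with_seed(seed, {
    if (rel_noise_sd > 0)
      intensity <- intensity *
        (1 + stats::rnorm(length(intensity), sd = rel_noise_sd))
    intensity
  })
  data.frame(power_uW = powers_uW, intensity = intensity)
}

#' Simulate a layer-by-layer deposition series
#'
#' One spectrum per deposition step (plus the bare-sphere reference as the
#' first element).  After depositing cumulative thickness e, every mode is
#' shifted by \eqn{\Delta\lambda = \lambda \, n_L e / (n_s R)} -- the
#' forward effective-radius model that [layer_thickness()] inverts.
#'
#' @param resonator A [resonator_model()] (overrides the scene's).
#' @param layer_thicknesses_nm Vector of per-layer thicknesses (>= 0), e.g.
#'   `c(0.8, 2.2, 3.2, 3.6, 3.4)` for a typical PAH/PSS sequence where the
#'   sparse first layer makes the first bilayer thinner than the second.
#' @param scene A [simulation_scene()].
#' @param pump_uW Pump power for each acquisition; defaults to twice the
#'   threshold (deposition is monitored on a lasing sphere).
#' @param seed Base RNG seed; spectrum k uses `seed + k`.
#' @return List of [wgm_spectrum()] of length
#'   `length(layer_thicknesses_nm) + 1`, reference first.
#' @export
simulate_deposition_series <- function(resonator, layer_thicknesses_nm,
                                       scene,
                                       pump_uW = 2 * scene$threshold_power_uW,
                                       seed = scene$seed) {
  if (any(layer_thicknesses_nm < 0)) stop("layer thicknesses must be >= 0")
  scene$resonator <- resonator
  e_cum <- c(0, cumsum(layer_thicknesses_nm))
  lapply(seq_along(e_cum), function(k) {
    f <- resonator$n_L * e_cum[k] /
      (resonator$n_s * resonator$radius_um * 1000)
    s <- simulate_spectrum(scene, pump_uW, shift_frac = f,
                           seed = if (is.null(seed)) NULL else seed + k)
    s$meta$time_s <- (k - 1) * 2400 # 30 min soak + 10 min rinse cadence
    s$meta$label <- if (k == 1) "reference" else paste0("layer_", k - 1)
    s
  })
}

#' Kinetic presets per analyte concentration
#'
#' Illustrative single-exponential saturation parameters for neutravidin
#' binding in still (diffusion-limited) solution: saturation within about a
#' minute at 1600 nM, ~5 min at 400 nM, ~15 min at 100 nM, and no
#' saturation within 30 min below that; plateau density decreasing with
#' concentration from ~1.77e-3 g/m2 (177 ng/cm2) at 1600 nM down to
#' ~1.2e-4 g/m2 (120 pg/mm2) at 4 nM, with 0 for the casein-blocked
#' negative control.  These presets encode qualitative trends only and are
#' not measured ground truth.
#'
#' @param concentration_nM One of 1600, 400, 100, 20, 4 or 0 (negative
#'   control).
#' @return List with `d_max_g_m2` and `tau_s`.
#' @export
kinetics_preset <- function(concentration_nM) {
  presets <- list(
    `1600` = list(d_max_g_m2 = 1.77e-3, tau_s = 15),
    `400`  = list(d_max_g_m2 = 0.9e-3,  tau_s = 100),
    `100`  = list(d_max_g_m2 = 0.55e-3, tau_s = 300),
    `20`   = list(d_max_g_m2 = 2.5e-4,  tau_s = 900),
    `4`    = list(d_max_g_m2 = 1.2e-4,  tau_s = 1200),
    `0`    = list(d_max_g_m2 = 0,       tau_s = 1)
  )
  key <- as.character(concentration_nM)
  if (!key %in% names(presets))
    stop("no preset for ", concentration_nM,
         " nM; available: ", paste(names(presets), collapse = ", "))
  presets[[key]]
}

#' Simulate a binding time series
#'
#' Surface density follows single-exponential (Langmuir-like) saturation
#' \eqn{d(t) = d_{max}(1 - e^{-t/\tau})}; the density is converted to a
#' resonance shift through the exact inverse of the transduction chain
#' ([density_to_shift()]) and seeded Gaussian wavelength noise is added to
#' every point.  The returned densities are re-derived from the *noisy*
#' shifts, exactly as the analysis of a measured series would.
#'
#' @param concentration_nM Analyte concentration (recorded; use
#'   [kinetics_preset()] for matching kinetics).
#' @param kinetics List with `d_max_g_m2` and `tau_s`.
#' @param molecule A [molecule_properties()].
#' @param resonator A [resonator_model()].
#' @param noise_sd_nm Wavelength noise SD per point in nm; default 0.004
#'   (the 4 pm detection-system resolution -- an assumption, the noise
#'   floor is not otherwise specified).
#' @param seed RNG seed (default 1).
#' @param times_s Sampling times; default once per minute over 30 min.
#' @param lambda_nm Reference resonance wavelength (620).
#' @return Object of class `binding_series`: data.frame `time_s`,
#'   `shift_nm`, `density_g_m2`; attributes `concentration_nM`,
#'   `true_d_max_g_m2`, `true_tau_s`, `lambda_nm`, `molecule`, `resonator`,
#'   `noise_sd_nm`.
#' @export
simulate_binding_series <- function(concentration_nM, kinetics,
                                    molecule = molecule_properties(),
                                    resonator = resonator_model(),
                                    noise_sd_nm = 0.004, seed = 1L,
                                    times_s = seq(0, 1800, by = 60),
                                    lambda_nm = 620) {
  stopifnot(kinetics$d_max_g_m2 >= 0, kinetics$tau_s > 0,
            noise_sd_nm >= 0)
  if (is.unsorted(times_s, strictly = TRUE))
    stop("times must be strictly increasing")
  d_true <- kinetics$d_max_g_m2 * (1 - exp(-times_s / kinetics$tau_s))
  shift_clean <- density_to_shift(d_true, molecule, resonator, lambda_nm)
  shift <- with_seed(seed, shift_clean +
    if (noise_sd_nm > 0) stats::rnorm(length(times_s), sd = noise_sd_nm)
    else 0)
  coefd <- density_shift_coefficient(molecule, resonator, lambda_nm)
  out <- data.frame(time_s = times_s, shift_nm = shift,
                    density_g_m2 = shift * coefd)
  attr(out, "concentration_nM") <- concentration_nM
  attr(out, "true_d_max_g_m2") <- kinetics$d_max_g_m2
  attr(out, "true_tau_s") <- kinetics$tau_s
  attr(out, "lambda_nm") <- lambda_nm
  attr(out, "molecule") <- molecule
  attr(out, "resonator") <- resonator
  attr(out, "noise_sd_nm") <- noise_sd_nm
  class(out) <- c("binding_series", class(out))
  out
}
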