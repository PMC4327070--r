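# shared fixtures: scenes sized so the mode comb is well resolved

# high-resolution scene: ~7.3 pm sampling, single-polarization option
quiet_scene <- function(additive_sd = 0, tm_amplitude = 0.6,
                        window = c(605, 635), n_pixels = 4096,
                        q_below = 3e3, q_above = 1.5e4) {
  simulation_scene(
    resonator = resonator_model(10, 1.59, 1.33, 1.5),
    noise = list(additive_sd = additive_sd),
    instrument = instrument_model(n_pixels, window),
    tm_amplitude = tm_amplitude,
    q_below = q_below, q_above = q_above
  )
}

# analytic Gaussian-peak spectrum on a uniform grid
gaussian_spectrum <- function(center = 620, fwhm = 0.2, amplitude = 500,
                              baseline = 20, window = c(618, 622),
                              n = 1001) {
  x <- seq(window[1], window[2], length.out = n)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  wgm_spectrum(x, baseline + amplitude * exp(-(x - center)^2 / (2 * s^2)))
}

neutravidin <- molecule_properties()
ps_sphere <- resonator_model(10, 1.59, 1.33, 1.5)
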