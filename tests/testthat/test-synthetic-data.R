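test_that("scene construction enforces the physical invariants", {
  expect_error(simulation_scene(q_below = 2e4, q_above = 1e4), "q_above")
  expect_error(simulation_scene(q_below = 0.5, q_above = 2), "q_above")
  expect_error(simulation_scene(threshold_power_uW = -1), "threshold")
  expect_error(simulation_scene(gain_window_nm = c(800, 820)),
               "envelope support")
  expect_error(simulate_spectrum(simulation_scene(), pump_uW = -5), ">= 0")
})

test_that("generators are deterministic given (scene, seed)", {
  scene <- simulation_scene(noise = list(additive_sd = 5),
                            instrument = instrument_model(1024, c(610, 630)))
  a <- simulate_spectrum(scene, 10, seed = 99)
  b <- simulate_spectrum(scene, 10, seed = 99)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_spectrum(scene, 10, seed = 100)
  expect_false(identical(c$intensity, b$intensity))

  s1 <- simulate_power_sweep(scene, seq(5, 100, 5), 2, 40,
                             rel_noise_sd = 0.05, seed = 7)
  s2 <- simulate_power_sweep(scene, seq(5, 100, 5), 2, 40,
                             rel_noise_sd = 0.05, seed = 7)
  expect_identical(s1$intensity, s2$intensity)

  b1 <- simulate_binding_series(400, kinetics_preset(400), seed = 3)
  b2 <- simulate_binding_series(400, kinetics_preset(400), seed = 3)
  expect_identical(b1$shift_nm, b2$shift_nm)
})

test_that("noiseless spectra put peaks on the comb and honour the Q regimes", {
  scene <- quiet_scene(window = c(605, 635))
  s <- simulate_spectrum(scene, pump_uW = 10) # below threshold
  comb <- scene_mode_comb(scene, pad_nm = 0)
  det <- detect_peaks(s)
  # every detected maximum within one sample of a comb position
  dmin <- vapply(det$wavelength_nm,
                 function(w) min(abs(w - comb$center_nm)), numeric(1))
  expect_lt(max(dmin), scene$instrument$resolution_nm)

  # below threshold no peak is narrower than lambda / q_below
  pk <- fit_peaks(s)
  expect_true(all(pk$fwhm_nm >= 0.95 * pk$center_nm / scene$q_below))

  # above threshold: in-window modes reach q_above, out-of-window modes
  # stay near q_below
  s_hi <- simulate_spectrum(scene, pump_uW = 2 * scene$threshold_power_uW)
  pk_hi <- fit_peaks(s_hi)
  inwin <- pk_hi$center_nm >= scene$gain_window_nm[1] &
    pk_hi$center_nm <= scene$gain_window_nm[2]
  expect_true(any(inwin) && any(!inwin))
  expect_true(all(pk_hi$q_factor[inwin] >= 1.5e4 * 0.9))
  expect_equal(median(pk_hi$q_factor[!inwin]), scene$q_below,
               tolerance = 0.02)
})

test_that("fitted center of the strongest peak is stable across noise seeds", {
  scene <- quiet_scene(additive_sd = 5, window = c(616, 624),
                       n_pixels = 2048)
  det0 <- detect_peaks(simulate_spectrum(scene, 10, seed = 1))
  top <- det0[which.max(det0$intensity), ]
  centers <- vapply(1:100, function(sd) {
    s <- simulate_spectrum(scene, 10, seed = sd)
    fit_peak(s, c(top$window_lo_nm, top$window_hi_nm))$center_nm
  }, numeric(1))
  expect_lt(sd(centers), scene$instrument$resolution_nm)
})

test_that("power sweeps are piecewise linear with a kink at threshold", {
  scene <- simulation_scene(threshold_power_uW = 28)
  p <- seq(5, 100, length.out = 20)
  sw <- simulate_power_sweep(scene, p, slope_below = 2, slope_above = 40,
                             rel_noise_sd = 0, seed = NULL)
  below <- sw$power_uW <= 28
  expect_equal(sw$intensity[below], 2 * sw$power_uW[below])
  expect_equal(sw$intensity[!below],
               2 * 28 + 40 * (sw$power_uW[!below] - 28))
  expect_error(simulate_power_sweep(scene, numeric(0), 2, 40), "empty")
  expect_error(simulate_power_sweep(scene, p, 40, 2), "slope_above")
  # equal slopes allowed: single line for the degenerate-fit path
  sw2 <- simulate_power_sweep(scene, p, 3, 3, seed = NULL)
  expect_equal(sw2$intensity, 3 * p)
})

test_that("deposition series implements the forward shift model exactly", {
  scene <- quiet_scene(window = c(616, 624))
  res <- scene$resonator
  zero <- simulate_deposition_series(res, c(0, 0), scene, seed = NULL)
  expect_equal(zero[[1]]$intensity, zero[[2]]$intensity)
  expect_equal(zero[[2]]$intensity, zero[[3]]$intensity)

  # single layer: e = 1.71 nm on R = 10 um shifts ~0.1 nm at 620 nm
  one <- simulate_deposition_series(res, 1.709677, scene, seed = NULL)
  pk0 <- fit_peaks(one[[1]])
  pk1 <- fit_peaks(one[[2]])
  i0 <- which.min(abs(pk0$center_nm - 620))
  shift <- pk1$center_nm[which.min(abs(pk1$center_nm - pk0$center_nm[i0] - 0.1))] -
    pk0$center_nm[i0]
  expect_equal(shift, 0.1, tolerance = 2e-3)
  expect_error(simulate_deposition_series(res, c(1, -1), scene), ">= 0")

  # inversion round trip through the analysis chain
  layers <- c(0.8, 2.2, 3.2)
  sp <- simulate_deposition_series(res, layers, scene, seed = NULL)
  anchor <- pk0$center_nm[i0]
  tracks <- lapply(seq_along(layers), function(k)
    track_peak(sp[k:(k + 1)], anchor * (1 + res$n_L * c(0, cumsum(layers))[k] /
                                          (res$n_s * res$radius_um * 1000)) +
                 c(-0.4, 0.4)))
  rep_tbl <- deposition_report(tracks, res, lambda_nm = anchor)
  expect_equal(rep_tbl$thickness_nm, layers, tolerance = 0.02)
  expect_equal(rep_tbl$cumulative_thickness_nm, cumsum(rep_tbl$thickness_nm))
})

test_that("binding series obey the saturation law and its limits", {
  kin <- list(d_max_g_m2 = 1.77e-3, tau_s = 15)
  clean <- simulate_binding_series(1600, kin, noise_sd_nm = 0, seed = NULL)
  expect_equal(clean$shift_nm[1], 0) # t = 0
  expect_equal(clean$density_g_m2[1], 0)
  # asymptote: final minute of a 30 min record at tau = 15 s is d_max
  expect_equal(clean$density_g_m2[nrow(clean)], kin$d_max_g_m2,
               tolerance = 1e-9)
  # noiseless forward + inverse chain is the identity at machine precision
  d_true <- kin$d_max_g_m2 * (1 - exp(-clean$time_s / kin$tau_s))
  expect_equal(clean$density_g_m2, d_true, tolerance = 1e-12)
  expect_error(simulate_binding_series(400, list(d_max_g_m2 = 1e-3,
                                                 tau_s = -1)),
               "tau_s")
  expect_error(kinetics_preset(7), "no preset")
})
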