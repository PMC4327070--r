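test_that("series_to_density applies the transduction chain point-wise", {
  tr <- data.frame(time_s = 0:5 * 60, shift_nm = rep(0, 6))
  attr(tr, "reference_center_nm") <- 620
  ser <- series_to_density(tr, ps_sphere, neutravidin)
  expect_equal(ser$density_g_m2, rep(0, 6))

  # noiseless simulator series maps back to the generating densities
  kin <- kinetics_preset(400)
  sim <- simulate_binding_series(400, kin, noise_sd_nm = 0, seed = NULL)
  tr2 <- data.frame(time_s = sim$time_s, shift_nm = sim$shift_nm)
  attr(tr2, "reference_center_nm") <- attr(sim, "lambda_nm")
  ser2 <- series_to_density(tr2, ps_sphere, neutravidin)
  d_true <- kin$d_max_g_m2 * (1 - exp(-sim$time_s / kin$tau_s))
  expect_equal(ser2$density_g_m2, d_true, tolerance = 1e-12)

  # noisy series: point-wise density errors follow linear propagation
  # (the chain is linear, so errors are exactly coefd * wavelength noise)
  coefd <- density_shift_coefficient(neutravidin, ps_sphere, 620)
  errs <- unlist(lapply(1:20, function(sd) {
    noisy <- simulate_binding_series(400, kin, noise_sd_nm = 0.004,
                                     seed = sd)
    noisy$density_g_m2 - d_true
  }))
  expect_equal(sd(errs), coefd * 0.004, tolerance = 0.15)
})

test_that("saturation metrics match the closed-form exponential", {
  # constant series
  tt <- seq(0, 600, 60)
  const <- structure(data.frame(time_s = tt, shift_nm = rep(0.1, 11),
                                density_g_m2 = rep(2e-3, 11)),
                     class = c("binding_series", "data.frame"))
  sm <- saturation_metrics(const)
  expect_equal(sm$plateau_g_m2, 2e-3)
  expect_equal(sm$time_to_95pct_s, 0)
  expect_true(sm$saturated)

  # dense exact exponential: plateau -> d_max, t95 ~ ln(20) tau
  tau <- 100
  tt <- seq(0, 30 * tau, tau / 100)
  d <- 5e-4 * (1 - exp(-tt / tau))
  ser <- structure(data.frame(time_s = tt, shift_nm = d, density_g_m2 = d),
                   class = c("binding_series", "data.frame"))
  sm2 <- saturation_metrics(ser)
  expect_equal(sm2$plateau_g_m2, 5e-4, tolerance = 1e-3)
  expect_equal(sm2$time_to_95pct_s, log(20) * tau, tolerance = 0.02)
  expect_true(sm2$saturated)

  # still-rising linear series is not saturated
  lin <- structure(data.frame(time_s = tt, shift_nm = tt,
                              density_g_m2 = 1e-6 * tt),
                   class = c("binding_series", "data.frame"))
  expect_false(saturation_metrics(lin)$saturated)
  expect_error(saturation_metrics(ser[1:3, ]), "at least 5")
})

test_that("exponential plateau fit recovers d_max across the presets", {
  for (conc in c(1600, 400, 100)) {
    kin <- kinetics_preset(conc)
    est <- vapply(1:25, function(sd) {
      ser <- simulate_binding_series(conc, kin, noise_sd_nm = 0.004,
                                     seed = sd)
      fit_saturation_exponential(ser)$d_max_g_m2
    }, numeric(1))
    expect_lt(abs(median(est) - kin$d_max_g_m2) / kin$d_max_g_m2, 0.1)
  }
})

test_that("LOD decisions detect signal and spare the negative control", {
  kin <- kinetics_preset(1600)
  ser <- simulate_binding_series(1600, kin, noise_sd_nm = 0.004, seed = 2)
  expect_true(lod_decision(ser, 0.004)$detected)

  # tail mean at 10 sigma must trigger
  tt <- seq(0, 600, 60)
  strong <- structure(data.frame(time_s = tt, shift_nm = rep(0.04, 11),
                                 density_g_m2 = rep(0.04, 11)),
                      class = c("binding_series", "data.frame"))
  expect_true(lod_decision(strong, 0.004)$detected)

  # casein-blocked negative control: binding off, noise only
  blank <- simulate_binding_series(0, kinetics_preset(0),
                                   noise_sd_nm = 0.004, seed = 17)
  expect_false(lod_decision(blank, 0.004)$detected)
  expect_error(lod_decision(blank, 0), "> 0")
})

test_that("higher generating plateaus never reduce the detection rate", {
  concs <- c(1600, 400, 100, 20, 4)
  for (noise in c(0.004, 0.02)) {
    rates <- vapply(concs, function(conc) {
      mean(vapply(1:40, function(sd) {
        ser <- simulate_binding_series(conc, kinetics_preset(conc),
                                       noise_sd_nm = noise, seed = sd)
        lod_decision(ser, noise)$detected
      }, logical(1)))
    }, numeric(1))
    # generating d_max decreases along concs; detection rate must not rise
    # (up to binomial wiggle at 40 seeds)
    expect_true(all(diff(rates) <= 0.05))
  }
})

test_that("deposition report sums per-layer thicknesses", {
  mk <- function(shift) {
    tr <- data.frame(time_s = c(0, 60), shift_nm = c(0, shift))
    attr(tr, "reference_center_nm") <- 620
    tr
  }
  rep0 <- deposition_report(list(mk(0), mk(0)), ps_sphere)
  expect_equal(rep0$thickness_nm, c(0, 0))
  shifts <- c(0.02, 0.08, 0.12)
  rep1 <- deposition_report(lapply(shifts, mk), ps_sphere)
  expect_equal(rep1$thickness_nm,
               layer_thickness(shifts, 620, 10, 1.5, 1.59))
  expect_equal(rep1$cumulative_thickness_nm, cumsum(rep1$thickness_nm))
})
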