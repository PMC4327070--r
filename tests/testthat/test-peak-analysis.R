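test_that("peak detection finds the comb and only the comb", {
  # constant spectrum: nothing to find
  flat <- wgm_spectrum(seq(600, 640, 0.01), rep(100, 4001))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  # noiseless single-polarization comb: one window per mode
  scene <- quiet_scene(tm_amplitude = 0, window = c(608, 632))
  s <- simulate_spectrum(scene, pump_uW = 10)
  comb <- scene_mode_comb(scene, pad_nm = 0)
  comb <- comb[comb$polarization == "TE", ]
  det <- detect_peaks(s)
  expect_equal(nrow(det), nrow(comb))
  expect_equal(det$wavelength_nm, comb$center_nm,
               tolerance = 2 * scene$instrument$resolution_nm / 620)

  # an isolated single-pixel spike below the prominence threshold is
  # excluded
  it <- s$intensity
  spike_at <- which.min(abs(s$wavelength_nm - 611))
  it[spike_at] <- it[spike_at] + 0.03 * max(it)
  s2 <- wgm_spectrum(s$wavelength_nm, it)
  expect_equal(nrow(detect_peaks(s2)), nrow(comb))
})

test_that("peak detection is translation-equivariant", {
  s <- gaussian_spectrum(center = 620, window = c(618, 622))
  shift <- 3.7
  s2 <- wgm_spectrum(s$wavelength_nm + shift, s$intensity)
  d1 <- detect_peaks(s)
  d2 <- detect_peaks(s2)
  expect_equal(d2$wavelength_nm, d1$wavelength_nm + shift)
  expect_equal(d2$window_lo_nm, d1$window_lo_nm + shift)
  expect_equal(d2$window_hi_nm, d1$window_hi_nm + shift)
})

test_that("Gaussian fit recovers exact parameters and the Q identity", {
  pk <- fit_peak(gaussian_spectrum(center = 620.000, fwhm = 0.2),
                 c(619, 621))
  expect_equal(pk$center_nm, 620, tolerance = 1e-9)
  expect_equal(pk$fwhm_nm, 0.2, tolerance = 1e-7)
  expect_equal(pk$q_factor, pk$center_nm / pk$fwhm_nm)

  # Q = lambda / dlambda at the two regimes of the sensor
  pk_lo <- fit_peak(gaussian_spectrum(center = 620, fwhm = 0.2067),
                    c(619, 621))
  expect_equal(pk_lo$q_factor, 3.0e3, tolerance = 2e-3)
  pk_hi <- fit_peak(gaussian_spectrum(center = 620, fwhm = 0.0413,
                                      window = c(619.5, 620.5)),
                    c(619.8, 620.2))
  expect_equal(pk_hi$q_factor, 1.5e4, tolerance = 2e-3)

  expect_error(fit_peak(gaussian_spectrum(n = 21), c(619.99, 620.01)),
               "fewer than 5")
  # FWHM below two sample spacings (0.03 nm vs 0.02 nm/px) is flagged
  expect_warning(
    fit_peak(gaussian_spectrum(fwhm = 0.03, n = 201), c(619, 621)),
    "under-resolved")
})

test_that("fitted centers are unbiased relative to their standard error", {
  # mean center error over seeded noisy realizations stays below the
  # per-fit standard error
  x <- seq(619, 621, length.out = 401)
  s_true <- 0.2 / (2 * sqrt(2 * log(2)))
  clean <- 30 + 400 * exp(-(x - 620)^2 / (2 * s_true^2))
  set.seed(11)
  errs <- ses <- numeric(200)
  for (i in seq_along(errs)) {
    pk <- fit_peak(wgm_spectrum(x, pmax(clean + rnorm(401, sd = 5), 0)),
                   c(619, 621))
    errs[i] <- pk$center_nm - 620
    ses[i] <- pk$center_se_nm
  }
  expect_lt(abs(mean(errs)), mean(ses))
  # and every fit keeps the Q identity exactly
  expect_equal(pk$q_factor, pk$center_nm / pk$fwhm_nm)
})

test_that("tracking reports zero shift on identical spectra and follows a
           deposition series", {
  scene <- quiet_scene(window = c(616, 624))
  s <- simulate_spectrum(scene, pump_uW = 10)
  # initial window around the TE mode near 620.5 nm
  tr <- track_peak(list(s, s, s), c(620.0, 621.1))
  expect_equal(tr$shift_nm[1], 0)
  expect_lt(max(abs(tr$shift_nm)), 1e-4)

  # deposition forward model round trip: recovered shifts match the
  # forward shifts within twice the fit standard error (plus grid quantization)
  layers <- c(0.8, 2.2, 3.2, 3.6, 3.4)
  res <- scene$resonator
  spectra <- simulate_deposition_series(res, layers, scene, seed = NULL)
  pk0 <- fit_peaks(simulate_spectrum(scene, 2 * scene$threshold_power_uW))
  anchor <- pk0$center_nm[which.min(abs(pk0$center_nm - 620))]
  tr <- track_peak(spectra, anchor + c(-0.5, 0.5))
  e_cum <- c(0, cumsum(layers))
  expected <- attr(tr, "reference_center_nm") * res$n_L * e_cum /
    (res$n_s * res$radius_um * 1000)
  expect_lt(max(abs(tr$shift_nm - expected)), 1e-3)
})

test_that("a one-FSR jump raises a mode-hopping error", {
  # when the tracked mode jumps a full FSR while its neighbours stay put,
  # the refit lands a comb tooth away and the step exceeds FSR/2
  fsr <- 620^2 / (2 * pi * 10 * 1000 * 1.59)
  s1 <- gaussian_spectrum(center = 620, window = c(612, 628), n = 4001)
  s2 <- gaussian_spectrum(center = 620 + fsr, window = c(612, 628),
                          n = 4001)
  expect_error(track_peak(list(s1, s2), c(616, 624), fsr_nm = fsr),
               "mode hopping")
  # without the FSR hint the ambiguity cannot be flagged
  expect_silent(track_peak(list(s1, s2), c(616, 624)))
})

test_that("mode pairing separates interleaved combs and respects a single
           comb", {
  scene <- quiet_scene(window = c(608, 632))
  comb <- scene_mode_comb(scene, pad_nm = 0)
  peaks <- data.frame(center_nm = sort(comb$center_nm),
                      amplitude = 1)
  pairs <- pair_modes_fsr(peaks)
  te <- sort(comb$center_nm[comb$polarization == "TE"])
  tm <- sort(comb$center_nm[comb$polarization == "TM"])
  # generator same-polarization spacings reproduced exactly (the comb
  # labels themselves are latent, so compare the spacing multisets)
  expect_equal(sort(pairs$spacing_nm), sort(c(diff(te), diff(tm))),
               tolerance = 1e-12)
  expect_equal(length(unique(pairs$comb)), 2L)

  # single comb (TM amplitude zero): all adjacent pairs returned
  single <- data.frame(center_nm = te, amplitude = 1)
  p2 <- pair_modes_fsr(single)
  expect_equal(nrow(p2), length(te) - 1)
  expect_equal(p2$spacing_nm, diff(te), tolerance = 1e-12)

  expect_error(pair_modes_fsr(data.frame(center_nm = c(620, 621))),
               "at least 3")
})

test_that("pairing recovers the FSR within 0.5 % under 4 pm jitter", {
  scene <- quiet_scene(window = c(608, 632))
  comb <- scene_mode_comb(scene, pad_nm = 0)
  true_fsr <- median(diff(sort(comb$center_nm[comb$polarization == "TE"])))
  set.seed(5)
  errs <- replicate(50, {
    peaks <- data.frame(
      center_nm = sort(comb$center_nm + rnorm(nrow(comb), sd = 0.004)),
      amplitude = 1)
    pairs <- pair_modes_fsr(peaks)
    abs(median(pairs$spacing_nm) - true_fsr) / true_fsr
  })
  expect_lt(median(errs), 0.005)
})
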