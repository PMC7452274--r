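# Forward simulation: determinism, linearity, spectral structure,
# annihilation, photon statistics.

test_that("identical seeds give bit-identical surfaces and histograms", {
  p <- make_preset("gel", "quenched", 674)
  a <- simulate_ta(p, noise = noise_model(seed = 99))
  b <- simulate_ta(p, noise = noise_model(seed = 99))
  expect_identical(a$data, b$data)

  d1 <- simulate_tcspc(c(1, 3), c(0.4, 0.6), total_counts = 1e4, seed = 7)
  d2 <- simulate_tcspc(c(1, 3), c(0.4, 0.6), total_counts = 1e4, seed = 7)
  expect_identical(d1$counts, d2$counts)
})

test_that("a noiseless surface is the sum of its per-component surfaces", {
  p <- make_preset("gel", "unquenched", 674)
  wl <- seq(430, 750, by = 4)
  t <- default_ta_times()
  irf <- irf_gaussian(0, 0.1)
  full <- simulate_ta(p, times = t, wavelengths = wl, irf = irf,
                      noise = noise_model(ta_sigma = 0))
  conc <- concentration_profiles(scheme_from_preset(p), irf, t)
  sp <- preset_spectra(p, wl)
  parts <- lapply(seq_len(nrow(sp$amplitudes)), function(l) {
    conc[, l, drop = FALSE] %*% sp$amplitudes[l, , drop = FALSE]
  })
  expect_equal(full$data, Reduce(`+`, parts), tolerance = 1e-12)
})

test_that("zero band amplitudes and zero noise give the all-zero surface", {
  p <- make_preset("gel", "quenched", 674)
  p$band_catalog <- lapply(p$band_catalog, function(cat) {
    cat$amplitude <- 0
    cat
  })
  s <- simulate_ta(p, noise = noise_model(ta_sigma = 0))
  expect_true(all(s$data == 0))
})

test_that("the 10-ps gel spectrum has a 515-nm ESA maximum and a 684-nm bleach minimum", {
  s <- simulate_ta(make_preset("gel", "quenched", 674),
                   noise = noise_model(ta_sigma = 0))
  sp <- spectrum_at(s, 10)
  expect_equal(sp$wavelength_nm[which.min(sp$value)], 684, tolerance = 1e-6)
  in_band <- sp$wavelength_nm >= 505 & sp$wavelength_nm <= 525
  expect_gt(max(sp$value[in_band]), 0)
  # local maximum: larger than the values flanking the window
  expect_gt(max(sp$value[in_band]), sp$value[sp$wavelength_nm == 500])
  expect_gt(max(sp$value[in_band]), sp$value[sp$wavelength_nm == 535])

  # gel/buffer contrast at 10 ps
  sb <- simulate_ta(make_preset("buffer", "quenched", 674),
                    noise = noise_model(ta_sigma = 0))
  spb <- spectrum_at(sb, 10)
  expect_lt(max(spb$value[spb$wavelength_nm >= 505 & spb$wavelength_nm <= 525]),
            1e-6)
})

test_that("Chl-b excitation shows a 684-nm rise but an IRF-limited 515-nm rise", {
  s <- simulate_ta(make_preset("gel", "quenched", 645),
                   noise = noise_model(ta_sigma = 0))
  rt <- rise_time_compare(s, 684, 515, c(-1, 3))
  expect_gt(rt$t50_ps[1] - rt$t50_ps[2], 0.1)
  # 515 nm rises within the IRF (fwhm 0.1 ps)
  expect_lt(abs(rt$t50_ps[2]), 0.05)
})

test_that("triplet plateau is weaker in the quenched sample", {
  t_late <- c(seq(-1, 1, 0.5), 10^seq(1, 4.2, length.out = 30))
  sq <- simulate_ta(make_preset("gel", "quenched", 674), times = t_late,
                    noise = noise_model(ta_sigma = 0))
  su <- simulate_ta(make_preset("gel", "unquenched", 674), times = t_late,
                    noise = noise_model(ta_sigma = 0))
  # at 15 ns the singlets are gone; what remains is the triplet spectrum
  last_q <- spectrum_at(sq, 15000)
  last_u <- spectrum_at(su, 15000)
  expect_lt(max(abs(last_q$value)), max(abs(last_u$value)))
  expect_gt(max(abs(last_q$value)), 0)
})

test_that("the numerical annihilation path agrees with the analytic path", {
  p <- make_preset("gel", "quenched", 674)
  wl <- seq(450, 720, by = 5)
  an <- simulate_ta(p, wavelengths = wl, noise = noise_model(ta_sigma = 0))
  od <- simulate_ta_intensity_series(p, 1, wavelengths = wl,
                                     noise = noise_model(ta_sigma = 0),
                                     force_ode = TRUE)[[1]]
  expect_lt(max(abs(od$data - an$data)) / max(abs(an$data)), 1e-3)

  # infinitesimal intensity with gamma > 0 reduces to the linear model
  pb <- make_preset("buffer", "quenched", 674)
  lin <- simulate_ta_intensity_series(pb, 1e-6, wavelengths = wl,
                                      noise = noise_model(ta_sigma = 0))[[1]]
  ref <- simulate_ta(pb, wavelengths = wl, noise = noise_model(ta_sigma = 0))
  expect_lt(max(abs(lin$data - ref$data)) / max(abs(ref$data)), 1e-3)
})

test_that("normalized gel kinetics are intensity-independent, buffer kinetics accelerate", {
  wl <- seq(660, 710, by = 2)
  tr685 <- function(s) extract_trace(s, 685, invert = TRUE, normalize = TRUE)
  gel <- simulate_ta_intensity_series(make_preset("gel", "quenched", 674),
                                      c(0.5, 1, 2), wavelengths = wl,
                                      noise = noise_model(ta_sigma = 0))
  expect_equal(annihilation_diagnostic(lapply(gel, tr685)), 0, tolerance = 1e-9)

  buf <- simulate_ta_intensity_series(make_preset("buffer", "quenched", 674),
                                      c(0.5, 1, 2), wavelengths = wl,
                                      noise = noise_model(ta_sigma = 0))
  traces <- lapply(buf, tr685)
  expect_gt(annihilation_diagnostic(traces), 0.02)
  # higher intensity decays faster: smaller normalized signal at 50 ps
  at50 <- vapply(traces, function(tr) tr$value[which.min(abs(tr$time_ps - 50))],
                 numeric(1))
  expect_true(all(diff(at50) < 0))
})

test_that("TCSPC simulation has the closed-form mean arrival time and validates inputs", {
  d <- simulate_tcspc(2, 1, irf = irf_gaussian(2, 0), total_counts = 5e6,
                      channels = 4096, window_ns = 50, seed = 1)
  mean_arrival <- sum(d$time_ns * d$counts) / sum(d$counts)
  expect_equal(mean_arrival, 2 + 2, tolerance = 0.01)

  expect_error(simulate_tcspc(-1, 1), "positive")
  expect_error(simulate_tcspc(c(1, 2), c(0.5, 0.5), channels = 5), "3 channels")
  expect_error(simulate_tcspc(c(1, 2), c(-0.1, 1.1)), "non-negative")
  # amplitudes are renormalized, so published rows summing to 1.12 are valid
  expect_s3_class(simulate_tcspc(c(0.57, 2.96, 4.11), c(0.13, 0.37, 0.62),
                                 total_counts = 100, seed = 1),
                  "fluor_decay")
})

test_that("axis validation rejects malformed grids", {
  p <- make_preset("gel", "quenched", 674)
  expect_error(simulate_ta(p, times = c(0, 2, 1)), "increasing")
  expect_error(simulate_ta(p, wavelengths = c(500, 480)), "increasing")
  expect_error(irf_gaussian(0, -0.1), "non-negative")
  expect_error(simulate_ta_intensity_series(p, c(-1, 1)), "positive")
})
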