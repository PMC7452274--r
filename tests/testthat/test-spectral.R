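# Spectral and kinetic quantifications.

test_that("trace extraction records the column used and validates input", {
  toy <- toy_two_comp()
  tr <- extract_trace(toy$surface, 561, normalize = TRUE)
  expect_equal(attr(tr, "wavelength_nm"), 560)
  expect_equal(max(abs(tr$value)), 1)
  expect_identical(attr(tr, "normalization"), "normalized")
  expect_error(extract_trace(toy$surface, 900), "outside")

  # double inversion is the identity
  raw <- extract_trace(toy$surface, 560)
  inv2 <- extract_trace(toy$surface, 560, invert = TRUE)
  expect_equal(raw$value, -inv2$value)

  zero <- ta_surface(0:2, c(500, 510), matrix(0, 3, 2))
  expect_error(extract_trace(zero, 500, normalize = TRUE), "all-zero")
})

test_that("inverted 515-nm kinetics overlay the 684-nm bleach decay", {
  s <- simulate_ta(make_preset("gel", "quenched", 674),
                   noise = noise_model(ta_sigma = 0))
  t515 <- extract_trace(s, 515, normalize = TRUE)
  t684 <- extract_trace(s, 684, invert = TRUE, normalize = TRUE)
  sel <- s$times_ps > 0.5 & s$times_ps < 500
  expect_lt(max(abs(t515$value[sel] - t684$value[sel])), 0.05)
})

test_that("the 515/684 band ratio is 0.50 in quenched gel and scale-invariant", {
  s <- simulate_ta(make_preset("gel", "quenched", 674),
                   noise = noise_model(ta_sigma = 0))
  sp <- spectrum_at(s, 10)
  br <- band_ratio(sp, c(505, 525), c(675, 695))
  expect_equal(br$ratio, 0.50, tolerance = 2e-3)
  expect_lt(br$band_amplitude * br$reference_amplitude, 0)  # ESA vs bleach

  sp2 <- sp
  sp2$value <- sp2$value * 7.3
  expect_equal(band_ratio(sp2, c(505, 525), c(675, 695))$ratio, br$ratio,
               tolerance = 1e-12)

  # buffer: no band, ratio at the numerical floor
  sb <- simulate_ta(make_preset("buffer", "quenched", 674),
                    noise = noise_model(ta_sigma = 0))
  expect_lt(band_ratio(spectrum_at(sb, 10), c(505, 525), c(675, 695))$ratio,
            0.01)

  expect_error(band_ratio(sp, c(505, 525), c(510, 540)), "disjoint")
  expect_error(band_ratio(sp, c(100, 200), c(675, 695)), "no grid points")
})

test_that("difference spectra and peak finding behave on degenerate input", {
  a <- absorption_preset("gel")
  expect_error(difference_spectrum(a, absorption_preset("gel", seq(400, 750, 2))),
               "identical wavelength grid")
  d <- difference_spectrum(a, a)
  expect_true(all(d$value == 0))
  expect_equal(nrow(peak_positions(d, c(640, 700))), 0L)
})

test_that("quadratic interpolation locates band centers to < 0.2 nm on a 1-nm grid", {
  wl <- seq(400, 750, by = 1)
  for (center in c(515.4, 540.0, 683.7)) {
    sp <- tibble::tibble(wavelength_nm = wl,
                         value = exp(-(wl - center)^2 / (2 * 8^2)))
    pk <- peak_positions(sp, c(center - 20, center + 20))
    expect_lt(abs(pk$wavelength_nm[pk$type == "max"] - center), 0.2)
  }
})

test_that("vibronic gaps follow the closed form", {
  expect_equal(vibronic_gap_cm(460, 490), 1e7 * (1 / 460 - 1 / 490))
  expect_equal(round(vibronic_gap_cm(460, 490)), 1331)
  expect_equal(round(vibronic_gap_cm(490, 515)), 991)
  expect_equal(vibronic_gap_cm(500, 500), 0)
  expect_error(vibronic_gap_cm(-1, 500), "positive")
})

test_that("the annihilation diagnostic is zero for identical traces and monotone in gamma", {
  wl <- seq(660, 710, by = 2)
  tr685 <- function(s) extract_trace(s, 685, invert = TRUE, normalize = TRUE)
  p <- make_preset("buffer", "quenched", 674)
  diag_at_gamma <- function(g) {
    p$annihilation_gamma <- g
    series <- simulate_ta_intensity_series(p, c(0.5, 1, 2), wavelengths = wl,
                                           noise = noise_model(ta_sigma = 0))
    annihilation_diagnostic(lapply(series, tr685))
  }
  d <- vapply(c(0, 0.5, 1), diag_at_gamma, numeric(1))
  expect_equal(d[1], 0, tolerance = 1e-9)
  expect_true(all(diff(d) > 0))

  tr <- tr685(simulate_ta(p, wavelengths = wl, noise = noise_model(ta_sigma = 0)))
  expect_equal(annihilation_diagnostic(list(tr, tr)), 0)
  expect_error(annihilation_diagnostic(list(tr)), "two traces")
  un <- tr
  un$value <- un$value * 0.5
  expect_error(annihilation_diagnostic(list(tr, un)), "normalized")
})

test_that("half-rise times distinguish transfer-fed from instantaneous bands", {
  # single-compartment surface: both probes rise together at t0
  t <- seq(-1, 10, by = 0.02)
  wl <- c(500, 600)
  C <- concentration_profiles(kinetic_scheme(50), irf_gaussian(0, 0.1), t)
  s <- ta_surface(t, wl, C %*% matrix(c(1, 0.4), nrow = 1))
  rt <- rise_time_compare(s, 500, 600, c(-1, 5))
  expect_equal(rt$t50_ps[1], rt$t50_ps[2], tolerance = 1e-9)
  expect_equal(rt$t50_ps[1], 0, tolerance = 0.01)

  # non-rising trace raises an error
  flat <- ta_surface(t, wl, matrix(1, length(t), 2))
  expect_error(rise_time_compare(flat, 500, 600, c(-1, 5)), "rise")
})
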