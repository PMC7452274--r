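# Variable-projection global fitting, masking, bootstrap, model-size scan.

test_that("noiseless two-component data are recovered to machine-level accuracy", {
  toy <- toy_two_comp()
  fit <- fit_global(toy$surface, kinetic_scheme(c(2, 50)), toy$irf,
                    fit_options(n_starts = 1))
  expect_equal(fit$lifetimes$lifetime_ps, c(5, 100), tolerance = 1e-6)
  expect_true(fit$converged)
  # EADS recovered on the full grid
  expect_equal(fit$eads[[1]]$amplitudes, toy$spectra, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(fit$rmse, 1e-10)
})

test_that("noiseless preset surfaces are recovered exactly (exact-model identifiability)", {
  for (args in list(list("gel", "quenched", 674), list("buffer", "unquenched", 674))) {
    p <- do.call(make_preset, args)
    s <- simulate_ta(p, wavelengths = seq(430, 750, 2),
                     noise = noise_model(ta_sigma = 0))
    truth <- p$ground_truth_lifetimes
    start <- kinetic_scheme(c(1, 10, 100, 2900),
                            status = c("free", "free", "free", "fixed"),
                            nondecaying_terminal = TRUE, branch_fraction = 0.2)
    fit <- fit_global(s, start, irf_gaussian(0, 0.1), fit_options(n_starts = 1))
    expect_equal(fit$lifetimes$lifetime_ps, truth, tolerance = 1e-6)
  }
})

test_that("variable projection agrees with a brute-force lifetime grid search", {
  toy <- toy_two_comp(times = seq(-0.5, 300, length.out = 40),
                      wavelengths = seq(520, 680, by = 20),
                      sigma = 0.01, seed = 4)
  tau1_grid <- seq(3, 8, by = 0.1)
  tau2_grid <- seq(70, 140, by = 1)
  ssr_node <- function(t1, t2) {
    C <- concentration_profiles(kinetic_scheme(c(t1, t2)), toy$irf,
                                toy$surface$times_ps)
    sum(qr.resid(qr(C), toy$surface$data)^2)
  }
  ssr <- outer(tau1_grid, tau2_grid, Vectorize(ssr_node))
  best <- which(ssr == min(ssr), arr.ind = TRUE)
  fit <- fit_global(toy$surface, kinetic_scheme(c(2, 50)), toy$irf,
                    fit_options(n_starts = 1))
  expect_lt(abs(fit$lifetimes$lifetime_ps[1] - tau1_grid[best[1]]), 0.1)
  expect_lt(abs(fit$lifetimes$lifetime_ps[2] - tau2_grid[best[2]]), 1)
})

test_that("masking drops exactly the requested columns and protects the fit from corruption", {
  toy <- toy_two_comp(wavelengths = seq(400, 750, by = 2))
  s <- toy$surface
  masked <- apply_mask(s, c(650, 700))
  expect_identical(which(masked$masked),
                   which(s$wavelengths_nm >= 650 & s$wavelengths_nm <= 700))
  expect_error(apply_mask(s, c(300, 800)), "every wavelength")
  expect_error(apply_mask(s, c(900, 950)), "outside")

  ref <- fit_global(s, kinetic_scheme(c(2, 50)), toy$irf, fit_options(n_starts = 1))

  # corrupt everything inside 650-700 nm, then mask it away
  bad <- s
  idx <- which(s$wavelengths_nm >= 650 & s$wavelengths_nm <= 700)
  set.seed(2)
  bad$data[, idx] <- matrix(rnorm(length(bad$data[, idx]), sd = 50),
                            nrow = nrow(bad$data))
  fit_masked <- fit_global(bad, kinetic_scheme(c(2, 50)), toy$irf,
                           fit_options(mask_ranges_nm = c(650, 700), n_starts = 1))
  expect_equal(fit_masked$lifetimes$lifetime_ps, ref$lifetimes$lifetime_ps,
               tolerance = 1e-6)
  # masked wavelengths carry no EADS values and no residuals
  expect_true(all(is.na(fit_masked$eads[[1]]$amplitudes[, idx])))
  expect_true(all(is.na(fit_masked$residuals[[1]][, idx])))

  # empty mask leaves the fit untouched
  fit_plain <- fit_global(s, kinetic_scheme(c(2, 50)), toy$irf,
                          fit_options(n_starts = 1))
  expect_equal(fit_plain$lifetimes$lifetime_ps, ref$lifetimes$lifetime_ps,
               tolerance = 1e-12)
})

test_that("shared lifetimes are linked across datasets while EADS stay per-dataset", {
  toy1 <- toy_two_comp(sigma = 0.01, seed = 21)
  toy2 <- toy_two_comp(sigma = 0.01, seed = 22)
  # second dataset: same kinetics, different spectra
  toy2$surface$data <- toy2$surface$data * 0.5
  fit <- fit_global(list(toy1$surface, toy2$surface),
                    kinetic_scheme(c(2, 50), status = "shared"),
                    toy1$irf, fit_options(n_starts = 1))
  expect_length(fit$eads, 2L)
  expect_lt(max(abs(fit$eads[[2]]$amplitudes - 0.5 * fit$eads[[1]]$amplitudes)),
            0.1)
  expect_equal(fit$lifetimes$lifetime_ps, c(5, 100), tolerance = 0.05)
})

test_that("degenerate configurations raise the documented errors", {
  toy <- toy_two_comp()
  expect_error(
    fit_global(toy$surface, kinetic_scheme(c(5, 100), status = "fixed"),
               toy$irf, fit_options(n_starts = 1)),
    "Nothing to optimize"
  )
  tiny <- ta_surface(c(0, 1), seq(500, 700, 5),
                     matrix(0.1, 2, 41))
  expect_error(
    fit_global(tiny, kinetic_scheme(c(1, 5, 20)), irf_gaussian(0, 0.1),
               fit_options(n_starts = 1)),
    "Fewer time points"
  )
  expect_error(bootstrap_cis(structure(list(converged = TRUE),
                                       class = "global_fit"), n_bootstrap = 5),
               "at least 20")
})

test_that("fixed lifetimes are never perturbed", {
  toy <- toy_two_comp()
  fit <- fit_global(toy$surface,
                    kinetic_scheme(c(2, 100), status = c("free", "fixed")),
                    toy$irf, fit_options(n_starts = 1))
  expect_equal(fit$lifetimes$lifetime_ps[2], 100)
  expect_identical(fit$lifetimes$status, c("free", "fixed"))
})

test_that("bootstrap intervals collapse on zero-noise data", {
  toy <- toy_two_comp()
  fit <- fit_global(toy$surface, kinetic_scheme(c(2, 50)), toy$irf,
                    fit_options(n_starts = 1))
  ci <- bootstrap_cis(fit, n_bootstrap = 20, seed = 1)
  widths <- (ci$ci_hi - ci$ci_lo)[1:2]
  expect_true(all(widths < 1e-6 * fit$lifetimes$lifetime_ps[1:2]))
})

test_that("bootstrap spread matches the linearized-covariance standard error", {
  # one-component toy with additive noise
  t <- seq(-0.5, 30, length.out = 80)
  wl <- seq(500, 600, by = 10)
  irf <- irf_gaussian(0, 0.1)
  tau <- 5
  spec <- gaussian_band_t(wl, 550, 20, 1)
  clean <- concentration_profiles(kinetic_scheme(tau), irf, t) %*%
    matrix(spec, nrow = 1)
  sigma <- 0.02
  set.seed(31)
  s <- ta_surface(t, wl, clean + matrix(rnorm(length(clean), sd = sigma),
                                        nrow = length(t)))
  fit <- fit_global(s, kinetic_scheme(3), irf, fit_options(n_starts = 1))
  ci <- bootstrap_cis(fit, n_bootstrap = 60, seed = 8)

  # independent oracle: delta-method SE from the full Jacobian of the
  # bilinear model (tau and the per-wavelength amplitudes)
  tau_hat <- fit$lifetimes$lifetime_ps[1]
  amps <- as.numeric(fit$eads[[1]]$amplitudes)
  model <- function(p) {
    as.vector(concentration_profiles(kinetic_scheme(p[1]), irf, t) %*%
                matrix(p[-1], nrow = 1))
  }
  p_hat <- c(tau_hat, amps)
  eps <- 1e-6
  J <- vapply(seq_along(p_hat), function(i) {
    dp <- p_hat; dm <- p_hat
    h <- eps * max(1, abs(p_hat[i]))
    dp[i] <- dp[i] + h; dm[i] <- dm[i] - h
    (model(dp) - model(dm)) / (2 * h)
  }, numeric(length(t) * length(wl)))
  sig2 <- sum(fit$residuals[[1]]^2) / (length(clean) - length(p_hat))
  se_lin <- sqrt(sig2 * solve(crossprod(J))[1, 1])
  expect_lt(abs(ci$se[1] - se_lin) / se_lin, 0.3)
})

test_that("adding components never increases the RMSE and the scan finds the elbow", {
  toy <- toy_two_comp(sigma = 0.01, seed = 41)
  scan <- select_n_components(toy$surface, 1:3, toy$irf,
                              fit_options(n_starts = 1))
  expect_true(all(diff(scan$rmse) <= 1e-8))
  # sharp drop up to the true count, flat beyond
  expect_gt(scan$rmse[1] / scan$rmse[2], 2)
  expect_lt(scan$rmse[2] / scan$rmse[3], 1.05)
  # structured residuals vanish once the model is rich enough
  expect_gt(scan$lag1_autocorr[1], scan$lag1_autocorr[2])

  # data simulated with one component stay flat beyond one
  t1 <- toy_two_comp(lifetimes = c(20, 2000),
                     times = seq(-0.5, 100, length.out = 50), sigma = 0.01,
                     seed = 42)
  one <- ta_surface(t1$surface$times_ps, t1$surface$wavelengths_nm,
                    concentration_profiles(kinetic_scheme(20), t1$irf,
                                           t1$surface$times_ps) %*%
                      t1$spectra[1, , drop = FALSE] +
                      matrix(rnorm(50 * ncol(t1$spectra), sd = 0.01), nrow = 50))
  scan1 <- select_n_components(one, 1:2, t1$irf, fit_options(n_starts = 1))
  expect_lt(scan1$rmse[1] / scan1$rmse[2], 1.05)
})

test_that("quenching gains 240-ps amplitude and loses triplet amplitude in linked fits", {
  wl <- seq(430, 750, by = 2)
  dq <- simulate_ta(make_preset("gel", "quenched", 674), wavelengths = wl,
                    noise = noise_model(seed = 61))
  du <- simulate_ta(make_preset("gel", "unquenched", 674), wavelengths = wl,
                    noise = noise_model(seed = 62))
  start <- kinetic_scheme(c(1, 10, 100, 2900),
                          status = c("free", "free", "free", "fixed"),
                          nondecaying_terminal = TRUE, branch_fraction = 0.2)
  fit <- fit_global(list(dq, du), start, irf_gaussian(0, 0.1),
                    fit_options(seed = 3))
  # EADS difference between the ~240-ps and terminal-singlet spectra
  diff_amp <- function(e) max(abs(e$amplitudes[3, ] - e$amplitudes[4, ]), na.rm = TRUE)
  expect_gt(diff_amp(fit$eads[[1]]), diff_amp(fit$eads[[2]]))
  # non-decaying (triplet) EADS magnitude: quenched < unquenched
  expect_lt(max(abs(fit$eads[[1]]$amplitudes[5, ]), na.rm = TRUE),
            max(abs(fit$eads[[2]]$amplitudes[5, ]), na.rm = TRUE))
})
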