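# Forward simulation of transient-absorption surfaces and TCSPC histograms.

#' Noise model for the synthetic generators
#'
#' @param ta_sigma Standard deviation of the additive, homoscedastic normal
#'   noise applied per (delay, wavelength) point of a TA surface, in the
#'   same (mOD-like) units as the signal. `NULL` (default) selects 1% of
#'   the maximum absolute clean signal at simulation time; `0` disables
#'   noise.
#' @param tcspc_total_counts Expected total photon count of a simulated
#'   TCSPC histogram (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#'   `NULL` draws from the session RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(ta_sigma = NULL, tcspc_total_counts = 1e6, seed = NULL) {
  if (!is.null(ta_sigma)) {
    assert_scalar_number(ta_sigma, "ta_sigma")
    if (ta_sigma < 0) stop_quenchkin("`ta_sigma` must be non-negative.")
  }
  assert_scalar_number(tcspc_total_counts, "tcspc_total_counts")
  if (tcspc_total_counts < 1) {
    stop_quenchkin("`tcspc_total_counts` must be at least 1.")
  }
  structure(
    list(ta_sigma = ta_sigma, tcspc_total_counts = tcspc_total_counts,
         seed = seed),
    class = "noise_model"
  )
}

#' Default delay grid for TA simulation
#'
#' 100 delays: linear from -1 to 1 ps (resolving the IRF), then
#' quasi-logarithmic out to 3000 ps.
#' @return Numeric vector of delays (ps).
#' @export
default_ta_times <- function() {
  c(seq(-1, 1, length.out = 41),
    exp(seq(log(1), log(3000), length.out = 60))[-1])
}

#' Default probe wavelength grid for TA simulation
#'
#' 1-nm steps over 430-750 nm, emulating the ~1 nm/pixel sampling of a
#' broadband probe spectrograph.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_ta_wavelengths <- function() {
  seq(430, 750, by = 1)
}

resolve_ta_sigma <- function(noise, clean) {
  if (is.null(noise$ta_sigma)) 0.01 * max(abs(clean)) else noise$ta_sigma
}

#' Simulate a transient-absorption surface
#'
#' Forward model of the pump-probe experiment:
#' `dA(t, lambda) = sum_l c_l(t) S_l(lambda) + noise`, with compartment
#' populations `c_l` from [concentration_profiles()] (sequential scheme,
#' Gaussian IRF) and component spectra `S_l` from the preset's band catalog.
#'
#' @param preset A [make_preset()] object.
#' @param times Delay grid (ps), default [default_ta_times()]; may be
#'   non-uniform.
#' @param wavelengths Probe grid (nm), ascending; default
#'   [default_ta_wavelengths()].
#' @param irf An [irf_gaussian()] in ps (default 0.1 ps FWHM at t0 = 0).
#' @param noise A [noise_model()].
#' @param scheme_override Optional [kinetic_scheme()] replacing the preset's
#'   ground-truth scheme (must have the same number of compartments).
#' @return A [ta_surface()] with metadata recording sample, state,
#'   excitation and seed.
#' @export
#' @examples
#' surf <- simulate_ta(make_preset("gel", "quenched", 674),
#'                     noise = noise_model(ta_sigma = 0))
simulate_ta <- function(preset,
                        times = default_ta_times(),
                        wavelengths = default_ta_wavelengths(),
                        irf = irf_gaussian(0, 0.1),
                        noise = noise_model(),
                        scheme_override = NULL) {
  stopifnot(inherits(preset, "sample_preset"))
  assert_increasing(times, "times")
  assert_increasing(wavelengths, "wavelengths")
  scheme <- if (is.null(scheme_override)) scheme_from_preset(preset) else scheme_override
  if (!inherits(scheme, "kinetic_scheme")) {
    stop_quenchkin("`scheme_override` must be a kinetic_scheme.")
  }
  spectra <- preset_spectra(preset, wavelengths)
  if (n_compartments(scheme) != nrow(spectra$amplitudes)) {
    stop_quenchkin("`scheme_override` must keep the preset's compartment count.")
  }
  conc <- concentration_profiles(scheme, irf, times)
  clean <- conc %*% spectra$amplitudes
  sigma <- resolve_ta_sigma(noise, clean)
  data <- if (sigma > 0) {
    with_seed(noise$seed,
              clean + matrix(stats::rnorm(length(clean), sd = sigma),
                             nrow = nrow(clean)))
  } else {
    clean
  }
  ta_surface(
    times, wavelengths, data,
    metadata = list(
      sample = preset$matrix, state = preset$state,
      excitation_nm = preset$excitation_nm,
      intensity = NA_real_, seed = noise$seed, ta_sigma = sigma
    )
  )
}

# Right-hand side of the annihilation-extended cascade: a bimolecular loss
# term -(gamma I / 2) n1^2 acts on the initially excited compartment.
annihilation_rhs <- function(t, y, parms) {
  k <- parms$k
  L <- length(k)
  g <- if (parms$sigma > 0) {
    stats::dnorm(t, mean = parms$t0, sd = parms$sigma)
  } else {
    0
  }
  dy <- numeric(L + 1L)
  dy[1] <- g - k[1] * y[1] - 0.5 * parms$gammaI * y[1]^2
  if (L > 1L) {
    dy[2:L] <- k[1:(L - 1L)] * y[1:(L - 1L)] - k[2:L] * y[2:L]
  }
  dy[L + 1L] <- parms$branch * k[L] * y[L]
  list(dy)
}

ode_profiles <- function(scheme, irf, times, gammaI) {
  k <- 1 / scheme$lifetimes_ps
  L <- length(k)
  parms <- list(k = k, gammaI = gammaI, t0 = irf$t0, sigma = irf$sigma,
                branch = scheme$branch_fraction)
  start <- if (irf$sigma > 0) irf$t0 - 8 * irf$sigma else irf$t0
  y0 <- if (irf$sigma > 0) rep(0, L + 1L) else c(1, rep(0, L))
  active <- times > start
  grid <- c(start, times[active])
  sol <- deSolve::lsoda(y0, grid, annihilation_rhs, parms,
                        rtol = 1e-10, atol = 1e-12)
  out <- matrix(0, nrow = length(times), ncol = L + 1L)
  out[active, ] <- as.matrix(sol[-1, -1, drop = FALSE])
  if (!scheme$nondecaying_terminal) out <- out[, seq_len(L), drop = FALSE]
  out
}

#' Simulate an excitation-intensity series with optional annihilation
#'
#' Repeats [simulate_ta()] at several excitation intensities, adding a
#' bimolecular singlet-singlet annihilation loss `-(gamma I / 2) n^2` to the
#' initially excited compartment and integrating the resulting nonlinear
#' cascade numerically (stiff-capable `lsoda`). `gamma` is the preset's
#' `annihilation_gamma`; when `gamma * I = 0` the analytic linear path of
#' [simulate_ta()] is used (the two agree to better than 0.1% in the linear
#' limit).
#'
#' @inheritParams simulate_ta
#' @param intensities Strictly positive, ascending excitation intensities
#'   (arbitrary excitation-fraction units).
#' @param force_ode Integrate numerically even when the annihilation term
#'   vanishes (used to validate the integrator against the analytic path).
#' @return A list of [ta_surface()] objects, one per intensity, with
#'   `intensity` recorded in the metadata.
#' @export
simulate_ta_intensity_series <- function(preset, intensities,
                                         times = default_ta_times(),
                                         wavelengths = default_ta_wavelengths(),
                                         irf = irf_gaussian(0, 0.1),
                                         noise = noise_model(),
                                         force_ode = FALSE) {
  stopifnot(inherits(preset, "sample_preset"))
  if (!is.numeric(intensities) || length(intensities) < 1L ||
      any(intensities <= 0)) {
    stop_quenchkin("`intensities` must be strictly positive.")
  }
  if (is.unsorted(intensities, strictly = TRUE) && length(intensities) > 1L) {
    stop_quenchkin("`intensities` must be ascending.")
  }
  scheme <- scheme_from_preset(preset)
  spectra <- preset_spectra(preset, wavelengths)
  purrr::imap(as.list(intensities), function(int, i) {
    gammaI <- preset$annihilation_gamma * int
    if (gammaI == 0 && !force_ode) {
      sub_noise <- noise_model(
        ta_sigma = noise$ta_sigma, tcspc_total_counts = noise$tcspc_total_counts,
        seed = if (is.null(noise$seed)) NULL else noise$seed + i - 1L
      )
      surf <- simulate_ta(preset, times, wavelengths, irf, sub_noise)
      surf$metadata$intensity <- int
      return(surf)
    }
    conc <- ode_profiles(scheme, irf, times, gammaI)
    clean <- conc %*% spectra$amplitudes
    sigma <- resolve_ta_sigma(noise, clean)
    seed_i <- if (is.null(noise$seed)) NULL else noise$seed + i - 1L
    data <- if (sigma > 0) {
      with_seed(seed_i,
                clean + matrix(stats::rnorm(length(clean), sd = sigma),
                               nrow = nrow(clean)))
    } else {
      clean
    }
    ta_surface(
      times, wavelengths, data,
      metadata = list(
        sample = preset$matrix, state = preset$state,
        excitation_nm = preset$excitation_nm,
        intensity = int, seed = seed_i, ta_sigma = sigma
      )
    )
  })
}

#' Simulate a TCSPC fluorescence decay histogram
#'
#' Per-channel photon counts are independent Poisson draws around the
#' IRF-reconvolved multi-exponential decay scaled to `total_counts` expected
#' photons over the window.
#'
#' @param lifetimes_ns Strictly positive component lifetimes (ns).
#' @param fractional_amplitudes Non-negative amplitudes, one per component.
#'   Renormalized internally to sum to 1 (published amplitude tables often
#'   sum to slightly more than 1 through rounding).
#' @param irf An [irf_gaussian()] in ns (default 0.5 ns FWHM centered at
#'   2 ns).
#' @param total_counts Expected total photon count.
#' @param channels Number of histogram channels (must be at least 3 per
#'   component).
#' @param window_ns Histogram time window (ns).
#' @param seed Integer seed for the Poisson draws; identical seeds give
#'   bit-identical histograms.
#' @return A [fluor_decay()].
#' @export
#' @examples
#' d <- simulate_tcspc(c(0.23, 1.19, 3.3), c(0.18, 0.32, 0.5),
#'                     total_counts = 1e5, seed = 1)
simulate_tcspc <- function(lifetimes_ns, fractional_amplitudes,
                           irf = irf_gaussian(2, 0.5),
                           total_counts = 1e6,
                           channels = 4096,
                           window_ns = 50,
                           seed = NULL) {
  if (any(lifetimes_ns <= 0)) {
    stop_quenchkin("All lifetimes must be strictly positive.")
  }
  if (length(fractional_amplitudes) != length(lifetimes_ns)) {
    stop_quenchkin("One amplitude per lifetime is required.")
  }
  if (any(fractional_amplitudes < 0) || sum(fractional_amplitudes) <= 0) {
    stop_quenchkin("Amplitudes must be non-negative with a positive sum.")
  }
  if (channels < 3L * length(lifetimes_ns)) {
    stop_quenchkin("At least 3 channels per component are required.")
  }
  assert_scalar_number(total_counts, "total_counts", positive = TRUE)
  amps <- fractional_amplitudes / sum(fractional_amplitudes)
  t <- (seq_len(channels) - 0.5) * window_ns / channels
  model <- numeric(channels)
  for (j in seq_along(lifetimes_ns)) {
    model <- model + amps[j] * exp_conv_gauss(1 / lifetimes_ns[j], t,
                                              t0 = irf$t0, sigma = irf$sigma)
  }
  expected <- total_counts * model / sum(model)
  counts <- with_seed(seed, stats::rpois(channels, expected))
  fluor_decay(
    t, counts,
    metadata = list(
      lifetimes_ns = lifetimes_ns, amplitudes = amps,
      irf = irf, total_counts = total_counts, seed = seed
    )
  )
}
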