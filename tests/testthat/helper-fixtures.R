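# Small fixtures built in code, shared across test files.

# A two-compartment toy surface with known Gaussian component spectra.
toy_two_comp <- function(lifetimes = c(5, 100), times = seq(-1, 400, length.out = 60),
                         wavelengths = seq(500, 700, by = 5),
                         irf = irf_gaussian(0, 0.1), sigma = 0, seed = NULL) {
  scheme <- kinetic_scheme(lifetimes)
  spectra <- rbind(
    gaussian_band_t(wavelengths, 560, 15, 1),
    gaussian_band_t(wavelengths, 640, 20, -0.8)
  )
  conc <- concentration_profiles(scheme, irf, times)
  clean <- conc %*% spectra
  data <- clean
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- clean + matrix(rnorm(length(clean), sd = sigma), nrow = nrow(clean))
  }
  list(
    surface = ta_surface(times, wavelengths, data),
    scheme = scheme, spectra = spectra, irf = irf, clean = clean
  )
}

gaussian_band_t <- function(l, c0, s, a) a * exp(-(l - c0)^2 / (2 * s^2))

# Noise-free single-exponential decay histogram (counts = rounded expectation).
toy_single_decay <- function(tau = 3, t0 = 2, fwhm = 0.5, total = 1e6,
                             channels = 1024, window = 30) {
  t <- (seq_len(channels) - 0.5) * window / channels
  m <- exp_conv_gauss(1 / tau, t, t0 = t0, sigma = fwhm / 2.3548)
  expected <- total * m / sum(m)
  fluor_decay(t, round(expected),
              metadata = list(irf = irf_gaussian(t0, fwhm)))
}
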