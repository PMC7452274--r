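# Closed-form sequential compartmental kinetics convolved with a Gaussian
# instrument response.

#' Exponential decay convolved with a Gaussian IRF
#'
#' The textbook building block of reconvolution analysis: the convolution of
#' a one-sided exponential `exp(-k (t - t0))` with a normalized Gaussian of
#' standard deviation `sigma` centered at `t0`,
#' \deqn{c(t) = \tfrac12 \exp(k(t_0 - t) + k^2\sigma^2/2)\,
#'       \mathrm{erfc}\!\left(\frac{t_0 + k\sigma^2 - t}{\sigma\sqrt2}\right).}
#' Evaluated through the scaled complementary error function
#' (`pracma::erfcx`) so that it stays finite at long delays where the naive
#' product would overflow. `sigma = 0` returns the pure exponential
#' (delta-IRF limit).
#'
#' @param k Decay rate (inverse time units of `times`).
#' @param times Numeric vector of delays.
#' @param t0 IRF center.
#' @param sigma IRF standard deviation (`fwhm / 2.3548`).
#' @return Numeric vector, same length as `times`.
#' @export
exp_conv_gauss <- function(k, times, t0 = 0, sigma = 0) {
  assert_scalar_number(k, "k", positive = TRUE)
  if (sigma < 0) stop_quenchkin("`sigma` must be non-negative.")
  if (sigma == 0) {
    out <- ifelse(times >= t0, exp(-k * (times - t0)), 0)
    return(out)
  }
  x <- (t0 + k * sigma^2 - times) / (sigma * sqrt(2))
  out <- numeric(length(times))
  # erfcx(x) overflows for strongly negative x; there erfc ~= 2 to machine
  # precision and the plain product is itself safe (the exponent is large
  # and negative at those delays).
  far <- x < -6
  if (any(far)) {
    out[far] <- exp(k * (t0 - times[far]) + k^2 * sigma^2 / 2)
  }
  if (any(!far)) {
    out[!far] <- 0.5 * exp(-((times[!far] - t0)^2) / (2 * sigma^2)) *
      pracma::erfcx(x[!far])
  }
  out
}

# Cumulative Gaussian IRF: the response of a non-decaying species.
step_conv_gauss <- function(times, t0 = 0, sigma = 0) {
  if (sigma == 0) return(as.numeric(times >= t0))
  stats::pnorm(times, mean = t0, sd = sigma)
}

#' Bateman coefficients of a sequential cascade
#'
#' Coefficient matrix `b` of the unbranched cascade
#' `1 -> 2 -> ... -> L` with distinct rates `k_j`: the population of
#' compartment `l` is \eqn{c_l(t) = \sum_{j \le l} b_{jl} e^{-k_j t}} with
#' \deqn{b_{jl} = \frac{\prod_{m<l} k_m}{\prod_{m \le l, m \ne j} (k_m - k_j)}.}
#'
#' @param rates Strictly positive, pairwise distinct decay rates, ordered by
#'   compartment (rate of compartment 1 first).
#' @return An `L x L` lower-triangular-by-column matrix `b` with `b[j, l]`
#'   the coefficient of `exp(-k_j t)` in compartment `l`.
#' @export
#' @examples
#' sequential_amplitudes(1)            # single compartment: b = 1
#' sequential_amplitudes(c(1, 0.5))    # classic two-step cascade
sequential_amplitudes <- function(rates) {
  if (!is.numeric(rates) || length(rates) < 1L || any(rates <= 0)) {
    stop_quenchkin("`rates` must be strictly positive.")
  }
  check_degenerate_rates(rates)
  L <- length(rates)
  b <- matrix(0, nrow = L, ncol = L)
  for (l in seq_len(L)) {
    pref <- if (l == 1L) 1 else prod(rates[seq_len(l - 1L)])
    for (j in seq_len(l)) {
      denom <- prod(rates[setdiff(seq_len(l), j)] - rates[j])
      b[j, l] <- pref / denom
    }
  }
  b
}

#' Concentration profiles of a sequential scheme under a Gaussian IRF
#'
#' Populations of every compartment of a [kinetic_scheme()] as a function of
#' pump-probe delay, computed in closed form as Bateman combinations of
#' Gaussian-convolved exponentials. The initial excitation (unit area) is
#' deposited entirely in compartment 1; in the delta-IRF limit compartment 1
#' therefore integrates to `1/k1`. A non-decaying terminal compartment, fed
#' from the last decaying compartment with the scheme's branch fraction,
#' rises to a plateau equal to that fraction.
#'
#' Negative delays are valid and show only the IRF-broadened rise.
#'
#' @param scheme A [kinetic_scheme()].
#' @param irf An [irf_gaussian()] (times in the same units as `times`).
#' @param times Numeric vector of delays (need not be uniform).
#' @return Numeric matrix, `length(times)` rows, one column per compartment
#'   (terminal compartment last when present).
#' @export
#' @examples
#' sch <- kinetic_scheme(c(2.2, 19, 240))
#' c_t <- concentration_profiles(sch, irf_gaussian(0, 0.1), seq(-1, 50, 0.5))
concentration_profiles <- function(scheme, irf, times) {
  if (!inherits(scheme, "kinetic_scheme")) {
    stop_quenchkin("`scheme` must be a kinetic_scheme.")
  }
  if (!inherits(irf, "irf_gaussian")) {
    stop_quenchkin("`irf` must be an irf_gaussian.")
  }
  if (!is.numeric(times) || length(times) < 1L) {
    stop_quenchkin("`times` must be numeric.")
  }
  rates <- 1 / scheme$lifetimes_ps
  L <- length(rates)
  b <- sequential_amplitudes(rates)
  E <- vapply(rates, exp_conv_gauss, numeric(length(times)),
              times = times, t0 = irf$t0, sigma = irf$sigma)
  E <- matrix(E, nrow = length(times))
  out <- E %*% b
  if (scheme$nondecaying_terminal) {
    # dT/dt = phi * k_L * c_L(t); integrate each convolved exponential:
    # int_-inf^t conv(k) = (H(t) - conv(k, t)) / k with H the cumulative IRF.
    H <- step_conv_gauss(times, irf$t0, irf$sigma)
    terminal <- numeric(length(times))
    for (j in seq_len(L)) {
      terminal <- terminal + b[j, L] * (H - E[, j]) / rates[j]
    }
    terminal <- scheme$branch_fraction * rates[L] * terminal
    out <- cbind(out, terminal)
  }
  colnames(out) <- NULL
  out
}

#' Convert between evolution- and decay-associated spectra
#'
#' For a sequential scheme the evolution-associated difference spectra
#' (EADS, one spectrum per compartment) and the decay-associated difference
#' spectra (DADS, one spectrum per exponential basis function) are exact
#' linear transforms of each other through the Bateman coefficient matrix:
#' `DADS = B %*% EADS` and `EADS = solve(B, DADS)`. The reconstructed signal
#' `sum_l c_l(t) EADS_l(lambda)` is identical to
#' `sum_j conv(k_j, t) DADS_j(lambda)` for all `(t, lambda)`.
#'
#' When the scheme carries a non-decaying terminal compartment its spectrum
#' is not part of the exponential basis; the terminal row is passed through
#' unchanged and only the decaying block is transformed.
#'
#' @param spectra A [component_spectra()] whose representation matches the
#'   source of `direction` (`"raw"` is accepted as EADS-like ground truth
#'   for the forward direction).
#' @param scheme The owning [kinetic_scheme()].
#' @param direction `"eads_to_dads"` or `"dads_to_eads"`.
#' @return A [component_spectra()] in the target representation.
#' @export
eads_dads_convert <- function(spectra, scheme,
                              direction = c("eads_to_dads", "dads_to_eads")) {
  direction <- match.arg(direction)
  if (!inherits(spectra, "component_spectra")) {
    stop_quenchkin("`spectra` must be a component_spectra.")
  }
  if (!inherits(scheme, "kinetic_scheme")) {
    stop_quenchkin("`scheme` must be a kinetic_scheme.")
  }
  expected <- if (direction == "eads_to_dads") c("EADS", "raw") else "DADS"
  if (!spectra$representation %in% expected) {
    stop_quenchkin(sprintf(
      "Representation tag \"%s\" does not match direction \"%s\" (expected %s).",
      spectra$representation, direction,
      paste(expected, collapse = " or ")
    ))
  }
  if (nrow(spectra$amplitudes) != n_compartments(scheme)) {
    stop_quenchkin("One spectrum per scheme compartment is required.")
  }
  L <- length(scheme$lifetimes_ps)
  b <- sequential_amplitudes(1 / scheme$lifetimes_ps)
  block <- spectra$amplitudes[seq_len(L), , drop = FALSE]
  converted <- if (direction == "eads_to_dads") {
    b %*% block
  } else {
    solve(b, block)
  }
  amplitudes <- spectra$amplitudes
  amplitudes[seq_len(L), ] <- converted
  component_spectra(
    spectra$wavelengths_nm, amplitudes,
    representation = if (direction == "eads_to_dads") "DADS" else "EADS"
  )
}
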