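#' Sequential kinetic scheme
#'
#' A sequential (unbranched cascade) compartmental scheme: compartment 1 is
#' populated by the pump pulse and each compartment feeds the next, with
#' 1/e lifetimes `lifetimes_ps`. An optional non-decaying terminal
#' compartment represents a (carotenoid) triplet that is fed from the last
#' singlet compartment with branching fraction `branch_fraction` and does not
#' decay on the experimental time window.
#'
#' @param lifetimes_ps Numeric vector of strictly positive, strictly
#'   ascending lifetimes in picoseconds. No two lifetimes may coincide
#'   within a relative 1e-9 (degenerate cascades are rejected, see Details).
#' @param status Character vector, one of `"free"`, `"fixed"`, `"shared"`
#'   per lifetime (recycled if length one). Free and shared lifetimes are
#'   optimized by [fit_global()]; fixed lifetimes are never perturbed.
#' @param nondecaying_terminal Logical; append a non-decaying terminal
#'   compartment fed by the last decaying compartment.
#' @param branch_fraction Fraction (0..1) of the population flux leaving the
#'   last decaying compartment that is routed into the terminal compartment.
#'   Only meaningful when `nondecaying_terminal` is `TRUE`.
#'
#' @details Equal rates would require `t * exp(-k t)` secular terms in the
#' cascade solution; such schemes are rejected here and the global fitter
#' perturbs colliding lifetimes by a relative 1e-6 (with a warning) to keep
#' the problem well-posed. The lifetimes of interest in antenna-complex work
#' are well separated, so nothing is lost in practice.
#'
#' @return An object of class `kinetic_scheme`.
#' @seealso [concentration_profiles()], [fit_global()]
#' @export
#' @examples
#' kinetic_scheme(c(2.2, 19, 240, 2900),
#'                status = c("free", "free", "free", "fixed"),
#'                nondecaying_terminal = TRUE, branch_fraction = 0.3)
kinetic_scheme <- function(lifetimes_ps,
                           status = "free",
                           nondecaying_terminal = FALSE,
                           branch_fraction = 1) {
  if (!is.numeric(lifetimes_ps) || length(lifetimes_ps) < 1L) {
    stop_quenchkin("`lifetimes_ps` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(lifetimes_ps)) || any(lifetimes_ps <= 0)) {
    stop_quenchkin("All lifetimes must be finite and strictly positive.")
  }
  if (is.unsorted(lifetimes_ps, strictly = TRUE)) {
    stop_quenchkin("Lifetimes must be strictly ascending.")
  }
  check_degenerate_rates(1 / lifetimes_ps)
  status <- rep_len(as.character(status), length(lifetimes_ps))
  bad <- setdiff(status, c("free", "fixed", "shared"))
  if (length(bad) > 0L) {
    stop_quenchkin("`status` entries must be one of \"free\", \"fixed\", \"shared\".")
  }
  if (!is.logical(nondecaying_terminal) || length(nondecaying_terminal) != 1L) {
    stop_quenchkin("`nondecaying_terminal` must be a single logical.")
  }
  assert_scalar_number(branch_fraction, "branch_fraction")
  if (branch_fraction < 0 || branch_fraction > 1) {
    stop_quenchkin("`branch_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      lifetimes_ps = as.numeric(lifetimes_ps),
      status = status,
      nondecaying_terminal = isTRUE(nondecaying_terminal),
      branch_fraction = branch_fraction
    ),
    class = "kinetic_scheme"
  )
}

# Error on rates closer than a relative 1e-9; the Bateman coefficients
# diverge there.
check_degenerate_rates <- function(rates, tol = 1e-9) {
  if (length(rates) < 2L) return(invisible(rates))
  s <- sort(rates)
  gap <- diff(s) / pmax(abs(s[-length(s)]), .Machine$double.xmin)
  if (any(gap < tol)) {
    stop_quenchkin(
      "Degenerate kinetic scheme: two rate constants coincide within a ",
      "relative 1e-9. Sequential cascade amplitudes are undefined for ",
      "equal rates; perturb one lifetime."
    )
  }
  invisible(rates)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> sequential,", length(x$lifetimes_ps), "decaying compartment(s)\n")
  cat("  lifetimes (ps):", paste(signif(x$lifetimes_ps, 6), collapse = ", "), "\n")
  cat("  status:        ", paste(x$status, collapse = ", "), "\n")
  if (x$nondecaying_terminal) {
    cat("  + non-decaying terminal, branch fraction", x$branch_fraction, "\n")
  }
  invisible(x)
}

n_compartments <- function(scheme) {
  length(scheme$lifetimes_ps) + as.integer(scheme$nondecaying_terminal)
}

#' Gaussian instrument response function
#'
#' @param t0 Center of the IRF, in the units of the time axis it will be
#'   applied to (picoseconds for transient absorption, nanoseconds for
#'   TCSPC).
#' @param fwhm Full width at half maximum, same units as `t0`. Must be
#'   non-negative; `fwhm = 0` denotes the delta-function limit (no
#'   broadening), which is the analytic reference for the convolution code.
#'
#' @return An object of class `irf_gaussian` with fields `t0`, `fwhm` and
#'   the derived standard deviation `sigma`.
#' @export
#' @examples
#' irf_gaussian(0, 0.1)   # ~100 fs pump-probe response
#' irf_gaussian(2, 0.5)   # 0.5 ns TCSPC response centered at 2 ns
irf_gaussian <- function(t0 = 0, fwhm = 0.1) {
  assert_scalar_number(t0, "t0")
  assert_scalar_number(fwhm, "fwhm")
  if (fwhm < 0) {
    stop_quenchkin("`fwhm` must be non-negative (0 selects the delta-IRF limit).")
  }
  structure(
    list(t0 = t0, fwhm = fwhm, sigma = fwhm / (2 * sqrt(2 * log(2)))),
    class = "irf_gaussian"
  )
}

#' @export
print.irf_gaussian <- function(x, ...) {
  cat("<irf_gaussian> t0 =", x$t0, ", fwhm =", x$fwhm, "\n")
  invisible(x)
}

#' Per-compartment component spectra
#'
#' Container for the spectra associated with the compartments of a kinetic
#' scheme: either evolution-associated (EADS, sequential-scheme reading),
#' decay-associated (DADS, exponential-basis reading) or raw simulation
#' ground truth.
#'
#' @param wavelengths_nm Ascending wavelength grid.
#' @param amplitudes Numeric matrix, one row per compartment, one column per
#'   wavelength.
#' @param representation One of `"EADS"`, `"DADS"`, `"raw"`.
#'
#' @return An object of class `component_spectra`.
#' @export
component_spectra <- function(wavelengths_nm, amplitudes,
                              representation = c("raw", "EADS", "DADS")) {
  representation <- match.arg(representation)
  assert_increasing(wavelengths_nm, "wavelengths_nm")
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != length(wavelengths_nm)) {
    stop_quenchkin("`amplitudes` must have one column per wavelength.")
  }
  structure(
    list(
      wavelengths_nm = as.numeric(wavelengths_nm),
      amplitudes = amplitudes,
      representation = representation
    ),
    class = "component_spectra"
  )
}

#' @export
print.component_spectra <- function(x, ...) {
  cat("<component_spectra>", x$representation, ":", nrow(x$amplitudes),
      "component(s) x", length(x$wavelengths_nm), "wavelengths\n")
  invisible(x)
}

#' @rdname component_spectra
#' @param x A `component_spectra` object.
#' @param ... Unused.
#' @method as_tibble component_spectra
#' @export
as_tibble.component_spectra <- function(x, ...) {
  n <- nrow(x$amplitudes)
  labels <- rownames(x$amplitudes)
  if (is.null(labels)) labels <- paste0("component_", seq_len(n))
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      component = labels[i],
      wavelength_nm = x$wavelengths_nm,
      amplitude = x$amplitudes[i, ],
      representation = x$representation
    )
  })
}
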