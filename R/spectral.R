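# Quantifications of spectra and kinetic traces: trace extraction, band
# ratios, difference spectra, interpolated peak finding, vibronic gaps, and
# the intensity-dependence (annihilation) diagnostic.

#' Extract a kinetic trace at a probe wavelength
#'
#' Selects the surface column nearest to the requested wavelength (no
#' interpolation across wavelength; the column actually used is recorded).
#' Optionally inverts the sign ("reverted" kinetics, so that a bleach decay
#' can be overlaid on an excited-state absorption decay) and normalizes to
#' unit extreme value.
#'
#' @param surface A [ta_surface()].
#' @param wavelength_nm Probe wavelength; must lie within the grid span.
#' @param invert Multiply the trace by -1 before normalization.
#' @param normalize Scale so that the extreme value is +-1. An all-zero
#'   trace cannot be normalized and raises an error.
#' @return A tibble with columns `time_ps`, `value`, plus attributes
#'   `wavelength_nm` (the grid column used) and `normalization` (one of
#'   `"raw"`, `"normalized"`, `"normalized-and-inverted"`, `"inverted"`).
#' @export
extract_trace <- function(surface, wavelength_nm, invert = FALSE,
                          normalize = FALSE) {
  stopifnot(inherits(surface, "ta_surface"))
  assert_scalar_number(wavelength_nm, "wavelength_nm")
  rng <- range(surface$wavelengths_nm)
  if (wavelength_nm < rng[1] || wavelength_nm > rng[2]) {
    stop_quenchkin(sprintf(
      "wavelength %.4g nm lies outside the grid span [%.4g, %.4g].",
      wavelength_nm, rng[1], rng[2]))
  }
  j <- nearest_index(surface$wavelengths_nm, wavelength_nm)
  v <- surface$data[, j]
  if (invert) v <- -v
  if (normalize) {
    m <- max(abs(v))
    if (m == 0) stop_quenchkin("Cannot normalize an all-zero trace.")
    v <- v / m
  }
  out <- tibble::tibble(time_ps = surface$times_ps, value = v)
  attr(out, "wavelength_nm") <- surface$wavelengths_nm[j]
  attr(out, "normalization") <- if (normalize && invert) {
    "normalized-and-inverted"
  } else if (normalize) {
    "normalized"
  } else if (invert) {
    "inverted"
  } else {
    "raw"
  }
  out
}

# Parabolic refinement of an extremum at interior grid index i; returns the
# vertex (x, y). Falls back to the grid point at window edges.
quad_vertex <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(c(x[i], y[i]))
  xs <- x[(i - 1):(i + 1)]
  ys <- y[(i - 1):(i + 1)]
  d1 <- (ys[3] - ys[1]) / (xs[3] - xs[1])
  d2 <- ((ys[3] - ys[2]) / (xs[3] - xs[2]) - (ys[2] - ys[1]) / (xs[2] - xs[1])) /
    ((xs[3] - xs[1]) / 2)
  if (d2 == 0) return(c(xs[2], ys[2]))
  xv <- min(max(xs[2] - d1 / d2, xs[1]), xs[3])
  c(xv, ys[2] + d1 * (xv - xs[2]) + 0.5 * d2 * (xv - xs[2])^2)
}

window_indices <- function(wavelengths, window, name) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_quenchkin(sprintf("`%s` must be c(lo, hi) with lo < hi.", name))
  }
  idx <- which(wavelengths >= window[1] & wavelengths <= window[2])
  if (length(idx) == 0L) {
    stop_quenchkin(sprintf("`%s` [%g, %g] contains no grid points.",
                           name, window[1], window[2]))
  }
  idx
}

#' Ratio of a band extremum to a reference extremum
#'
#' Locates the largest-magnitude value inside each of two disjoint
#' wavelength windows and reports the unsigned amplitude ratio
#' band / reference, e.g. the 515-nm excited-state absorption relative to
#' the Q_y bleach at 684 nm. Invariant under positive rescaling of the
#' spectrum.
#'
#' @param spectrum A tibble with columns `wavelength_nm` and `value` (as
#'   returned by [spectrum_at()] or [absorption_preset()]).
#' @param band_window_nm,reference_window_nm Wavelength windows `c(lo, hi)`;
#'   must be non-empty and disjoint.
#' @return A one-row tibble: `band_peak_nm`, `band_amplitude`,
#'   `reference_peak_nm`, `reference_amplitude`, `ratio` (unsigned).
#' @export
band_ratio <- function(spectrum, band_window_nm, reference_window_nm) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength_nm", "value") %in% names(spectrum)))
  wl <- spectrum$wavelength_nm
  v <- spectrum$value
  bi <- window_indices(wl, band_window_nm, "band_window_nm")
  ri <- window_indices(wl, reference_window_nm, "reference_window_nm")
  if (max(band_window_nm[1], reference_window_nm[1]) <=
      min(band_window_nm[2], reference_window_nm[2])) {
    stop_quenchkin("Band and reference windows must be disjoint.")
  }
  bx <- bi[which.max(abs(v[bi]))]
  rx <- ri[which.max(abs(v[ri]))]
  if (abs(v[rx]) == 0) stop_quenchkin("Reference extremum is zero.")
  # Parabolic refinement so the amplitudes do not depend on whether a band
  # center happens to fall on a grid point.
  bv <- quad_vertex(wl, v, bx)
  rv <- quad_vertex(wl, v, rx)
  tibble::tibble(
    band_peak_nm = bv[1],
    band_amplitude = bv[2],
    reference_peak_nm = rv[1],
    reference_amplitude = rv[2],
    ratio = abs(bv[2]) / abs(rv[2])
  )
}

#' Pointwise difference of two spectra
#'
#' @param a,b Spectrum tibbles (`wavelength_nm`, `value`) on identical
#'   wavelength grids.
#' @return A spectrum tibble `a - b`.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (!isTRUE(all.equal(a$wavelength_nm, b$wavelength_nm))) {
    stop_quenchkin("Spectra must share an identical wavelength grid.")
  }
  tibble::tibble(wavelength_nm = a$wavelength_nm, value = a$value - b$value)
}

#' Locate spectral extrema with quadratic interpolation
#'
#' Finds interior local maxima and minima of a spectrum inside a window and
#' refines each position by fitting a parabola through the extremal grid
#' point and its two neighbors. Extrema smaller in magnitude than
#' `threshold` are dropped; the default threshold is 3x the noise level
#' estimated from the median absolute successive difference (so an all-zero
#' or pure-noise spectrum returns no extrema).
#'
#' @param spectrum A spectrum tibble (`wavelength_nm`, `value`).
#' @param window Wavelength window `c(lo, hi)` to search.
#' @param threshold Minimum absolute amplitude for a reported extremum;
#'   `NULL` for the 3x-MAD default.
#' @return A tibble with columns `wavelength_nm` (interpolated),
#'   `value` (interpolated) and `type` (`"max"` or `"min"`), ordered by
#'   wavelength. Zero rows when nothing exceeds the threshold.
#' @export
peak_positions <- function(spectrum, window = NULL, threshold = NULL) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength_nm", "value") %in% names(spectrum)))
  wl <- spectrum$wavelength_nm
  v <- spectrum$value
  if (!is.null(window)) {
    idx <- window_indices(wl, window, "window")
    wl <- wl[idx]; v <- v[idx]
  }
  if (length(v) < 3L) stop_quenchkin("Need at least 3 points in the window.")
  if (is.null(threshold)) {
    noise <- stats::mad(diff(v)) / sqrt(2)
    threshold <- 3 * noise
  }
  rows <- list()
  for (i in 2:(length(v) - 1L)) {
    is_max <- v[i] >= v[i - 1] && v[i] >= v[i + 1] && (v[i] > v[i - 1] || v[i] > v[i + 1])
    is_min <- v[i] <= v[i - 1] && v[i] <= v[i + 1] && (v[i] < v[i - 1] || v[i] < v[i + 1])
    if (!is_max && !is_min) next
    if (abs(v[i]) < threshold) next
    vert <- quad_vertex(wl, v, i)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      wavelength_nm = vert[1], value = vert[2],
      type = if (is_max) "max" else "min"
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(wavelength_nm = numeric(), value = numeric(),
                          type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$wavelength_nm)
}

#' Wavenumber gap between two wavelengths
#'
#' `1e7 * |1/lambda1 - 1/lambda2|` with wavelengths in nm, e.g. the gap
#' between the 0-0 and 0-1 vibronic bands of a carotenoid.
#'
#' @param lambda1_nm,lambda2_nm Wavelengths in nm, strictly positive.
#' @return The energy gap in reciprocal centimeters.
#' @export
#' @examples
#' vibronic_gap_cm(460, 490)  # ~1331 cm^-1
vibronic_gap_cm <- function(lambda1_nm, lambda2_nm) {
  assert_scalar_number(lambda1_nm, "lambda1_nm", positive = TRUE)
  assert_scalar_number(lambda2_nm, "lambda2_nm", positive = TRUE)
  1e7 * abs(1 / lambda1_nm - 1 / lambda2_nm)
}

#' Intensity-dependence (annihilation) diagnostic
#'
#' Given normalized kinetic traces of the same probe wavelength measured at
#' different excitation intensities, reports the maximum over time of the
#' spread (max minus min) across traces. An intensity-independent decay
#' gives 0; singlet-singlet annihilation makes high-intensity decays faster
#' and the spread positive.
#'
#' @param traces A list of at least two normalized trace tibbles (from
#'   [extract_trace()] with `normalize = TRUE`) on a common time grid.
#' @return A single non-negative number.
#' @export
annihilation_diagnostic <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L) {
    stop_quenchkin("At least two traces are required.")
  }
  t0 <- traces[[1]]$time_ps
  vals <- vapply(traces, function(tr) {
    stopifnot(is.data.frame(tr), all(c("time_ps", "value") %in% names(tr)))
    if (!isTRUE(all.equal(tr$time_ps, t0))) {
      stop_quenchkin("All traces must share a common time grid.")
    }
    if (max(abs(tr$value)) == 0 ||
        abs(max(abs(tr$value)) - 1) > 1e-6) {
      stop_quenchkin("Traces must be normalized (unit extreme value).")
    }
    tr$value
  }, numeric(length(t0)))
  max(apply(vals, 1L, function(row) diff(range(row))))
}

# Half-rise time of a normalized rising trace by linear interpolation.
half_rise_time <- function(times, values) {
  m <- max(abs(values))
  if (m == 0) stop_quenchkin("Trace is identically zero in the window.")
  v <- abs(values) / m
  imax <- which.max(v)
  if (imax == 1L) {
    stop_quenchkin("Trace does not rise within the window (maximum at the first point).")
  }
  below <- which(v[seq_len(imax)] < 0.5)
  if (length(below) == 0L) {
    stop_quenchkin("Trace never drops below half maximum before its peak; no rise to time.")
  }
  i <- max(below)
  # interpolate between i and i+1
  t1 <- times[i]; t2 <- times[i + 1L]
  v1 <- v[i]; v2 <- v[i + 1L]
  t1 + (0.5 - v1) / (v2 - v1) * (t2 - t1)
}

#' Compare rise times at two probe wavelengths
#'
#' Half-maximum times of the (magnitude-)normalized rising signal at two
#' probe wavelengths within an early-time window, e.g. to show that a
#' Chl-a bleach populated by Chl-b -> Chl-a transfer rises later than an
#' instantaneously appearing band.
#'
#' @param surface A [ta_surface()].
#' @param probe1_nm,probe2_nm Probe wavelengths (nearest-column selection).
#' @param window_ps Time window `c(lo, hi)` covering the rise.
#' @return A tibble with columns `probe_nm` and `t50_ps` (two rows, in the
#'   order given).
#' @export
rise_time_compare <- function(surface, probe1_nm, probe2_nm, window_ps) {
  stopifnot(inherits(surface, "ta_surface"))
  if (length(window_ps) != 2L || window_ps[1] >= window_ps[2]) {
    stop_quenchkin("`window_ps` must be c(lo, hi) with lo < hi.")
  }
  sel <- surface$times_ps >= window_ps[1] & surface$times_ps <= window_ps[2]
  if (sum(sel) < 3L) stop_quenchkin("Window covers fewer than 3 delays.")
  t50 <- vapply(c(probe1_nm, probe2_nm), function(p) {
    tr <- extract_trace(surface, p)
    half_rise_time(tr$time_ps[sel], tr$value[sel])
  }, numeric(1))
  tibble::tibble(probe_nm = c(probe1_nm, probe2_nm), t50_ps = t50)
}
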