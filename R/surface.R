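#' Time x wavelength transient-absorption surface
#'
#' The unit of pump-probe analysis: a matrix of difference absorbance
#' `dA(t, lambda)` (mOD) on a delay grid (ps) by wavelength grid (nm), plus
#' sample metadata. A logical `masked` flag per wavelength marks columns
#' excluded from fitting (see [apply_mask()]).
#'
#' @param times_ps Strictly increasing delay axis (ps); negative delays are
#'   valid and show the IRF-limited rise.
#' @param wavelengths_nm Strictly increasing wavelength axis (nm).
#' @param data Numeric matrix, `length(times_ps)` rows by
#'   `length(wavelengths_nm)` columns.
#' @param metadata Named list (sample, state, excitation_nm, intensity,
#'   seed, ...). Free-form; `excitation_nm` is written to disk by
#'   [write_surface()].
#' @param masked Logical vector per wavelength (default all `FALSE`).
#' @return An object of class `ta_surface`.
#' @export
ta_surface <- function(times_ps, wavelengths_nm, data, metadata = list(),
                       masked = NULL) {
  assert_increasing(times_ps, "times_ps")
  assert_increasing(wavelengths_nm, "wavelengths_nm")
  data <- as.matrix(data)
  if (nrow(data) != length(times_ps) || ncol(data) != length(wavelengths_nm)) {
    stop_quenchkin("`data` must be length(times_ps) x length(wavelengths_nm).")
  }
  if (is.null(masked)) masked <- rep(FALSE, length(wavelengths_nm))
  if (length(masked) != length(wavelengths_nm) || !is.logical(masked)) {
    stop_quenchkin("`masked` must be one logical per wavelength.")
  }
  structure(
    list(
      times_ps = as.numeric(times_ps),
      wavelengths_nm = as.numeric(wavelengths_nm),
      data = unname(data),
      metadata = metadata,
      masked = masked
    ),
    class = "ta_surface"
  )
}

#' @export
print.ta_surface <- function(x, ...) {
  cat("<ta_surface>", length(x$times_ps), "delays x",
      length(x$wavelengths_nm), "wavelengths")
  if (any(x$masked)) cat(" (", sum(x$masked), "masked)")
  cat("\n")
  md <- x$metadata[!vapply(x$metadata, is.null, logical(1))]
  if (length(md) > 0L) {
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = " = ",
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname ta_surface
#' @param x A `ta_surface`.
#' @param ... Unused.
#' @return `as_tibble()`: the surface in long form with columns `delay_ps`,
#'   `wavelength_nm`, `dA`, `masked`.
#' @method as_tibble ta_surface
#' @export
as_tibble.ta_surface <- function(x, ...) {
  tibble::tibble(
    delay_ps = rep(x$times_ps, times = length(x$wavelengths_nm)),
    wavelength_nm = rep(x$wavelengths_nm, each = length(x$times_ps)),
    dA = as.vector(x$data),
    masked = rep(x$masked, each = length(x$times_ps))
  )
}

#' Extract the transient spectrum nearest to a delay
#'
#' Selects the surface row whose delay is nearest to `delay_ps` (no
#' interpolation across time) and returns it as a spectrum tibble.
#'
#' @param surface A [ta_surface()].
#' @param delay_ps Requested delay (ps); must lie within the delay span.
#' @return A tibble with columns `wavelength_nm`, `value` and the attribute
#'   `delay_ps` recording the delay actually used.
#' @export
spectrum_at <- function(surface, delay_ps) {
  stopifnot(inherits(surface, "ta_surface"))
  assert_scalar_number(delay_ps, "delay_ps")
  rng <- range(surface$times_ps)
  if (delay_ps < rng[1] || delay_ps > rng[2]) {
    stop_quenchkin(sprintf("delay %.4g ps lies outside the delay span [%.4g, %.4g].",
                           delay_ps, rng[1], rng[2]))
  }
  i <- nearest_index(surface$times_ps, delay_ps)
  out <- tibble::tibble(
    wavelength_nm = surface$wavelengths_nm,
    value = surface$data[i, ]
  )
  attr(out, "delay_ps") <- surface$times_ps[i]
  out
}

#' @rdname ta_surface
#' @param object A `ta_surface`.
#' @method autoplot ta_surface
#' @export
autoplot.ta_surface <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$delay_ps,
                                   fill = .data$dA)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "wavelength (nm)", y = "delay (ps)",
                  fill = expression(Delta * A ~ "(mOD)"))
}

#' Photon-counting fluorescence decay histogram
#'
#' @param time_ns Strictly increasing channel times (ns).
#' @param counts Non-negative integer photon counts per channel.
#' @param irf_counts Optional measured IRF histogram on the same channels.
#' @param metadata Named list (excitation_nm, detection_nm, seed, ...).
#' @return An object of class `fluor_decay`.
#' @export
fluor_decay <- function(time_ns, counts, irf_counts = NULL, metadata = list()) {
  assert_increasing(time_ns, "time_ns")
  if (length(counts) != length(time_ns)) {
    stop_quenchkin("`counts` must match `time_ns` in length.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_quenchkin("`counts` must be non-negative integers.")
  }
  if (!is.null(irf_counts)) {
    if (length(irf_counts) != length(time_ns) || any(irf_counts < 0)) {
      stop_quenchkin("`irf_counts` must be non-negative and match `time_ns`.")
    }
  }
  structure(
    list(
      time_ns = as.numeric(time_ns),
      counts = as.numeric(round(counts)),
      irf_counts = if (is.null(irf_counts)) NULL else as.numeric(irf_counts),
      metadata = metadata
    ),
    class = "fluor_decay"
  )
}

#' @export
print.fluor_decay <- function(x, ...) {
  cat("<fluor_decay>", length(x$time_ns), "channels,",
      format(sum(x$counts), big.mark = ","), "photons\n")
  invisible(x)
}

#' @rdname fluor_decay
#' @param x A `fluor_decay`.
#' @param ... Unused.
#' @method as_tibble fluor_decay
#' @export
as_tibble.fluor_decay <- function(x, ...) {
  out <- tibble::tibble(time_ns = x$time_ns, counts = x$counts)
  if (!is.null(x$irf_counts)) out$irf_counts <- x$irf_counts
  out
}

#' @rdname fluor_decay
#' @param object A `fluor_decay`.
#' @method autoplot fluor_decay
#' @export
autoplot.fluor_decay <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts")
}
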