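# Internal helpers shared across modules.

# Evaluate a Gaussian band profile in wavelength. `width_nm` is the standard
# deviation of the band, not its FWHM.
gaussian_band <- function(wavelength_nm, center_nm, width_nm, amplitude) {
  amplitude * exp(-(wavelength_nm - center_nm)^2 / (2 * width_nm^2))
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Nearest grid index, used for documented nearest-column trace extraction.
nearest_index <- function(grid, value) {
  which.min(abs(grid - value))
}

stop_quenchkin <- function(...) {
  stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_quenchkin(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_quenchkin(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# Strictly increasing check with an informative error.
assert_increasing <- function(x, name) {
  if (any(!is.finite(x))) {
    stop_quenchkin(sprintf("`%s` contains non-finite values.", name))
  }
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop_quenchkin(sprintf("`%s` must be strictly increasing.", name))
  }
  invisible(x)
}
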