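# Synthetic sample presets emulating LHCII trimers in four states
# (gel/buffer x quenched/unquenched) under three excitation conditions.
# Amplitudes are in arbitrary mOD-like units with the Chl-a Q_y bleach of the
# first compartment normalized to -1; absolute signal scales are not
# emulated.

PRESET_EXCITATIONS <- c(674, 645, 490)

# Ground-truth lifetime ladders (ps) per excitation. The 674-nm ladder has
# four singlet components; Chl-b excitation at 645 nm needs one extra fast
# component for the Chl-b -> Chl-a transfer step; the 490-nm (carotenoid)
# ladder prepends the S2 -> S1 internal conversion and the carotenoid S1
# decay, both generator conventions.
preset_lifetimes <- function(excitation_nm) {
  switch(as.character(excitation_nm),
    "674" = c(2.2, 19, 240, 2900),
    "645" = c(0.4, 3, 38, 280, 2900),
    "490" = c(0.15, 15, 240, 2900)
  )
}

# Q_y bleach amplitude ladder of the Chl-a compartments. Quenching drains
# population through the ~240 ps channel, so the quenched ladder loses much
# more amplitude between the 240-ps and terminal-singlet spectra.
qy_ladder <- function(state, n) {
  full <- if (state == "quenched") c(1, 0.95, 0.80, 0.50) else c(1, 0.97, 0.93, 0.88)
  utils::tail(full, n)
}

# Ratio of the 515-nm excited-state absorption band to the Q_y bleach; the
# band exists only in gel, stronger when quenched (0.50 of the bleach).
esa515_ratio <- function(matrix, state) {
  if (matrix != "gel") return(0)
  if (state == "quenched") 0.5 else 0.3
}

band <- function(center_nm, width_nm, amplitude) {
  tibble::tibble(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude)
}

# Carotenoid ground-state bleach structure superimposed on the singlet
# spectra: in gel the main negative band sits at 472 nm with a weak lutein
# 0-0 bleach at 490 nm; in buffer only the weak 490-nm feature remains.
car_bleach_bands <- function(matrix) {
  if (matrix == "gel") {
    dplyr::bind_rows(band(472, 6, -0.12), band(490, 5, -0.06))
  } else {
    band(490, 5, -0.06)
  }
}

# Chlorophyll-a singlet spectrum: Q_y bleach at 684 nm plus the 515-nm band
# (gel only) locked to the stated fraction of the bleach. The band of the
# hot, unequilibrated first compartment sits 2 nm to the red (517 nm):
# ultrafast equilibration over the pigment pool blue-shifts the
# excited-state absorption, which is what makes the fastest step visible as
# spectral evolution rather than a pure rescaling.
chl_a_bands <- function(qy_amp, ratio515, matrix, center515 = 515) {
  out <- band(684, 5, -qy_amp)
  if (ratio515 > 0) {
    out <- dplyr::bind_rows(out, band(center515, 8, ratio515 * qy_amp))
  }
  dplyr::bind_rows(out, car_bleach_bands(matrix))
}

# Carotenoid triplet spectrum (non-decaying terminal): lutein 0-0/0-1
# bleaches at 490/460 nm and a broad positive triplet-triplet band.
triplet_bands <- function() {
  dplyr::bind_rows(band(490, 5, -0.6), band(460, 6, -0.5), band(523, 10, 0.8))
}

#' Synthetic sample preset
#'
#' Builds the full parameterization of one emulated sample: ground-truth
#' lifetimes of the sequential scheme, per-compartment band catalogs
#' (symmetric Gaussian bands in wavelength), triplet branching and the
#' bimolecular annihilation rate. Gel presets carry a positive 515-nm
#' excited-state absorption band in every singlet-component spectrum
#' (amplitude 50% of the Q_y bleach when quenched, 30% when unquenched);
#' buffer presets carry none. Annihilation is zero in gel, where
#' immobilization keeps excitations on isolated trimers.
#'
#' @param matrix `"gel"` or `"buffer"`.
#' @param state `"quenched"` or `"unquenched"`.
#' @param excitation_nm One of 674 (Chl-a), 645 (Chl-b), 490 (carotenoid).
#' @return An object of class `sample_preset` with fields `matrix`, `state`,
#'   `excitation_nm`, `ground_truth_lifetimes` (ps), `band_catalog` (one
#'   tibble of `center_nm`, `width_nm`, `amplitude` per compartment, triplet
#'   last), `triplet_branch` and `annihilation_gamma`.
#' @export
#' @examples
#' p <- make_preset("gel", "quenched", 674)
#' p$ground_truth_lifetimes
make_preset <- function(matrix = c("gel", "buffer"),
                        state = c("quenched", "unquenched"),
                        excitation_nm = 674) {
  if (!is.character(matrix) || !matrix[1] %in% c("gel", "buffer")) {
    stop_quenchkin("`matrix` must be \"gel\" or \"buffer\".")
  }
  if (!is.character(state) || !state[1] %in% c("quenched", "unquenched")) {
    stop_quenchkin("`state` must be \"quenched\" or \"unquenched\".")
  }
  matrix <- matrix[1]; state <- state[1]
  if (!is.numeric(excitation_nm) || length(excitation_nm) != 1L ||
      !excitation_nm %in% PRESET_EXCITATIONS) {
    stop_quenchkin("`excitation_nm` must be one of 674, 645, 490.")
  }
  lifetimes <- preset_lifetimes(excitation_nm)
  ratio515 <- esa515_ratio(matrix, state)

  catalog <- switch(as.character(excitation_nm),
    "674" = {
      amps <- qy_ladder(state, 4L)
      purrr::map2(amps, c(517, 515, 515, 515), function(a, c515) {
        chl_a_bands(a, ratio515, matrix, center515 = c515)
      })
    },
    "645" = {
      # First compartment is the Chl-b excited state: Chl-b bleach at 652 nm,
      # no Chl-a bleach yet, but (in gel) the 515-nm band is already present
      # at full relative strength -- it rises within the IRF.
      first <- band(652, 5, -1)
      if (ratio515 > 0) first <- dplyr::bind_rows(first, band(515, 8, ratio515))
      amps <- qy_ladder(state, 4L)
      c(list(first),
        purrr::map2(amps, c(517, 515, 515, 515), function(a, c515) {
          chl_a_bands(a, ratio515, matrix, center515 = c515)
        }))
    },
    "490" = {
      # Carotenoid excitation: S2 (broad, short-lived), then the S1 state
      # with its characteristic S1-Sn absorption peaking at 540 nm, then the
      # Chl-a pool reached by energy transfer.
      s2 <- band(560, 25, 0.8)
      s1 <- dplyr::bind_rows(band(540, 10, 1), band(490, 5, -0.3),
                             band(460, 6, -0.25))
      if (ratio515 > 0) {
        s2 <- dplyr::bind_rows(s2, band(515, 8, 0.3 * ratio515 / 0.5))
        s1 <- dplyr::bind_rows(s1, band(515, 8, 0.3 * ratio515 / 0.5))
      }
      amps <- qy_ladder(state, 2L)
      c(list(s2, s1),
        purrr::map(amps, chl_a_bands, ratio515 = ratio515, matrix = matrix))
    }
  )
  catalog <- c(catalog, list(triplet_bands()))

  structure(
    list(
      matrix = matrix,
      state = state,
      excitation_nm = excitation_nm,
      ground_truth_lifetimes = lifetimes,
      band_catalog = catalog,
      # Triplet yield via intersystem crossing from the terminal singlet;
      # quenching shortcuts the singlet before the triplet can form.
      triplet_branch = if (state == "quenched") 0.1 else 0.3,
      annihilation_gamma = if (matrix == "gel") 0 else 1.0
    ),
    class = "sample_preset"
  )
}

#' @export
print.sample_preset <- function(x, ...) {
  cat("<sample_preset>", x$matrix, x$state, paste0(x$excitation_nm, " nm\n"))
  cat("  lifetimes (ps):", paste(x$ground_truth_lifetimes, collapse = ", "),
      "+ triplet (branch", x$triplet_branch, ")\n")
  cat("  annihilation gamma:", x$annihilation_gamma, "\n")
  invisible(x)
}

#' Ground-truth kinetic scheme of a preset
#'
#' The sequential scheme a preset simulates: all singlet lifetimes free
#' except the terminal 2900-ps singlet (held fixed, as its value is
#' constrained from fluorescence decays rather than the pump-probe window),
#' plus the non-decaying triplet terminal.
#'
#' @param preset A [make_preset()] object.
#' @return A [kinetic_scheme()].
#' @export
scheme_from_preset <- function(preset) {
  stopifnot(inherits(preset, "sample_preset"))
  lt <- preset$ground_truth_lifetimes
  status <- ifelse(lt == 2900, "fixed", "free")
  kinetic_scheme(lt, status = status, nondecaying_terminal = TRUE,
                 branch_fraction = preset$triplet_branch)
}

#' Evaluate a preset's component spectra on a wavelength grid
#'
#' @param preset A [make_preset()] object.
#' @param wavelengths_nm Ascending wavelength grid (nm).
#' @return A [component_spectra()] (representation `"raw"`), one row per
#'   singlet compartment plus the triplet terminal (last row).
#' @export
preset_spectra <- function(preset, wavelengths_nm) {
  stopifnot(inherits(preset, "sample_preset"))
  assert_increasing(wavelengths_nm, "wavelengths_nm")
  rows <- purrr::map(preset$band_catalog, function(cat) {
    Reduce(`+`, purrr::pmap(cat, function(center_nm, width_nm, amplitude) {
      gaussian_band(wavelengths_nm, center_nm, width_nm, amplitude)
    }), accumulate = FALSE)
  })
  amplitudes <- do.call(rbind, rows)
  rownames(amplitudes) <- c(paste0("S", seq_len(length(rows) - 1L)), "T")
  component_spectra(wavelengths_nm, amplitudes, representation = "raw")
}

#' Synthetic ground-state absorption spectrum
#'
#' Steady-state absorption of the emulated sample, as a sum of Gaussian
#' bands. The buffer spectrum peaks at 674 nm in the Q_y region; embedding
#' in gel blue-shifts the Q_y maximum to 672 nm and redistributes red-edge
#' absorption so that the gel-minus-buffer difference spectrum has its
#' maximal loss at 680 nm and maximal gain at 660 nm (with the analogous
#' 488-nm loss / 458-nm gain in the carotenoid region).
#'
#' @param matrix `"gel"` or `"buffer"`.
#' @param wavelengths_nm Wavelength grid (nm), default 1-nm steps over
#'   400-750 nm.
#' @return A tibble with columns `wavelength_nm`, `value` and attribute
#'   `sample`.
#' @export
absorption_preset <- function(matrix = c("gel", "buffer"),
                              wavelengths_nm = seq(400, 750, by = 1)) {
  matrix <- match.arg(matrix)
  assert_increasing(wavelengths_nm, "wavelengths_nm")
  l <- wavelengths_nm
  base <- gaussian_band(l, 650, 7, 0.62) +
    gaussian_band(l, 488, 6, 0.55) +
    gaussian_band(l, 470, 7, 0.50) +
    gaussian_band(l, 458, 6, 0.45) +
    gaussian_band(l, 436, 10, 0.90)
  v <- if (matrix == "buffer") {
    base + gaussian_band(l, 674, 6.5, 1)
  } else {
    base + gaussian_band(l, 673, 6.5, 1) +
      0.20 * (gaussian_band(l, 659, 5, 1) - gaussian_band(l, 680, 5, 1)) +
      0.08 * (gaussian_band(l, 458, 5, 1) - gaussian_band(l, 488, 5, 1))
  }
  out <- tibble::tibble(wavelength_nm = l, value = v)
  attr(out, "sample") <- matrix
  out
}
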