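# Variable-projection global fitting of transient-absorption surfaces.
#
# The nonlinear parameters (free/shared lifetimes, optionally IRF center and
# width per dataset) are optimized by Levenberg-Marquardt on log-lifetimes
# (positivity by construction); at every iteration the per-dataset component
# spectra are solved exactly by linear least squares, so they never appear
# in the nonlinear search space.

#' Options controlling the global fit
#'
#' @param mask_ranges_nm List of wavelength intervals `c(lo, hi)` excluded
#'   from the fit (e.g. a pump-scatter region); applied to every dataset.
#' @param fit_t0,fit_fwhm Also optimize the IRF center / width (one value
#'   per dataset)?
#' @param n_bootstrap Number of residual-bootstrap replicates run by
#'   [fit_global()] after convergence (0 skips the bootstrap; [bootstrap_cis()]
#'   can be called later).
#' @param ci_level Central confidence level for bootstrap intervals
#'   (default 0.68, i.e. 1 sigma).
#' @param seed Integer seed driving the multi-start jitter and the
#'   bootstrap resampling.
#' @param n_starts Number of optimization starts; the first is unjittered,
#'   the rest perturb the starting log-lifetimes to guard against local
#'   minima.
#' @param start_jitter Standard deviation of the log-lifetime jitter.
#' @param ftol,ptol,maxiter Levenberg-Marquardt tolerances.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(mask_ranges_nm = NULL,
                        fit_t0 = FALSE, fit_fwhm = FALSE,
                        n_bootstrap = 0, ci_level = 0.68, seed = NULL,
                        n_starts = 3L, start_jitter = 0.1,
                        ftol = 1e-12, ptol = 1e-12, maxiter = 300L) {
  if (ci_level <= 0 || ci_level >= 1) {
    stop_quenchkin("`ci_level` must lie strictly between 0 and 1.")
  }
  if (!is.null(mask_ranges_nm)) {
    if (is.numeric(mask_ranges_nm) && length(mask_ranges_nm) == 2L) {
      mask_ranges_nm <- list(mask_ranges_nm)
    }
    ok <- vapply(mask_ranges_nm, function(r) {
      is.numeric(r) && length(r) == 2L && r[1] < r[2]
    }, logical(1))
    if (!all(ok)) stop_quenchkin("Mask ranges must be c(lo, hi) with lo < hi.")
  }
  structure(
    list(mask_ranges_nm = mask_ranges_nm, fit_t0 = isTRUE(fit_t0),
         fit_fwhm = isTRUE(fit_fwhm), n_bootstrap = n_bootstrap,
         ci_level = ci_level, seed = seed, n_starts = n_starts,
         start_jitter = start_jitter, ftol = ftol, ptol = ptol,
         maxiter = maxiter),
    class = "fit_options"
  )
}

#' Mask wavelength intervals of a surface
#'
#' Marks the columns with wavelengths inside any of the given intervals as
#' masked. Masked columns are excluded from both the linear solve and the
#' residual norm of [fit_global()]; fitted spectra are still reported on the
#' full grid with masked columns set to `NA`.
#'
#' @param surface A [ta_surface()].
#' @param mask_ranges_nm A `c(lo, hi)` interval or a list of them. Intervals
#'   must overlap the wavelength span and must not cover it entirely.
#' @return The surface with its `masked` flags updated (previous masking is
#'   replaced).
#' @export
apply_mask <- function(surface, mask_ranges_nm) {
  stopifnot(inherits(surface, "ta_surface"))
  if (is.numeric(mask_ranges_nm) && length(mask_ranges_nm) == 2L) {
    mask_ranges_nm <- list(mask_ranges_nm)
  }
  wl <- surface$wavelengths_nm
  masked <- rep(FALSE, length(wl))
  for (r in mask_ranges_nm) {
    if (!is.numeric(r) || length(r) != 2L || r[1] >= r[2]) {
      stop_quenchkin("Mask ranges must be c(lo, hi) with lo < hi.")
    }
    if (r[2] < min(wl) || r[1] > max(wl)) {
      stop_quenchkin(sprintf("Mask [%g, %g] lies outside the wavelength span.",
                             r[1], r[2]))
    }
    masked <- masked | (wl >= r[1] & wl <= r[2])
  }
  if (all(masked)) stop_quenchkin("Mask covers every wavelength; nothing to fit.")
  surface$masked <- masked
  surface
}

# --- internals --------------------------------------------------------------

trial_scheme <- function(scheme, lifetimes) {
  scheme$lifetimes_ps <- lifetimes
  scheme
}

# Separate colliding lifetimes by a relative 1e-6 so the Bateman
# coefficients stay finite during optimization.
separate_lifetimes <- function(lifetimes, warn_env = NULL) {
  repeat {
    s <- sort(lifetimes, index.return = TRUE)
    gaps <- diff(s$x) / s$x[-length(s$x)]
    hit <- which(gaps < 1e-6)
    if (length(hit) == 0L) return(lifetimes)
    i <- s$ix[hit[1] + 1L]
    lifetimes[i] <- lifetimes[i] * (1 + 2e-6)
    if (!is.null(warn_env) && !isTRUE(warn_env$warned)) {
      warn_env$warned <- TRUE
      warning("Colliding lifetimes perturbed by a relative 1e-6 during fitting.",
              call. = FALSE)
    }
  }
}

# Build the parameter vector and the decoder for the nonlinear search.
make_par_map <- function(scheme, irfs, options) {
  free_idx <- which(scheme$status %in% c("free", "shared"))
  n_ds <- length(irfs)
  n <- length(free_idx) + n_ds * (options$fit_t0 + options$fit_fwhm)
  decode <- function(par) {
    lt <- scheme$lifetimes_ps
    lt[free_idx] <- exp(par[seq_along(free_idx)])
    off <- length(free_idx)
    irfs2 <- irfs
    if (options$fit_t0) {
      for (d in seq_len(n_ds)) irfs2[[d]]$t0 <- par[off + d]
      off <- off + n_ds
    }
    if (options$fit_fwhm) {
      for (d in seq_len(n_ds)) {
        f <- exp(par[off + d])
        irfs2[[d]]$fwhm <- f
        irfs2[[d]]$sigma <- f / (2 * sqrt(2 * log(2)))
      }
    }
    list(lifetimes = lt, irfs = irfs2)
  }
  start <- c(log(scheme$lifetimes_ps[free_idx]),
             if (options$fit_t0) vapply(irfs, `[[`, numeric(1), "t0"),
             if (options$fit_fwhm) log(vapply(irfs, `[[`, numeric(1), "fwhm")))
  list(free_idx = free_idx, n = n, decode = decode, start = start)
}

# Residuals over the unmasked columns of every dataset, with the linear
# (spectral) parameters projected out.
varpro_residuals <- function(par, datasets, scheme, pmap, warn_env) {
  n_res <- sum(vapply(datasets, function(ds) {
    length(ds$times_ps) * sum(!ds$masked)
  }, numeric(1)))
  # Penalty residual for trial steps that leave the numerically meaningful
  # region (lifetimes far outside the observable window, overflow in the
  # cascade coefficients): a large constant makes Levenberg-Marquardt
  # shrink the step rather than abort.
  penalty <- function() rep(1e6, n_res)
  dec <- pmap$decode(par)
  if (any(!is.finite(dec$lifetimes)) ||
      any(dec$lifetimes < 1e-6) || any(dec$lifetimes > 1e9)) {
    return(penalty())
  }
  lt <- separate_lifetimes(dec$lifetimes, warn_env)
  sch <- trial_scheme(scheme, lt)
  out <- tryCatch(
    unlist(lapply(seq_along(datasets), function(d) {
      ds <- datasets[[d]]
      C <- concentration_profiles(sch, dec$irfs[[d]], ds$times_ps)
      Y <- ds$data[, !ds$masked, drop = FALSE]
      qrC <- qr(C)
      as.vector(Y - C %*% qr.coef(qrC, Y))
    })),
    error = function(e) penalty()
  )
  if (any(!is.finite(out))) penalty() else out
}

solve_spectra <- function(datasets, scheme, irfs) {
  lapply(seq_along(datasets), function(d) {
    ds <- datasets[[d]]
    C <- concentration_profiles(scheme, irfs[[d]], ds$times_ps)
    qrC <- qr(C)
    coef_un <- qr.coef(qrC, ds$data[, !ds$masked, drop = FALSE])
    S <- matrix(NA_real_, nrow = ncol(C), ncol = length(ds$wavelengths_nm))
    S[, !ds$masked] <- coef_un
    resid <- matrix(NA_real_, nrow = length(ds$times_ps),
                    ncol = length(ds$wavelengths_nm))
    resid[, !ds$masked] <- ds$data[, !ds$masked, drop = FALSE] - C %*% coef_un
    fitted <- matrix(NA_real_, nrow = length(ds$times_ps),
                     ncol = length(ds$wavelengths_nm))
    fitted[, !ds$masked] <- C %*% coef_un
    list(C = C, spectra = S, resid = resid, fitted = fitted)
  })
}

#' Global variable-projection fit of one or more TA surfaces
#'
#' Fits a shared sequential [kinetic_scheme()] to one or several
#' [ta_surface()] datasets simultaneously. Free and shared lifetimes take a
#' single value across all datasets of the linked group while the component
#' spectra (EADS) remain per-dataset; fixed lifetimes are never perturbed.
#' The IRF center and width can optionally be fitted per dataset. The sum
#' of squared residuals over all unmasked (delay, wavelength) points is
#' minimized with uniform weights.
#'
#' @param datasets A [ta_surface()] or a list of them; all surfaces in a
#'   linked group must share the wavelength grid. Apply scatter masks with
#'   [apply_mask()] or via `options$mask_ranges_nm`.
#' @param scheme Starting [kinetic_scheme()]; its lifetimes are the initial
#'   values and its statuses decide what is optimized.
#' @param irf An [irf_gaussian()] (shared start) or a list, one per dataset.
#' @param options A [fit_options()].
#' @return An object of class `global_fit`: `lifetimes` (tibble with
#'   `lifetime_ps`, `status`, bootstrap `ci_lo`/`ci_hi`/`se` when
#'   requested), `eads` (list of [component_spectra()], one per dataset,
#'   `NA` at masked wavelengths), `residuals`, `rmse`, `ssr`, `converged`,
#'   `niter`, plus the final scheme, per-dataset IRFs, inputs and options.
#'   Non-convergence is flagged and warned about, never silent.
#' @seealso [bootstrap_cis()], [select_n_components()]
#' @export
fit_global <- function(datasets, scheme, irf, options = fit_options()) {
  if (inherits(datasets, "ta_surface")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "ta_surface")),
            inherits(scheme, "kinetic_scheme"),
            inherits(options, "fit_options"))
  wl <- datasets[[1]]$wavelengths_nm
  for (ds in datasets[-1]) {
    if (!isTRUE(all.equal(ds$wavelengths_nm, wl))) {
      stop_quenchkin("All linked datasets must share the wavelength grid.")
    }
  }
  if (!is.null(options$mask_ranges_nm)) {
    datasets <- lapply(datasets, apply_mask, mask_ranges_nm = options$mask_ranges_nm)
  }
  irfs <- if (inherits(irf, "irf_gaussian")) {
    rep(list(irf), length(datasets))
  } else {
    stopifnot(length(irf) == length(datasets))
    irf
  }
  ncomp <- n_compartments(scheme)
  for (ds in datasets) {
    if (length(ds$times_ps) < ncomp) {
      stop_quenchkin("Fewer time points than compartments.")
    }
  }
  pmap <- make_par_map(scheme, irfs, options)
  if (pmap$n == 0L) {
    stop_quenchkin("Nothing to optimize: all lifetimes fixed and no IRF parameter free.")
  }
  warn_env <- new.env()

  starts <- list(pmap$start)
  if (options$n_starts > 1L) {
    jitters <- with_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1L), function(i) {
        stats::rnorm(pmap$n, sd = options$start_jitter)
      })
    })
    starts <- c(starts, lapply(jitters, function(j) pmap$start + j))
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol, ptol = options$ptol,
                                     maxiter = options$maxiter,
                                     maxfev = 400L * (pmap$n + 1L))
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = varpro_residuals,
      datasets = datasets, scheme = scheme, pmap = pmap, warn_env = warn_env,
      control = ctrl
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop_quenchkin("All optimization starts failed.")
  converged <- best$info %in% 1:4
  if (!converged) {
    warning("Global fit did not converge: ", best$message, call. = FALSE)
  }

  dec <- pmap$decode(best$par)
  lifetimes <- separate_lifetimes(dec$lifetimes)
  # Report lifetimes ascending; permute statuses and spectra rows along.
  ord <- order(lifetimes)
  final_scheme <- kinetic_scheme(lifetimes[ord], status = scheme$status[ord],
                                 nondecaying_terminal = scheme$nondecaying_terminal,
                                 branch_fraction = scheme$branch_fraction)
  sol <- solve_spectra(datasets, final_scheme, dec$irfs)
  n_res <- sum(vapply(datasets, function(ds) {
    length(ds$times_ps) * sum(!ds$masked)
  }, numeric(1)))
  ssr <- best$deviance
  eads <- lapply(seq_along(datasets), function(d) {
    amp <- sol[[d]]$spectra
    rownames(amp) <- c(paste0("EADS", seq_len(length(final_scheme$lifetimes_ps))),
                       if (final_scheme$nondecaying_terminal) "terminal")
    component_spectra(wl, amp, representation = "EADS")
  })
  result <- structure(
    list(
      lifetimes = tibble::tibble(
        lifetime_ps = final_scheme$lifetimes_ps,
        status = final_scheme$status,
        ci_lo = NA_real_, ci_hi = NA_real_, se = NA_real_
      ),
      scheme = final_scheme,
      irfs = dec$irfs,
      eads = eads,
      residuals = lapply(sol, `[[`, "resid"),
      fitted = lapply(sol, `[[`, "fitted"),
      rmse = sqrt(ssr / n_res),
      ssr = ssr,
      n_residuals = n_res,
      converged = converged,
      niter = best$niter,
      datasets = datasets,
      options = options
    ),
    class = "global_fit"
  )
  if (options$n_bootstrap > 0) {
    ci <- bootstrap_cis(result, n_bootstrap = options$n_bootstrap,
                        seed = options$seed)
    result$lifetimes$ci_lo <- ci$ci_lo
    result$lifetimes$ci_hi <- ci$ci_hi
    result$lifetimes$se <- ci$se
    result$bootstrap <- ci
  }
  result
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>", length(x$datasets), "linked dataset(s),",
      length(x$scheme$lifetimes_ps), "decaying component(s)\n")
  print(x$lifetimes)
  cat(sprintf("  RMSE = %.4g, converged = %s (%d iterations)\n",
              x$rmse, x$converged, x$niter))
  invisible(x)
}

#' @rdname fit_global
#' @param x A `global_fit`.
#' @param ... Unused.
#' @method tidy global_fit
#' @export
tidy.global_fit <- function(x, ...) {
  x$lifetimes
}

#' @rdname fit_global
#' @method glance global_fit
#' @export
glance.global_fit <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(x$datasets),
    n_components = length(x$scheme$lifetimes_ps),
    rmse = x$rmse,
    ssr = x$ssr,
    n_residuals = x$n_residuals,
    niter = x$niter,
    converged = x$converged
  )
}

#' @rdname fit_global
#' @param object A `global_fit`.
#' @method autoplot global_fit
#' @export
autoplot.global_fit <- function(object, ...) {
  df <- purrr::imap_dfr(object$eads, function(sp, d) {
    dplyr::mutate(as_tibble(sp), dataset = paste0("dataset ", d))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$amplitude,
                                   color = .data$component)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(x = "wavelength (nm)", y = "EADS amplitude")
}

#' Residual-bootstrap confidence intervals for fitted lifetimes
#'
#' Resamples the fit residuals (with replacement, over the unmasked
#' time-pixel pool of each dataset), rebuilds each surface as fit +
#' resampled residuals, refits, and reports central percentile intervals of
#' the free lifetimes. Residual (not case) resampling is used because
#' wavelengths are strongly correlated. Deterministic under a fixed seed.
#'
#' @param result A converged [fit_global()] result.
#' @param n_bootstrap Number of replicates (at least 20; fewer make the
#'   interval meaningless and is refused).
#' @param seed Integer seed.
#' @param ci_level Central interval mass (default: the fit's
#'   `options$ci_level`, normally 0.68).
#' @return A tibble with one row per lifetime: `lifetime_ps`, `status`,
#'   `ci_lo`, `ci_hi`, `se` (`NA` for fixed lifetimes), and `n_bootstrap`.
#' @export
bootstrap_cis <- function(result, n_bootstrap = 200L, seed = NULL,
                          ci_level = NULL) {
  stopifnot(inherits(result, "global_fit"))
  if (!result$converged) {
    stop_quenchkin("Bootstrap requires a converged fit.")
  }
  if (n_bootstrap < 20L) {
    stop_quenchkin("`n_bootstrap` must be at least 20 for a meaningful interval.")
  }
  if (is.null(ci_level)) ci_level <- result$options$ci_level
  datasets <- result$datasets
  scheme <- result$scheme
  opts <- result$options
  opts$n_starts <- 1L
  opts$n_bootstrap <- 0
  opts$mask_ranges_nm <- NULL  # masks already applied to stored datasets
  pmap <- make_par_map(scheme, result$irfs, opts)
  free_idx <- pmap$free_idx
  pools <- lapply(result$residuals, function(r) r[!is.na(r)])
  fits <- lapply(result$fitted, identity)

  draws <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      sims <- lapply(seq_along(datasets), function(d) {
        ds <- datasets[[d]]
        keep <- !ds$masked
        newdata <- ds$data
        n_draw <- length(ds$times_ps) * sum(keep)
        newdata[, keep] <- fits[[d]][, keep] +
          matrix(sample(pools[[d]], n_draw, replace = TRUE),
                 nrow = length(ds$times_ps))
        ds$data <- newdata
        ds
      })
      fit_b <- fit_global(sims, scheme, result$irfs, opts)
      fit_b$lifetimes$lifetime_ps[fit_b$lifetimes$status != "fixed"]
    }, numeric(length(free_idx)))
  })
  draws <- matrix(draws, nrow = length(free_idx))

  lt <- result$lifetimes
  out <- tibble::tibble(
    lifetime_ps = lt$lifetime_ps,
    status = lt$status,
    ci_lo = NA_real_, ci_hi = NA_real_, se = NA_real_,
    n_bootstrap = n_bootstrap
  )
  alpha <- (1 - ci_level) / 2
  free_rows <- which(lt$status != "fixed")
  for (i in seq_along(free_rows)) {
    q <- stats::quantile(draws[i, ], c(alpha, 1 - alpha), names = FALSE)
    out$ci_lo[free_rows[i]] <- q[1]
    out$ci_hi[free_rows[i]] <- q[2]
    out$se[free_rows[i]] <- stats::sd(draws[i, ])
  }
  out
}

#' Model-size scan: fit with varying numbers of components
#'
#' Refits the data with sequential schemes of increasing size and reports
#' the residual RMSE and a structured-residual score (mean lag-1
#' autocorrelation of the residuals along time) per component count. The
#' caller judges the elbow; this function ranks, it does not decide.
#'
#' @param datasets As in [fit_global()].
#' @param n_components Integer vector of component counts (each >= 1), or a
#'   list of starting [kinetic_scheme()]s.
#' @param irf As in [fit_global()].
#' @param options A [fit_options()].
#' @return A tibble with columns `n_components`, `rmse`, `lag1_autocorr`,
#'   `converged` and a list-column `fit` holding each [fit_global()] result.
#' @export
select_n_components <- function(datasets, n_components, irf,
                                options = fit_options()) {
  if (inherits(datasets, "ta_surface")) datasets <- list(datasets)
  schemes <- if (is.list(n_components) &&
                 all(vapply(n_components, inherits, logical(1), "kinetic_scheme"))) {
    n_components
  } else {
    if (any(n_components < 1L)) stop_quenchkin("Component counts must be >= 1.")
    tspan <- range(datasets[[1]]$times_ps)
    lapply(as.integer(n_components), function(k) {
      lo <- max(diff(tspan) / 1000, 0.1)
      hi <- diff(tspan) / 2
      kinetic_scheme(exp(seq(log(lo), log(hi), length.out = k)))
    })
  }
  purrr::map_dfr(schemes, function(sch) {
    fit <- fit_global(datasets, sch, irf, options)
    ac <- mean(vapply(fit$residuals, function(r) {
      cols <- which(!is.na(r[1, ]))
      mean(vapply(cols, function(j) {
        v <- r[, j]
        if (stats::sd(v) == 0) return(0)
        stats::cor(v[-length(v)], v[-1])
      }, numeric(1)))
    }, numeric(1)))
    tibble::tibble(
      n_components = length(sch$lifetimes_ps),
      rmse = fit$rmse,
      lag1_autocorr = ac,
      converged = fit$converged,
      fit = list(fit)
    )
  })
}
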