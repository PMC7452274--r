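# quenchkin

Kinetic and spectral analysis of quenching in light-harvesting complexes.

## The problem

The major light-harvesting complex of plants (LHCII) switches between a
light-harvesting and a dissipative conformation; the dissipative state
underlies non-photochemical quenching (NPQ), the photoprotective release of
excess excitation energy as heat. Immobilizing single LHCII trimers in a
polyacrylamide gel locks the quenched conformation without aggregation, and
its transient-absorption signature is a positive excited-state absorption
band near 515 nm — reaching ~50% of the chlorophyll-a Q_y bleach — that is
absent for trimers in buffer. Quantifying the underlying excited-state
dynamics requires the standard toolbox of ultrafast spectroscopy:

* **global lifetime analysis** of time × wavelength ΔA surfaces with a
  sequential compartmental model convolved with a Gaussian instrument
  response, fitted by **variable projection** (the component spectra —
  EADS/DADS — are solved exactly by linear least squares at every iteration
  of the nonlinear lifetime search), with lifetime linking across datasets,
  fixed components, scatter masks and **residual-bootstrap confidence
  intervals**;
* **TCSPC reconvolution fitting** of fluorescence decay histograms by
  Poisson maximum likelihood, with amplitude- and intensity-weighted mean
  lifetimes ⟨τ⟩ = ΣAτ/ΣA and ΣAτ²/ΣAτ;
* **spectral quantifications**: band/bleach amplitude ratios, difference
  spectra with interpolated peak finding, vibronic gaps
  (10⁷·|1/λ₁ − 1/λ₂| cm⁻¹), rise-time comparisons, and an
  intensity-dependence diagnostic for singlet–singlet annihilation.

`quenchkin` implements this pipeline in R, together with a synthetic-data
generator that emulates the four sample states (gel/buffer ×
quenched/unquenched) and three excitation conditions (674, 645, 490 nm), so
the whole analysis is testable end to end without measured data. The
methods vignette (`vignettes/quenchkin-methods.Rmd`) documents the models,
defaults and limitations.

## Worked example

Simulate linked quenched and unquenched gel surfaces at the default study
conditions, mask the 650–700 nm pump-scatter region, and fit a
four-component sequential scheme with the terminal singlet fixed at
2900 ps:

```r
library(quenchkin)

dq <- simulate_ta(make_preset("gel", "quenched", 674),   noise = noise_model(seed = 1))
du <- simulate_ta(make_preset("gel", "unquenched", 674), noise = noise_model(seed = 2))
start <- kinetic_scheme(c(1, 10, 100, 2900),
                        status = c("free", "free", "free", "fixed"),
                        nondecaying_terminal = TRUE, branch_fraction = 0.2)
fit <- fit_global(list(dq, du), start, irf_gaussian(0, 0.1),
                  fit_options(mask_ranges_nm = c(650, 700), seed = 1,
                              n_bootstrap = 40))
fit
#> <global_fit> 2 linked dataset(s), 4 decaying component(s)
#> # A tibble: 4 × 5
#>   lifetime_ps status  ci_lo  ci_hi      se
#>         <dbl> <chr>   <dbl>  <dbl>   <dbl>
#> 1        2.13 free     2.08   2.22  0.0707
#> 2       20.3  free    18.6   20.8   1.58
#> 3      232.   free   226.   243.   10.5
#> 4     2900    fixed   NA     NA    NA
#>   RMSE = 0.009777, converged = TRUE (50 iterations)
```

The fit recovers the generator's ground-truth ladder (2.2, 19, 240,
2900 ps) from data with 1% noise; the 68% bootstrap intervals quantify the
spread. `tidy(fit)`, `glance(fit)` and `autoplot(fit)` expose the lifetime
table, fit summary and per-dataset EADS; `eads_dads_convert()` switches to
the decay-associated representation.

The worked-example quantities of the fluorescence and spectral analyses:

```r
mean_lifetimes(data.frame(tau_ns = c(0.23, 1.19, 3.3),
                          amplitude = c(0.18, 0.32, 0.5)))
#> # A tibble: 1 × 2
#>   tau_amp_ns tau_int_ns
#>        <dbl>      <dbl>
#> 1       2.07       2.85

s <- simulate_ta(make_preset("gel", "quenched", 674), noise = noise_model(ta_sigma = 0))
band_ratio(spectrum_at(s, 10), c(505, 525), c(675, 695))
#> # A tibble: 1 × 5
#>   band_peak_nm band_amplitude reference_peak_nm reference_amplitude ratio
#>          <dbl>          <dbl>             <dbl>               <dbl> <dbl>
#> 1         515.          0.449               684              -0.898 0.500
```

The first is the amplitude-weighted mean lifetime of a quenched-gel
fluorescence decay (2.07 ns — quenched, versus 3.18/3.65 ns for unquenched
gel/buffer parameter sets); the second shows the 515-nm band at exactly
half the Q_y bleach amplitude in the quenched-gel transient spectrum at
10 ps.

Surfaces and decay histograms read and write as plain delimited text with
`read_surface()`/`write_surface()` and `read_decay()`/`write_decay()`
(ps/nm/mOD and ns/counts conventions, `#`-prefixed metadata, lossless
round trip).

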