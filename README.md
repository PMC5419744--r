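# polexchange

Simulation and analysis toolkit for single-molecule studies of DNA
polymerase III* exchange at the *E. coli* replisome.

The replisome presents a paradox: it is highly processive and stable
against dilution, yet the polymerase holoenzyme (Pol III*, the clamp-loader
complex with up to three αεθ cores) exchanges in and out of active
replisomes within seconds when competitors are present in solution. The
resolution is **multisite competitive exchange**: a multivalent resident is
safe while every transiently broken interaction reforms before anything
else binds, but a competitor occupying a transiently vacated sub-site can
complete the replacement. polexchange implements the full quantitative
workflow used to characterise this behaviour:

* an exact event-driven (Gillespie) simulator of resident + auxiliary-site
  exchange kinetics, with photophysics (irreversible photobleaching,
  power-scaled FRAP pulse schedules, binomial labeling) layered on top —
  in the two-site limit the mean residence time is
  `τ(C) = 1/(k_on·C) + 1/k_handoff`;
* kymograph rendering and fork tracking for flow-stretched rolling-circle
  replication assays, with penalized piecewise-linear segmentation
  (`RSS + penalty × segments`, exact dynamic program) for replication
  rates, and exponential-MLE processivity fits;
* spot photometry, single-fluorophore calibration, and integer-centered
  Gaussian-mixture stoichiometry (components fixed at counts 1..K, sds
  `√n·σ₁`, weights fitted by EM);
* single-molecule FRAP analysis: pulse location, normalized recovery-curve
  averaging, and exchange-time fitting with
  `I(t) = offset + A(1 − exp(−t/τ))` across concentration series;
* two-color focus cross-correlation (per-lag Pearson normalisation,
  exponential decay fit, randomized cross-cell null band) that
  discriminates whole-complex exchange from core-only, uncoupled, or no
  exchange;
* photobleaching step counting by penalized change-point analysis and
  whole-cell copy-number / concentration estimation.

## Worked example: exchange time from a simulated smFRAP experiment

```r
library(polexchange)

# arrival-dominated two-site kinetics with a 10 s mean residence time
params <- exchange_params(n_sites = 2, k_on = 1 / 9.5, k_off = 0,
                          k_handoff = 2, conc = 1)
photo  <- photo_params(bleach_lifetime_s = 3000, power_pulse = 75000,
                       pulse_period_s = 50, pulse_duration_s = 0.4,
                       unit_intensity = 1000, bg_mean = 20, bg_sd = 5,
                       frame_interval_s = 0.2)

traces <- simulate_frap_experiment(params, photo, n_replisomes = 60,
                                   duration = 165, seed = 1)
curve  <- extract_and_average_recovery(traces)
fit    <- fit_exchange_time(curve)
glance(fit)
#> # A tibble: 1 x 6
#>     tau tau_se amplitude offset  conc flag
#>   <dbl>  <dbl>     <dbl>  <dbl> <dbl> <chr>
#> 1  9.76  0.159      1.07 0.0652     1 <NA>
```

The fitted `tau` (9.76 s here) is the characteristic exchange time: the
post-pulse signal recovers as unbleached complexes from solution replace
the bleached resident, so its timescale is the resident residence time —
within the fit error of the generative 10 s
(`1/(k_on·conc) + 1/k_handoff = 9.5 + 0.5`). `amplitude` is the recovered
fraction of the pre-pulse steady state and `offset` the immediate
post-pulse floor. `autoplot(curve, fit = fit)` overlays the fit on the
averaged recovery curve (`amplitude` slightly above 1 and `tau_se` reflect
Monte-Carlo noise of the 60-trace ensemble); at `conc = 0` the same
pipeline flags
`"no_recovery"`, the dilution-stability control.

## Layout

* `R/` — simulators (`simulate_exchange`, `apply_photophysics`,
  `simulate_replication_trajectory`, `render_kymograph`,
  `simulate_invivo_pair`, `simulate_frap_experiment`,
  `simulate_cell_field`) and analyses (`track_fork`,
  `segment_trajectory`, `fit_rate_distribution`, `fit_processivity`,
  `integrate_spot`, `calibrate_single`, `stoichiometry_series`,
  `fit_integer_mixture`, `colocalization_fraction`, `locate_pulses`,
  `extract_and_average_recovery`, `fit_exchange_time`,
  `exchange_vs_concentration`, `cross_correlation`, `average_ccf`,
  `randomized_control`, `fit_ccf_decay`, `classify_mechanism`,
  `detect_steps`, `single_molecule_intensity`, `copy_number`,
  `concentration`, `complex_concentration`, `count_cells`), plus
  `run_pipeline()` with YAML configs and a thin CLI wrapper in
  `inst/scripts/polexchange.R`.
* `vignettes/polexchange-methods.Rmd` — the models, defaults, numerical
  choices and limitations.
* `tests/testthat/` — unit, property and end-to-end tests with
  closed-form, brute-force and generative-truth oracles.

Fit objects follow broom conventions (`tidy()`, `glance()`); result types
have `autoplot()` methods.
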