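---
title: "Models and methods behind polexchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polexchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polexchange)
```

polexchange implements the quantitative workflow of a single-molecule study
of DNA polymerase III* (the holoenzyme without the sliding clamp) exchanging
at the *E. coli* replisome: stochastic simulation of multisite exchange
kinetics and photophysics, kymograph and trace analysis for rolling-circle
replication assays, single-molecule FRAP exchange-time estimation, two-color
cross-correlation mechanism discrimination, and photobleaching-based
molecule counting. Raw microscopy for this class of experiment is rarely
deposited, so the package pairs every analysis with a synthetic-data
generator that reproduces the statistical structure the analysis assumes;
the generators are first-class, tested code, not test fixtures.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulations do and do not capture.

## The multisite exchange model

A replisome that is stable in isolation but replaced concentration-
dependently is modelled as one **resident** polymerase site plus
`n_sites - 1` **auxiliary** (transiently vacated) binding sites:

* empty auxiliary sites fill from solution at rate $k_{on} C$ each;
* occupied auxiliary sites empty at $k_{off}$;
* while at least one auxiliary occupant is present, the resident is
  replaced at $k_{handoff}$: the old resident departs and one auxiliary
  occupant (chosen uniformly) becomes the new resident.

This is a modelling choice of this package — single-molecule data of this
kind constrain the phenomenology (dilution stability, concentration-
dependent exchange) but not the microscopic scheme. The scheme was chosen
because it reproduces both limits exactly:

* at $C = 0$ no competitor ever arrives and the resident persists
  indefinitely (dilution stability);
* with two sites and $k_{off} = 0$, the mean resident residence time is
  $\tau(C) = 1/(k_{on} C) + 1/k_{handoff}$, the saturating concentration
  dependence seen in smFRAP concentration series.

The simulation is an exact event-driven jump process (Gillespie), then
discretised to frames; the per-frame occupancy table is a view of the exact
event log, so discretisation affects only frame-level summaries (an event
and its reversal inside one frame interval are invisible at the frame
level, which is the same censoring a camera applies).

**Default rates.** `exchange_params()` defaults to `n_sites = 3` (up to two
competitors near the fork, matching stoichiometry histograms that need
components up to 3–4), $k_{on} = 0.55$ nM$^{-1}$s$^{-1}$ and
$k_{handoff} = 1/1.7$ s$^{-1}$ — the values for which the two-site closed
form gives $\tau \approx 1.85$ s at 13 nM, the fast end of the measured
concentration series — and $k_{off} = 10$ s$^{-1}$, chosen so that at the
standard 6.7 nM working concentration the auxiliary equilibrium occupancy
$k_{on}C/(k_{on}C + k_{off}) \approx 0.27$ puts the **modal** total
occupancy at one complex, as observed in vitro. These are package defaults
fixed once, not measured quantities.

Two parameter regimes are used deliberately in the tests and the
acceptance script:

* the **full three-site model** with the defaults above for stoichiometry
  studies;
* the **two-site, $k_{off}=0$ limit** for FRAP residence-time recovery,
  because there the generative residence time has the exact closed form
  that serves as ground truth. The split between arrival and handoff is
  set to 98%/2% of the target residence time: recovery of fluorescence is
  then dominated by a single (arrival) timescale and a single-exponential
  fit is an unbiased estimator. The validation experiment uses perfect
  labeling (every core fluorescent), 20 frames per residence time, and
  eight recovery windows of four residence times per trace — each window
  contains essentially one recovery event, so the Monte-Carlo standard
  error of the fitted time scales with the window count, and these
  conditions put it near 5% for 100 traces, well inside the 15% recovery
  check. With comparable arrival and handoff times
  the recovery is hypoexponential and biased; worse, with $k_{off} = 0$
  and fast arrivals the auxiliary site is usually occupied by a *bleached*
  competitor at pulse time, which must first be promoted before a fresh
  complex can land — an extra handoff delay that inflates the measured
  recovery time at high concentration. The concentration-series
  (monotonicity) studies therefore run the full default model, whose fast
  auxiliary turnover avoids that pathology and whose predicted exchange
  time $1/(k_{handoff}(1-(1-p)^{n_{sites}-1}))$, with
  $p = k_{on}C/(k_{on}C+k_{off})$, sets the pulse schedule per
  concentration.

## Photophysics

Each labeled complex carries `cores_per_complex` (default 3) polymerase
cores, each fluorescent with probability `label_efficiency` (default
0.85). A fluorophore survives a frame of length $\Delta t$ at relative
excitation power $p$ with probability $\exp(-\Delta t\, p / T_{bleach})$;
bleaching is irreversible and blinking is not modelled (imaging buffers in
this field are designed to suppress it). FRAP pulses are frames at
`power_pulse`; entering complexes always carry fresh fluorophores, so
post-pulse recovery reports exchange from solution only. Detected
intensity is `unit_intensity` per active fluorophore plus Gaussian
background.

The default bleach lifetime (14.1 s at reference power) and single-core
intensity scale (5100 counts) match the in vitro calibration values this
workflow is designed to reproduce.

## Kymographs and trajectory analysis

Replication trajectories are piecewise linear: total processivity drawn
exponential (default mean 73 kb; 3.5 kb models the core-challenged
condition), per-segment rates Gaussian (default 561 ± 27 bp/s, truncated
at zero), segment durations exponential (default mean 30 s — constant-slope
segment durations are not a reported quantity in this kind of assay;
30 s gives a few segments per average molecule).
Flow-stretched DNA converts length to position at
`gamma_um_per_kb = 2.1/7.2` µm/kb. Rendering uses a Gaussian point-spread
profile (σ = 1.2 px) whose discrete photon sum equals the spot intensity
to well under 1%, plus optional stationary deposit spots left by departing
polymerases (suppressed when Pol I is present, which removes the flaps
they remain bound to).

Fork tracking is per-column: among pixels above a threshold — the larger
of a robust noise level (image median + 5 MAD) and 20% of the brightest
structure still allowed — and at most 2 px behind the previous position
(backtrack tolerance absorbing noise), the *furthest local maximum* wins;
the fork always leads its deposits, so this never locks onto a brighter
deposit behind it. The position is refined by an intensity-weighted
centroid (±3 px). Columns without a candidate are gaps, interpolated and
flagged; more than 50% gaps aborts.

Segmentation into constant-slope stretches is penalized piecewise-linear
least squares: cost = RSS + penalty × (number of segments), solved exactly
by dynamic programming with a minimum segment duration (default 5 s). The
default penalty is $4\hat\sigma^2\log n$ with $\hat\sigma$ the
second-difference MAD noise estimate — a BIC-style choice calibrated on
synthetic trajectories; the criterion the original analysis used for
"constant slope" is not stated, so the penalty is exposed. On exact cost
ties the earliest change point wins (reconstruction from the left takes
the earliest boundary among optima, i.e. the lexicographically smallest
optimal change-point vector), and the test suite verifies equality with
exhaustive enumeration on short traces.

Rates are summarised as a Gaussian mean ± s.e.m. (Freedman–Diaconis bins
recorded for display); processivities by the exponential maximum-
likelihood estimator (the sample mean), which is bin-free and matches the
single-exponential decay assumption — binned histograms are display only.

## Stoichiometry

Replisome-spot intensities are integrated in a fixed disc minus the median
of a surrounding annulus times the disc area, making the measurement
invariant to flat background offsets. Counts are intensities divided by
the intensity of a single Pol III*. The field is ambiguous about
normalising by one *core* or one *complex* (three cores); the default unit
is `cores_per_complex × label_efficiency × single-core mean`
(3 × 0.85 × calibration), both factors configurable, and the per-core
alternative is carried in the result metadata.

The stoichiometry histogram is fitted by a mixture of Gaussians centered
at integers $1..K$ with fixed sds $\sqrt{n}\,\sigma_1$ (independent
emitters add variance) and only the weights free, by EM; $K$ defaults to 4
at the high-concentration condition and 3 at the low one. The modal
stoichiometry is the argmax weight. Colocalization uses greedy mutual
nearest-neighbor matching inside a radius so no spot is counted twice.

## smFRAP

Pulse positions come from the recorded schedule when available, otherwise
from detection (a falling edge below 20% of the running pre-frame median).
Each post-pulse window is normalized by the trace's pre-pulse steady state
— the mean over *all* of that trace's pre-pulse windows (10 frames before
each pulse; pulse frames excluded from both normalization and fitting) —
then averaged within trace over pulses, then across traces. Pooling the
steady state across pulses matters: a trace that has not yet recovered
when the next pulse arrives would otherwise be normalized by its own dark
level, exploding that window; because exchange arrivals are memoryless,
such windows are still valid recovery samples under pooled normalization.
Traces whose pooled steady state is not significantly positive are
dropped. The exchange-time fit is multi-start over the time constant. The recovery curve is fitted with
$I(t) = \mathrm{offset} + A(1 - e^{-t/\tau})$; the functional form of the
original fit is not stated, and the saturating single exponential is the
reaction-dominant default (diffusion-limited FRAP is out of scope).
Non-convergence, negligible amplitude, or $\tau$ beyond ten times the
window is flagged "no recovery" — the expected outcome at zero
concentration. A concentration series is summarised with a monotonicity
report and an optional fit of $\tau(C) = 1/(k_{on}C) + 1/k_{handoff}$.

## Two-color cross-correlation

The CCF of two traces is, per lag, the Pearson correlation of the
overlapping windows (means and sds over the overlap). This normalisation
was chosen over the fixed-global-moments variant because it is exactly
bounded in $[-1, 1]$ at every lag and gives CCF(0) = 1 for identical
traces; the two differ only at large lags, well away from the near-zero
peak that carries the signal. Correlation runs on unsmoothed traces — the
2 s moving average used for display would widen the peak — and, by
default, after dividing out a per-trace single-exponential bleaching fit,
because shared bleaching induces a spurious positive correlation; both
switches are exposed (`preprocess` arguments) since the original choices
are not stated.

The null band comes from the study's own control: random channel-1 /
channel-2 pairs from different cells. Classification compares the observed
averaged CCF's maximum within ±3 frames of zero lag against the 99th
percentile of the *windowed maximum* of bootstrap-averaged null draws.
Using the maximum's null distribution (rather than per-lag quantiles)
keeps the family-wise false-positive rate at the nominal 1% — comparing
seven correlated lags each at their own 99th percentile would call a
spurious peak in roughly 5% of experiments.

The in vivo generator drives each focus with per-frame binding chains
(`k_on`, `k_off` in frames⁻¹, defaults 0.01): shared chains for
whole-complex exchange, one stable channel (`k_off = 10⁻⁶`, the
documented "much less than one" constant) for core-only exchange and
no-exchange, independent chains for uncoupled exchange. Arrivals carry
fresh fluorophores; with finite bleach lifetime, exchange continuously
re-brightens foci, so only *shared* arrivals/departures produce a positive
CCF peak. For CCF decay-time recovery the correlation time of a shared
two-state chain is $1/(k_{on}+k_{off})$ frames, so the generative
residence time $1/k_{off}$ is recovered accurately only when
$k_{on} \ll k_{off}$; the recovery test uses $k_{on} = k_{off}/10$ and
long traces (3000 frames) because the sample CCF of short traces is
biased toward faster decay.

## Copy-number counting

Whole-cell traces are corrected for constant cellular autofluorescence and
for the coverslip background (single-exponential field fit), then fitted
with a single exponential whose value at $t = 0$ is the cell's label
intensity; amplitude-based counting is the default because the maximum
intensity of a noisy first frame is biased. Copies = amplitude /
single-molecule intensity, where the single-molecule unit is the Gaussian
mean of photobleaching step sizes found by the same penalized
change-point machinery (piecewise-constant model, steps below
`min_step = 2σ̂` merged).

Concentration conversion needs a cytoplasmic volume the original analysis
does not state. The default 2.4 fL is the value consistent with *both*
reported copy/concentration pairs (104 copies ↔ ~72 nM and 96 copies ↔
~66 nM); it is exposed as `cell_geometry(volume_fL = )` and flagged as a
configuration constant, not a measurement. The complex concentration
estimator averages the per-subunit estimates (`conc/3` for each of the
two labeled subunits), reproducing the reported ~23 nM; a conservative
limiting-subunit alternative (`min/3`) is also returned.

## What the generators do and do not emulate

Emulated: exponential processivities and Gaussian rates; concentration-
dependent multisite exchange with dilution stability; irreversible
photobleaching with power scaling and FRAP pulse schedules; binomial
labeling; Gaussian PSF rendering with deposit spots; two-color foci with
the four exchange mechanisms; per-cell fluorescence with constant
autofluorescence, decaying coverslip background and stepwise-bleaching
foci.

Not emulated: diffraction beyond a Gaussian PSF, stage drift, fluorophore
blinking, channel cross-talk, cell segmentation (masks and areas are
inputs), Okazaki-fragment biochemistry, and diffusion-limited FRAP.
Passing tests therefore demonstrate correctness of the estimators under
the stated generative assumptions, not robustness to every artifact of
real microscopy.

Frame intervals are configuration entries (0.5 s in vitro, 0.1 s in vivo
by default) — the original acquisition rates are not stated, and these
values are assumptions.

## Numerical choices and problem sizes

Stochastic tests compare against closed forms within three standard
errors, computed across independent runs; residence times use the first
completed residency per run, which is an unbiased draw (residencies
completed inside a fixed window are length-biased short). EM for mixture
weights iterates to a 10⁻⁸ log-likelihood tolerance; nonlinear fits use
Levenberg–Marquardt with analytic-free restarts and flagged failures;
rendered images clip negatives at zero but trace tables never do.

The shipped test suite and acceptance script scale the study's designs to
sizes that keep the whole suite in the minutes range on one CPU — e.g.
100 FRAP traces per residence time, 300 focus pairs per mechanism (the
mechanism *replicate* study runs at 100 foci × 4 replicates), 40–100
molecules or cells for round trips, 200 random traces for the brute-force
change-point comparison. These sizes are package choices; every
comparison reports its own Monte-Carlo error where relevant.

## Known limitations

* The exchange CTMC is one concrete instantiation of multisite competitive
  exchange; its $k_{off}$ default ties the auxiliary equilibrium to the
  observed modal stoichiometry, and the same parameter set does not also
  reproduce the absolute low-concentration exchange times — the two-site
  limit is used where the closed form is the point.
* The CCF decay time equals the generative residence time only in the
  arrival-limited regime (see above); elsewhere it reports the fluctuation
  correlation time $1/(k_{on}+k_{off})$.
* Fork tracking assumes a single replicating molecule per kymograph and no
  crossing trajectories. It takes the furthest local intensity maximum in
  the allowed region, so it never locks onto a deposit behind the fork,
  but while a fresh deposit still overlaps the fork spot the centroid is
  pulled back by up to a few pixels until they separate.
* The integer-mixture fit fixes component means at exact integers; partial
  labeling shifts real components slightly below integers, which the
  normalisation absorbs only on average.
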