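#' Fit a single-exponential decay to a field background trace
#'
#' The coverslip background of a field of view photobleaches as a single
#' exponential `A * exp(-t/tau) + c`; amplitude, lifetime and offset are
#' fitted by least squares.
#'
#' @param trace Tibble with `time_s` and `intensity` (>= 10 frames).
#' @return An `expdecay_fit`: `amplitude`, `lifetime_s`, `offset`, `flag`
#'   (`"non_decaying"` when the trace does not decay).
#' @export
fit_field_background <- function(trace) {
  stopifnot(all(c("time_s", "intensity") %in% names(trace)))
  if (nrow(trace) < 10) abort("need at least 10 frames")
  t <- trace$time_s; y <- trace$intensity
  n <- length(y)
  decaying <- mean(y[seq_len(max(3, n %/% 5))]) >
    mean(y[(n - max(3, n %/% 5) + 1):n]) + 1e-12
  fit <- if (decaying) {
    lm_fit(function(p) y - (p$a * exp(-t / p$tau) + p$c0),
           start = list(a = max(y) - min(y), tau = max(t) / 3, c0 = min(y)),
           lower = c(1e-12, 1e-9, -Inf))
  } else NULL
  if (is.null(fit)) {
    warn("field background does not decay; returning flat fit")
    return(new_fit("expdecay_fit", amplitude = 0, lifetime_s = NA_real_,
                   offset = mean(y), flag = "non_decaying"))
  }
  new_fit("expdecay_fit", amplitude = fit$par$a,
          lifetime_s = fit$par$tau, offset = fit$par$c0,
          lifetime_se = unname(fit$se[["tau"]]),
          flag = NA_character_)
}

#' Correct a cell trace and fit its bleach amplitude
#'
#' Subtracts the (constant) cellular autofluorescence and the coverslip
#' background fit from the measured total-cell trace, fits the corrected
#' trace with a single exponential decay, and returns the fitted intensity
#' at `t = 0` -- the maximum cell fluorescence attributable to the labeled
#' protein.
#'
#' @param cell_trace Tibble with `time_s` and `intensity` (total cell
#'   counts).
#' @param autofluorescence Constant autofluorescence level, counts.
#' @param field_fit An `expdecay_fit` from [fit_field_background()] on the
#'   matching frame grid.
#' @return An `expdecay_fit` whose `amplitude` is the corrected t = 0
#'   intensity; negative amplitudes are flagged `"negative_amplitude"`.
#' @export
correct_and_fit_cell <- function(cell_trace, autofluorescence, field_fit) {
  stopifnot(inherits(field_fit, "expdecay_fit"))
  t <- cell_trace$time_s
  bg <- if (is.na(field_fit$lifetime_s)) {
    rep(field_fit$offset, length(t))
  } else {
    field_fit$amplitude * exp(-t / field_fit$lifetime_s) + field_fit$offset
  }
  corrected <- cell_trace$intensity - autofluorescence - bg
  fit <- fit_field_background(tibble(time_s = t, intensity = corrected))
  amp0 <- fit$amplitude + ifelse(is.na(fit$lifetime_s), 0, fit$offset)
  if (is.finite(amp0) && amp0 < 0) fit$flag <- "negative_amplitude"
  fit$amplitude <- amp0
  fit
}

#' Detect photobleaching steps by change-point analysis
#'
#' Piecewise-constant penalized least-squares fit of a focus bleaching
#' trace (cost = residual sum of squares + penalty per change point; exact
#' dynamic program, earliest change point on cost ties). Steps smaller than
#' `min_step` are merged into their neighbours. Defaults: penalty
#' `3 * sigma^2 * log(n)` and `min_step = 2 * sigma`, with `sigma` the
#' frame-difference MAD noise estimate.
#'
#' @param trace Tibble with `intensity` (>= 6 frames); `frame` optional.
#' @param penalty Penalty per segment; `NULL` for the default.
#' @param min_step Minimum retained step size, counts (`0` disables
#'   merging).
#' @return A `step_fit`: `changepoints` (first frame of each new level),
#'   `levels`, `steps` (level drops, positive for bleaching),
#'   `residual_var`.
#' @export
detect_steps <- function(trace, penalty = NULL, min_step = NULL) {
  y <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  n <- length(y)
  if (n < 6) abort("need at least 6 frames")
  sigma <- mad(diff(y)) / sqrt(2)
  if (is.null(penalty)) penalty <- max(3 * sigma^2 * log(n), 1e-12)
  if (is.null(min_step)) min_step <- 2 * sigma
  starts <- cp_segment(n, cost_const_factory(y), penalty, min_len = 1L)
  ends <- c(starts[-1] - 1L, n)
  levels <- purrr::map2_dbl(starts, ends, function(i, j) mean(y[i:j]))
  # merge steps below min_step (smallest first, recompute each time)
  repeat {
    if (length(levels) < 2) break
    drops <- abs(diff(levels))
    k <- which.min(drops)
    if (drops[k] >= min_step) break
    starts <- starts[-(k + 1)]
    ends <- c(starts[-1] - 1L, n)
    levels <- purrr::map2_dbl(starts, ends, function(i, j) mean(y[i:j]))
  }
  resid <- y - rep(levels, ends - starts + 1L)
  new_fit("step_fit",
          changepoints = starts[-1], levels = levels,
          steps = if (length(levels) > 1) -diff(levels) else numeric(0),
          residual_var = stats::var(resid), penalty = penalty,
          min_step = min_step)
}

#' Single-molecule intensity from bleaching step sizes
#'
#' Gaussian fit (mean and standard error of the mean) of a histogram of
#' photobleaching step sizes; the mean is the intensity of one fluorescent
#' molecule. A mixture-BIC heuristic flags multimodal step distributions
#' (suggesting unresolved double steps).
#'
#' @param steps Numeric vector of step sizes (>= 50).
#' @return A `calibration` (fields `unit_mean`, `unit_sd`, `sem`, `n`,
#'   `flag`).
#' @export
single_molecule_intensity <- function(steps) {
  steps <- steps[is.finite(steps) & steps > 0]
  if (length(steps) < 50) abort("need at least 50 steps")
  cal <- calibrate_single(steps)
  cal$sem <- cal$unit_sd / sqrt(cal$n)
  if (identical(cal$flag, "bimodal")) cal$flag <- "multimodal_steps"
  cal
}

#' Copy number of a labeled protein per cell
#'
#' Total cell fluorescence attributable to the label (bleach-fit amplitude
#' when available, else mean intensity times cell area) divided by the
#' single-molecule intensity.
#'
#' @param cell One-row tibble/list with either `amplitude` (counts) or
#'   `mean_intensity` and `area_px`.
#' @param cal A `calibration` from [single_molecule_intensity()].
#' @return Copies (numeric scalar).
#' @export
copy_number <- function(cell, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$unit_mean == 0) abort("calibration mean is zero")
  total <- if (!is.null(cell$amplitude) && is.finite(cell$amplitude[1])) {
    cell$amplitude[1]
  } else {
    cell$mean_intensity[1] * cell$area_px[1]
  }
  total / cal$unit_mean
}

#' Convert copies per cell to a cellular concentration
#'
#' `C [nM] = copies / (N_A * volume)`, with the volume from
#' [cell_geometry()].
#'
#' @param copies Copies per cell (>= 0).
#' @param geom A [cell_geometry()]; its default volume (2.4 fL) is the
#'   value consistent with the reported copy/concentration pairs, not a
#'   measured quantity.
#' @return Concentration in nM.
#' @export
concentration <- function(copies, geom = cell_geometry()) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (any(copies < 0)) abort("`copies` must be >= 0")
  copies / (geom$avogadro * geom$volume_fL * 1e-15) * 1e9
}

#' Pol III* complex concentration from subunit concentrations
#'
#' Each Pol III* carries `subunits_per_complex` copies of the polymerase
#' core (epsilon) and of the clamp-loader tau subunit; assuming all
#' measured subunits are complex-bound, the complex concentration is the
#' mean of the per-subunit estimates `conc/subunits`. Reports round to the
#' nearest integer nM; the unrounded value and the conservative
#' limiting-subunit alternative `min(conc)/subunits` are retained.
#'
#' @param conc_eps,conc_tau Subunit concentrations, nM.
#' @param subunits_per_complex Copies of each subunit per complex.
#' @return List with `complex_nM` (rounded), `complex_nM_unrounded`,
#'   `limiting_nM`.
#' @export
complex_concentration <- function(conc_eps, conc_tau, subunits_per_complex = 3) {
  stopifnot(conc_eps >= 0, conc_tau >= 0)
  per <- c(conc_eps, conc_tau) / subunits_per_complex
  list(
    complex_nM = round(mean(per)),
    complex_nM_unrounded = mean(per),
    limiting_nM = round(min(per))
  )
}

#' Fit a photobleaching lifetime to a decaying intensity trace
#'
#' Single-exponential fit of e.g. the mean intensity of immobilized
#' fluorophores; returns the bleach lifetime with its standard error. Flat
#' or increasing traces are flagged.
#'
#' @param trace Tibble with `time_s` and `intensity` (>= 10 frames).
#' @return An `expdecay_fit` with `lifetime_s` and `lifetime_se`.
#' @export
fit_bleach_lifetime <- function(trace) {
  fit_field_background(trace)
}
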