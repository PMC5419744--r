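#' Kinetic parameters of the multisite Pol III* exchange model
#'
#' The replisome is modelled with one *resident* polymerase site plus
#' `n_sites - 1` auxiliary (transiently vacated) binding sites. Empty
#' auxiliary sites are filled from solution at rate `k_on * conc` each and
#' emptied at `k_off`; while at least one auxiliary occupant is present the
#' resident is replaced at rate `k_handoff` (the old resident departs and one
#' auxiliary occupant, chosen uniformly, becomes the new resident). This
#' yields dilution stability (no exchange at zero concentration) and a
#' concentration-dependent exchange time of approximately
#' `1/(k_on * conc) + 1/k_handoff` in the two-site, `k_off = 0` limit.
#'
#' Default rates were chosen so that the in vitro exchange-time series over
#' 0.03--13 nM and the modal replisome stoichiometry at 6.7 nM match the
#' regimes the analysis modules are designed for; see the methods vignette.
#'
#' @param n_sites Total number of polymerase binding sites (resident +
#'   auxiliary); must be >= 1.
#' @param k_on Per-site association rate constant, 1/(nM s).
#' @param k_off Auxiliary-site dissociation rate, 1/s.
#' @param k_handoff Resident-replacement completion rate when a competitor
#'   occupies an auxiliary site, 1/s.
#' @param conc Free Pol III* concentration, nM.
#' @param cores_per_complex Labeled polymerase cores per Pol III* complex.
#' @param label_efficiency Probability that a core carries an active
#'   fluorophore.
#' @param color_fractions Named or unnamed length-2 numeric, fractions of
#'   complexes labeled in channel 1 (red) vs channel 2 (green); must sum to 1.
#' @return An object of class `exchange_params` (a validated list).
#' @export
#' @examples
#' exchange_params(conc = 6.7)
exchange_params <- function(n_sites = 3,
                            k_on = 0.55,
                            k_off = 10,
                            k_handoff = 1 / 1.7,
                            conc = 6.7,
                            cores_per_complex = 3,
                            label_efficiency = 0.85,
                            color_fractions = c(red = 0.5, green = 0.5)) {
  check_number(n_sites, "n_sites", min = 1)
  check_number(k_on, "k_on", min = 0)
  check_number(k_off, "k_off", min = 0)
  check_number(k_handoff, "k_handoff", min = 0)
  check_number(conc, "conc", min = 0)
  check_number(cores_per_complex, "cores_per_complex", min = 1)
  check_number(label_efficiency, "label_efficiency", min = 0, max = 1)
  if (length(color_fractions) != 2 || any(color_fractions < 0) ||
      abs(sum(color_fractions) - 1) > 1e-9) {
    abort("`color_fractions` must be two non-negative fractions summing to 1")
  }
  if (is.null(names(color_fractions))) names(color_fractions) <- c("red", "green")
  structure(
    list(
      n_sites = as.integer(n_sites), k_on = k_on, k_off = k_off,
      k_handoff = k_handoff, conc = conc,
      cores_per_complex = as.integer(cores_per_complex),
      label_efficiency = label_efficiency,
      color_fractions = color_fractions
    ),
    class = "exchange_params"
  )
}

#' Photophysics and illumination-schedule parameters
#'
#' Photobleaching is irreversible: each active fluorophore survives a frame of
#' duration `frame_interval_s` at relative power `p` with probability
#' `exp(-frame_interval_s * p / bleach_lifetime_s)` (power 1 is the reference
#' at which `bleach_lifetime_s` is defined). During FRAP pulse frames the
#' elevated `power_pulse` applies. Detected intensity per frame is
#' `unit_intensity` per active fluorophore plus Gaussian background.
#'
#' @param bleach_lifetime_s Mean time to photobleach per fluorophore at the
#'   reference power, seconds.
#' @param power_normal,power_pulse Relative excitation powers; the bleach rate
#'   scales linearly with power.
#' @param pulse_duration_s,pulse_period_s FRAP pulse schedule (both `NULL`
#'   disables pulsing). The first pulse starts at `t = pulse_period_s`.
#' @param unit_intensity Mean detected counts per active fluorophore per frame.
#' @param bg_mean,bg_sd Additive Gaussian background per frame (per pixel for
#'   rendered images).
#' @param frame_interval_s Time per frame, seconds.
#' @return An object of class `photo_params`.
#' @export
#' @examples
#' photo_params(bleach_lifetime_s = 14.1)
photo_params <- function(bleach_lifetime_s = 14.1,
                         power_normal = 1,
                         power_pulse = 1,
                         pulse_duration_s = NULL,
                         pulse_period_s = NULL,
                         unit_intensity = 5100,
                         bg_mean = 0,
                         bg_sd = 0,
                         frame_interval_s = 0.5) {
  check_number(bleach_lifetime_s, "bleach_lifetime_s", min = 1e-12, finite = FALSE)
  check_number(power_normal, "power_normal", min = 0)
  check_number(power_pulse, "power_pulse", min = 0)
  check_number(unit_intensity, "unit_intensity", min = 1e-12)
  check_number(bg_mean, "bg_mean")
  check_number(bg_sd, "bg_sd", min = 0)
  check_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  pulses_on <- !is.null(pulse_duration_s) || !is.null(pulse_period_s)
  if (pulses_on) {
    if (is.null(pulse_duration_s) || is.null(pulse_period_s)) {
      abort("both `pulse_duration_s` and `pulse_period_s` must be set to enable pulses")
    }
    check_number(pulse_duration_s, "pulse_duration_s", min = 1e-12)
    check_number(pulse_period_s, "pulse_period_s", min = 1e-12)
    if (pulse_duration_s >= pulse_period_s) {
      abort("`pulse_duration_s` must be shorter than `pulse_period_s`")
    }
    if (pulse_period_s < 2 * frame_interval_s) {
      abort("`pulse_period_s` must span at least 2 frames")
    }
  }
  structure(
    list(
      bleach_lifetime_s = bleach_lifetime_s,
      power_normal = power_normal, power_pulse = power_pulse,
      pulse_duration_s = pulse_duration_s, pulse_period_s = pulse_period_s,
      unit_intensity = unit_intensity, bg_mean = bg_mean, bg_sd = bg_sd,
      frame_interval_s = frame_interval_s
    ),
    class = "photo_params"
  )
}

#' Cell geometry for copy-number to concentration conversion
#'
#' The cytoplasmic volume is not a measured quantity of this workflow; the
#' default 2.4 fL is the value consistent with converting both reported
#' per-cell copy numbers into their reported nanomolar concentrations
#' (104 copies -> ~72 nM; 96 copies -> ~66 nM).
#'
#' @param volume_fL Cell volume in femtolitres.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(volume_fL = 2.4) {
  if (is.null(volume_fL) || !is.numeric(volume_fL) || is.na(volume_fL)) {
    abort("cell volume is not set; provide `volume_fL` (config key `cell.volume_fL`)")
  }
  check_number(volume_fL, "volume_fL", min = 1e-12)
  structure(
    list(volume_fL = volume_fL, avogadro = 6.02214076e23),
    class = "cell_geometry"
  )
}

# Frame grid implied by a duration and photo params (frame timestamps are the
# frame start times; frame i covers [t_i, t_i + dt)).
frame_grid <- function(duration, frame_interval_s) {
  n <- max(1L, floor(duration / frame_interval_s))
  tibble(frame = seq_len(n), time_s = (seq_len(n) - 1) * frame_interval_s)
}

# Frames (indices into frame_grid) that fall inside a FRAP pulse, plus pulse
# start frames. Returns list(pulse_frames, pulse_starts).
pulse_schedule <- function(photo, duration) {
  if (is.null(photo$pulse_period_s)) {
    return(list(pulse_frames = integer(0), pulse_starts = integer(0)))
  }
  grid <- frame_grid(duration, photo$frame_interval_s)
  starts <- seq(photo$pulse_period_s, duration, by = photo$pulse_period_s)
  in_pulse <- rep(FALSE, nrow(grid))
  start_frames <- integer(0)
  for (s in starts) {
    idx <- which(grid$time_s >= s - 1e-9 & grid$time_s < s + photo$pulse_duration_s - 1e-9)
    if (length(idx)) {
      in_pulse[idx] <- TRUE
      start_frames <- c(start_frames, idx[1])
    }
  }
  list(pulse_frames = which(in_pulse), pulse_starts = start_frames)
}
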