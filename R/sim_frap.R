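#' Simulate a single-molecule FRAP experiment
#'
#' Simulates `n_replisomes` independent replisomes under pulsed
#' illumination: exchange kinetics from [simulate_exchange()], photophysics
#' from [apply_photophysics()]. Periodic high-power pulses rapidly bleach
#' the fork-associated fluorophores; the signal recovers only through
#' exchange of unbleached complexes from solution (entering complexes carry
#' fresh fluorophores), so the recovery rate reports the exchange time.
#'
#' @param params An [exchange_params()] object. The reference in vitro FRAP
#'   condition is 23 replisomes at 3 nM with three pulses.
#' @param photo A [photo_params()] object with a pulse schedule
#'   (`pulse_period_s`, `pulse_duration_s`, `power_pulse`).
#' @param n_replisomes Number of replisomes (traces) to simulate.
#' @param duration Trace duration, seconds.
#' @param seed Integer root seed; per-trace streams are derived from it.
#' @return A tibble of intensity traces (columns `trace_id`, `frame`,
#'   `time_s`, `channel`, `intensity`, `truth_count`, `truth_active`) with
#'   the pulse schedule in `attr(, "meta")`.
#' @export
#' @examples
#' ph <- photo_params(power_pulse = 60, pulse_period_s = 25,
#'                    pulse_duration_s = 1, bg_sd = 10)
#' traces <- simulate_frap_experiment(exchange_params(conc = 3),
#'                                    ph, n_replisomes = 4,
#'                                    duration = 100, seed = 1)
simulate_frap_experiment <- function(params, photo, n_replisomes = 23,
                                     duration = 100, seed = NULL) {
  stopifnot(inherits(params, "exchange_params"), inherits(photo, "photo_params"))
  if (is.null(photo$pulse_period_s)) {
    abort("`photo` must define a FRAP pulse schedule")
  }
  if (photo$pulse_period_s < 2 * photo$frame_interval_s) {
    abort("`pulse_period_s` must span at least 2 frames")
  }
  check_number(n_replisomes, "n_replisomes", min = 1)
  traces <- purrr::map(seq_len(n_replisomes), function(i) {
    occ <- simulate_exchange(params, duration,
                             frame_interval_s = photo$frame_interval_s,
                             seed = derive_seed(seed, paste0("frap-occ-", i)))
    tr <- apply_photophysics(occ, photo,
                             seed = derive_seed(seed, paste0("frap-photo-", i)))
    mutate(tr, trace_id = i, .before = 1)
  })
  meta <- attr(traces[[1]], "meta")
  out <- purrr::list_rbind(traces)
  attr(out, "meta") <- meta
  out
}
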