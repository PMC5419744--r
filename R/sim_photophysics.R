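#' Apply photobleaching and detection noise to an occupancy trace
#'
#' Converts the ground-truth occupancy of [simulate_exchange()] into a
#' detected fluorescence intensity trace. Each fluorophore bleaches
#' irreversibly with per-frame survival probability
#' `exp(-frame_interval_s * power / bleach_lifetime_s)`; during FRAP pulse
#' frames (schedule in `photo`) the elevated `power_pulse` applies. Detected
#' intensity per channel is `unit_intensity` times the number of active
#' fluorophores of that color plus Gaussian background. Complexes entering
#' from solution carry fresh (unbleached) fluorophores, so post-pulse
#' recovery reports exchange.
#'
#' @param occ An `occupancy_trace` from [simulate_exchange()].
#' @param photo A [photo_params()] object; its `frame_interval_s` must match
#'   the occupancy trace's frame grid.
#' @param seed Integer seed (optional).
#' @return An intensity trace: a tibble with columns `frame`, `time_s`,
#'   `channel`, `intensity`, `truth_count` (bound complexes of that color)
#'   and `truth_active` (active fluorophores of that color), carrying the
#'   pulse schedule and parameters in `attr(, "meta")`. Ground truth links
#'   back to `occ`.
#' @export
#' @examples
#' occ <- simulate_exchange(exchange_params(conc = 6.7), duration = 30, seed = 1)
#' tr <- apply_photophysics(occ, photo_params(bg_sd = 20), seed = 2)
#' head(tr)
apply_photophysics <- function(occ, photo, seed = NULL) {
  stopifnot(inherits(occ, "occupancy_trace"), inherits(photo, "photo_params"))
  if (abs(photo$frame_interval_s - occ$frame_interval_s) > 1e-9) {
    abort("`photo$frame_interval_s` must match the occupancy trace frame grid")
  }
  grid <- occ$frames[, c("frame", "time_s")]
  n_frames <- nrow(grid)
  sched <- pulse_schedule(photo, occ$duration)
  power <- rep(photo$power_normal, n_frames)
  power[sched$pulse_frames] <- photo$power_pulse
  hazard <- photo$frame_interval_s * power / photo$bleach_lifetime_s

  cx <- occ$complexes
  dep <- ifelse(is.na(cx$t_depart), Inf, cx$t_depart)
  # first frame whose start time >= arrival contributes; complex present in
  # frame f iff t_arrive <= time_s[f] < t_depart
  f_a <- vapply(cx$t_arrive, function(ta) {
    idx <- which(grid$time_s >= ta - 1e-12)
    if (length(idx)) idx[1] else NA_integer_
  }, integer(1))
  f_d <- vapply(dep, function(td) {
    idx <- which(grid$time_s < td - 1e-12)
    if (length(idx)) idx[length(idx)] else 0L
  }, integer(1))

  channels <- names(occ$params$color_fractions)[occ$params$color_fractions > 0]

  with_seed_if(seed, {
    active <- matrix(0L, nrow = n_frames, ncol = length(channels),
                     dimnames = list(NULL, channels))
    bound <- matrix(0L, nrow = n_frames, ncol = length(channels),
                    dimnames = list(NULL, channels))
    for (i in seq_len(nrow(cx))) {
      if (is.na(f_a[i]) || f_d[i] < f_a[i]) next
      fr <- f_a[i]:f_d[i]
      ch <- cx$color[i]
      if (!ch %in% channels) next
      bound[fr, ch] <- bound[fr, ch] + 1L
      nf <- cx$n_fluor[i]
      if (nf == 0) next
      ch_cum <- cumsum(hazard[fr])
      for (k in seq_len(nf)) {
        e <- rexp(1)
        # active at frame j iff survived hazards of frames before j
        alive_until <- findInterval(e, c(0, ch_cum), left.open = TRUE)
        if (alive_until >= 1) {
          idx <- fr[seq_len(min(alive_until, length(fr)))]
          active[idx, ch] <- active[idx, ch] + 1L
        }
      }
    }
    out <- purrr::map(channels, function(ch) {
      tibble(
        frame = grid$frame, time_s = grid$time_s, channel = ch,
        intensity = photo$unit_intensity * active[, ch] +
          rnorm(n_frames, photo$bg_mean, photo$bg_sd),
        truth_count = bound[, ch], truth_active = active[, ch]
      )
    }) |> purrr::list_rbind()
    attr(out, "meta") <- list(
      conc = occ$params$conc, seed = seed,
      pulse_frames = sched$pulse_frames, pulse_starts = sched$pulse_starts,
      photo = photo, params = occ$params
    )
    out
  })
}

# Bleach-survival bookkeeping for a set of independent fluorophores that are
# present for the whole trace (used by calibration-field and deposit
# rendering). Returns an n_frames x n_mol logical matrix of activity.
bleach_matrix <- function(n_mol, hazard) {
  n_frames <- length(hazard)
  ch_cum <- cumsum(hazard)
  alive_until <- findInterval(rexp(n_mol), c(0, ch_cum), left.open = TRUE)
  outer(seq_len(n_frames), alive_until, `<=`)
}
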