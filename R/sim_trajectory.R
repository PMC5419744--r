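#' Simulate a single-molecule replication trajectory
#'
#' Synthesized DNA length versus time for one rolling-circle replication
#' event: total processivity is drawn from an exponential distribution,
#' per-segment rates from a Gaussian (truncated at zero), and segment
#' durations from an exponential, giving the piecewise-linear trajectories
#' seen in flow-stretched kymographs.
#'
#' @param rate_mean Mean replication rate, bp/s (default 561, the labeled
#'   polymerase rate).
#' @param rate_sd Between-segment rate standard deviation, bp/s.
#' @param processivity_mean Mean total synthesis before terminal
#'   dissociation, bp (default 73000).
#' @param segment_mean_duration Mean duration of a constant-rate segment, s.
#' @param frame_interval_s Sampling interval of the returned trajectory, s.
#' @param n_segments Force a fixed number of segments (e.g. 1 for a single
#'   constant slope); `NULL` draws segments until the processivity is
#'   exhausted.
#' @param max_duration Observation horizon, seconds; trajectories still
#'   running at the horizon are truncated there (like a finite movie).
#' @param seed Integer seed (optional).
#' @return An object of class `replication_trajectory`: list with `track`
#'   (tibble: frame, time_s, length_bp), `segments` (tibble: t_start, t_end,
#'   slope_bp_s), and `processivity_bp`. Length is non-decreasing and slopes
#'   are >= 0.
#' @export
#' @examples
#' traj <- simulate_replication_trajectory(seed = 1)
#' traj$processivity_bp
simulate_replication_trajectory <- function(rate_mean = 561,
                                            rate_sd = 27,
                                            processivity_mean = 73000,
                                            segment_mean_duration = 30,
                                            frame_interval_s = 0.5,
                                            n_segments = NULL,
                                            max_duration = 3600,
                                            seed = NULL) {
  check_number(rate_mean, "rate_mean", min = 1e-12)
  check_number(rate_sd, "rate_sd", min = 0)
  check_number(processivity_mean, "processivity_mean", min = 1e-12)
  check_number(segment_mean_duration, "segment_mean_duration", min = 1e-12)

  with_seed_if(seed, {
    processivity <- rexp(1, 1 / processivity_mean)
    t_start <- numeric(0); t_end <- numeric(0); slope <- numeric(0)
    t <- 0; len <- 0; k <- 0L
    repeat {
      k <- k + 1L
      s <- max(0, rnorm(1, rate_mean, rate_sd))
      d <- if (!is.null(n_segments) && k == n_segments) Inf else
        rexp(1, 1 / segment_mean_duration)
      # truncate where processivity is exhausted or the movie ends
      if (s > 0 && len + s * d >= processivity) d <- (processivity - len) / s
      if (is.infinite(d)) d <- segment_mean_duration
      ended <- t + d >= max_duration
      if (ended) d <- max_duration - t
      t_start <- c(t_start, t); t_end <- c(t_end, t + d); slope <- c(slope, s)
      t <- t + d; len <- len + s * d
      if (ended || len >= processivity - 1e-9) break
      if (!is.null(n_segments) && k >= n_segments) break
      if (k > 10000L) abort("segment guard exceeded")
    }
    segments <- tibble(t_start = t_start, t_end = t_end, slope_bp_s = slope)
    total_t <- max(t_end)
    grid <- frame_grid(total_t, frame_interval_s)
    # piecewise-linear length at frame times
    knots_t <- c(segments$t_start[1], segments$t_end)
    knots_len <- cumsum(c(0, segments$slope_bp_s * (segments$t_end - segments$t_start)))
    length_bp <- stats::approx(knots_t, knots_len, xout = pmin(grid$time_s, total_t),
                               rule = 2)$y
    structure(
      list(
        track = mutate(grid, length_bp = length_bp),
        segments = segments,
        processivity_bp = len,
        frame_interval_s = frame_interval_s,
        seed = seed
      ),
      class = "replication_trajectory"
    )
  })
}

#' @export
print.replication_trajectory <- function(x, ...) {
  cat("<replication_trajectory> ", nrow(x$track), " frames, ",
      nrow(x$segments), " segments, final length ",
      round(x$processivity_bp), " bp\n", sep = "")
  invisible(x)
}
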