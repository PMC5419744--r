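#' Track the replication fork in a kymograph
#'
#' Per-column detection of the leading bright spot: among pixels above a
#' robust intensity threshold and not more than `backtrack_px` behind the
#' previous fork position, the furthest-advanced pixel is taken and refined
#' to sub-pixel precision by an intensity-weighted centroid. Positions are
#' converted to synthesized DNA length via the `gamma_um_per_kb` conversion.
#' Columns with no qualifying pixel become gaps (linearly interpolated,
#' flagged); more than `max_gap_frac` gaps aborts.
#'
#' @param kymo A `kymograph`.
#' @param threshold Detection threshold in counts; default
#'   `median(image) + 5 * mad(image)`.
#' @param backtrack_px Allowed apparent backward motion, pixels.
#' @param centroid_halfwidth Half-width of the centroid refinement window,
#'   pixels.
#' @param max_gap_frac Maximum tolerated fraction of gap columns.
#' @return A `replication_trajectory` whose `track` has columns `frame`,
#'   `time_s`, `length_bp`, `gap`; `segments` is `NULL` (see
#'   [segment_trajectory()]).
#' @export
track_fork <- function(kymo, threshold = NULL, backtrack_px = 2,
                       centroid_halfwidth = 3, max_gap_frac = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  n_frames <- ncol(img)
  noise_floor <- if (is.null(threshold)) median(img) + 5 * mad(img) else threshold
  n_rows <- nrow(img)
  pos <- rep(NA_real_, n_frames)
  prev <- NULL
  for (f in seq_len(n_frames)) {
    col <- img[, f]
    sm <- moving_average(col, 3)
    allowed <- if (is.null(prev)) seq_len(n_rows) else
      seq.int(max(1L, floor(prev - backtrack_px)), n_rows)
    # adapt to the brightest structure still allowed, so a dimmed fork is
    # not lost next to brighter deposits; (near-)noiseless images fall back
    # to the fractional-peak rule rather than admitting PSF tails
    thr <- max(noise_floor, 0.2 * max(col[allowed]))
    ok <- allowed[col[allowed] >= thr]
    if (!length(ok)) next
    # furthest local maximum above threshold: the fork leads any deposit,
    # even when a deposit behind it is brighter
    is_peak <- ok[sm[ok] >= sm[pmax(ok - 1, 1)] & sm[ok] >= sm[pmin(ok + 1, n_rows)]]
    peak <- if (length(is_peak)) max(is_peak) else ok[which.max(col[ok])]
    win <- max(1, peak - centroid_halfwidth):min(n_rows, peak + centroid_halfwidth)
    w <- pmax(col[win] - min(col[win]), 0)
    pos[f] <- if (sum(w) > 0) sum(win * w) / sum(w) else peak
    prev <- pos[f]
  }
  gaps <- is.na(pos)
  if (mean(gaps) > max_gap_frac) {
    abort(sprintf("%.0f%% of columns have no detectable fork spot",
                  100 * mean(gaps)))
  }
  if (any(gaps)) {
    filled <- stats::approx(which(!gaps), pos[!gaps], xout = seq_len(n_frames),
                            rule = 2)$y
    pos[gaps] <- filled[gaps]
    warn(sprintf("interpolated %d gap column(s)", sum(gaps)))
  }
  length_bp <- px_to_bp(pos, kymo)
  track <- tibble(
    frame = seq_len(n_frames),
    time_s = (seq_len(n_frames) - 1) * kymo$frame_interval_s,
    length_bp = length_bp, gap = gaps
  )
  structure(
    list(track = track, segments = NULL,
         processivity_bp = max(length_bp),
         frame_interval_s = kymo$frame_interval_s, seed = NULL),
    class = "replication_trajectory"
  )
}

#' Segment a trajectory into constant-slope stretches
#'
#' Penalized piecewise-linear change-point fitting: minimises the residual
#' sum of squares plus `penalty` per segment, with each segment at least
#' `min_duration` long. The default penalty scales a robust noise-variance
#' estimate (from second differences) by `log(n)`, a BIC-style choice
#' calibrated on synthetic trajectories.
#'
#' @param traj A `replication_trajectory` (>= 4 frames, non-degenerate time
#'   grid).
#' @param min_duration Minimum segment duration, seconds.
#' @param penalty Penalty per additional segment, in squared-bp units;
#'   `NULL` for the default.
#' @return Tibble of segment fits: `t_start`, `t_end`, `slope_bp_s`,
#'   `intercept_bp`, `rss_bp`, `n_frames`.
#' @export
#' @examples
#' traj <- simulate_replication_trajectory(seed = 1)
#' segment_trajectory(traj)
segment_trajectory <- function(traj, min_duration = 5, penalty = NULL) {
  stopifnot(inherits(traj, "replication_trajectory"))
  tr <- traj$track
  n <- nrow(tr)
  if (n < 4) abort("need at least 4 frames to segment")
  if (diff(range(tr$time_s)) <= 0) abort("degenerate (constant-time) trajectory")
  x <- tr$time_s; y <- tr$length_bp
  dt <- median(diff(x))
  min_len <- max(2L, ceiling(min_duration / dt))
  if (is.null(penalty)) {
    sigma <- mad(diff(y, differences = 2)) / sqrt(6)
    sigma <- max(sigma, 1e-9)
    penalty <- 4 * sigma^2 * log(n)
  }
  starts <- cp_segment(n, cost_linear_factory(x, y), penalty, min_len)
  ends <- c(starts[-1] - 1L, n)
  purrr::map2(starts, ends, function(i, j) {
    fit <- lm(y[i:j] ~ x[i:j])
    tibble(
      t_start = x[i], t_end = x[j],
      slope_bp_s = unname(coef(fit)[2]),
      intercept_bp = unname(coef(fit)[1]),
      rss_bp = sum(resid(fit)^2), n_frames = j - i + 1L
    )
  }) |> purrr::list_rbind()
}

#' Fit a Gaussian to a replication-rate distribution
#'
#' Summarises constant-slope segment rates as a Gaussian mean with standard
#' error of the mean, the way rate histograms of single-molecule replication
#' assays are reported. Histogram bin width follows the Freedman--Diaconis
#' rule (recorded for plotting).
#'
#' @param slopes Numeric vector of segment rates, bp/s.
#' @return A `rate_fit` object (fields `mean`, `sem`, `sd`, `n`,
#'   `bin_width`, `flag`). With fewer than 5 slopes the sample mean is
#'   returned with `flag = "n_too_small"`.
#' @export
fit_rate_distribution <- function(slopes) {
  slopes <- slopes[is.finite(slopes)]
  n <- length(slopes)
  if (n < 1) abort("no finite slopes supplied")
  flag <- if (n < 5) "n_too_small" else NA_character_
  bw <- if (n >= 2 && stats::IQR(slopes) > 0) {
    2 * stats::IQR(slopes) / n^(1 / 3)
  } else {
    NA_real_
  }
  new_fit("rate_fit",
          mean = mean(slopes), sd = stats::sd(slopes),
          sem = if (n > 1) stats::sd(slopes) / sqrt(n) else 0,
          n = n, bin_width = bw, flag = flag, slopes = slopes)
}

#' Fit an exponential processivity distribution
#'
#' Single-molecule processivities (final product lengths) follow a single
#' exponential; the mean is fitted by the exponential maximum-likelihood
#' estimator (the sample mean of the lengths, equivalent to fitting the
#' empirical survival function), with the standard `mean/sqrt(n)` fit error.
#' Binned histograms are for display only.
#'
#' @param final_lengths Positive lengths, bp (>= 10 values).
#' @return A `processivity_fit` (fields `mean`, `se`, `n`, `flag`).
#' @export
fit_processivity <- function(final_lengths) {
  if (any(!is.finite(final_lengths)) || any(final_lengths <= 0)) {
    abort("processivities must be positive and finite")
  }
  n <- length(final_lengths)
  if (n < 10) abort("need at least 10 molecules")
  flag <- NA_character_
  if (stats::sd(final_lengths) == 0) {
    warn("degenerate processivity distribution (all lengths equal)")
    flag <- "degenerate"
  }
  new_fit("processivity_fit",
          mean = mean(final_lengths), se = mean(final_lengths) / sqrt(n),
          n = n, flag = flag, lengths = final_lengths)
}
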