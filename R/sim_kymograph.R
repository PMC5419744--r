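#' Construct a kymograph object
#'
#' A position-by-time image with the metadata needed to convert pixels to
#' DNA lengths: pixel size, frame interval, and the flow-stretch conversion
#' factor `gamma_um_per_kb` (default 2.1 um per 7.2 kb of stretched DNA).
#'
#' @param image Numeric matrix indexed `[position, time]`, counts.
#' @param pixel_size_um Pixel size along the DNA axis, micrometres.
#' @param frame_interval_s Time per column, seconds.
#' @param gamma_um_per_kb Stretched extent per kb of DNA, um/kb.
#' @param origin_px Row (1-based, can be fractional) corresponding to zero
#'   synthesized DNA.
#' @param truth Optional `replication_trajectory` ground truth.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(image, pixel_size_um = 0.16, frame_interval_s = 0.5,
                      gamma_um_per_kb = 2.1 / 7.2, origin_px = 1,
                      truth = NULL) {
  stopifnot(is.matrix(image))
  check_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  check_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  check_number(gamma_um_per_kb, "gamma_um_per_kb", min = 1e-12)
  structure(
    list(image = image, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         gamma_um_per_kb = gamma_um_per_kb, origin_px = origin_px,
         truth = truth),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph> ", nrow(x$image), " px x ", ncol(x$image), " frames (",
      signif(x$pixel_size_um, 3), " um/px, ",
      signif(x$frame_interval_s, 3), " s/frame)\n", sep = "")
  invisible(x)
}

# bp <-> pixel conversions
bp_to_px <- function(length_bp, kymo) {
  kymo$origin_px + kymo$gamma_um_per_kb * (length_bp / 1000) / kymo$pixel_size_um
}
px_to_bp <- function(row_px, kymo) {
  (row_px - kymo$origin_px) * kymo$pixel_size_um / kymo$gamma_um_per_kb * 1000
}

#' Render a synthetic kymograph from a replication trajectory
#'
#' Draws the moving replisome spot of a flow-stretched rolling-circle
#' product as a Gaussian point-spread profile whose row follows
#' `gamma_um_per_kb * length(t)`, plus optional stationary spots deposited by
#' polymerases that leave the fork (visible as horizontal lines unless Pol I
#' is present to process Okazaki fragments, in which case they are not
#' drawn). Total spot photon count per column equals the spot intensity
#' regardless of position. Gaussian background noise is added and negative
#' rendered pixels are clipped at zero (images only; trace tables are never
#' clipped).
#'
#' @param traj A `replication_trajectory`.
#' @param photo A [photo_params()] object (background, unit intensity, frame
#'   interval; the frame interval must match the trajectory grid).
#' @param occ Optional `occupancy_trace` on the same frame grid; its active
#'   complex count modulates fork-spot brightness, and complexes departing
#'   the fork deposit stationary bleaching spots.
#' @param fork_intensity Fork-spot photon count per frame (scalar or
#'   per-frame vector); default `unit_intensity` per frame. Ignored when
#'   `occ` is given.
#' @param pol1_present If `TRUE`, deposited spots are omitted (Pol I removes
#'   the flaps the departing polymerases stay bound to).
#' @param pixel_size_um,gamma_um_per_kb,psf_sigma_px Rendering geometry.
#' @param n_rows Image height in pixels; default fits the trajectory with a
#'   margin. A trajectory exceeding a user-set height is a geometry error.
#' @param seed Integer seed (optional).
#' @return A `kymograph` with the trajectory attached as truth.
#' @export
#' @examples
#' traj <- simulate_replication_trajectory(seed = 1)
#' kym <- render_kymograph(traj, photo_params(bg_mean = 10, bg_sd = 2), seed = 2)
render_kymograph <- function(traj, photo, occ = NULL, fork_intensity = NULL,
                             pol1_present = FALSE,
                             pixel_size_um = 0.16,
                             gamma_um_per_kb = 2.1 / 7.2,
                             psf_sigma_px = 1.2, n_rows = NULL, seed = NULL) {
  stopifnot(inherits(traj, "replication_trajectory"),
            inherits(photo, "photo_params"))
  track <- traj$track
  n_frames <- nrow(track)
  margin <- ceiling(5 * psf_sigma_px)
  kym0 <- list(origin_px = 1 + margin, gamma_um_per_kb = gamma_um_per_kb,
               pixel_size_um = pixel_size_um)
  pos <- kym0$origin_px + gamma_um_per_kb * (track$length_bp / 1000) / pixel_size_um
  need_rows <- ceiling(max(pos)) + margin
  if (is.null(n_rows)) {
    n_rows <- need_rows
  } else if (need_rows > n_rows) {
    abort("fork excursion exceeds the image extent", class = "polexchange_geometry_error")
  }

  if (is.null(fork_intensity)) fork_intensity <- photo$unit_intensity
  fork_int <- rep_len(fork_intensity, n_frames)

  with_seed_if(seed, {
    if (!is.null(occ)) {
      stopifnot(inherits(occ, "occupancy_trace"))
      # occupancy grid may be one frame short of the trajectory grid
      idx <- pmin(seq_len(n_frames), nrow(occ$frames))
      fork_int <- photo$unit_intensity * occ$frames$n_bound[idx]
    }
    img <- matrix(0, nrow = n_rows, ncol = n_frames)
    rows <- seq_len(n_rows)
    for (f in seq_len(n_frames)) {
      img[, f] <- img[, f] + fork_int[f] * dnorm(rows, pos[f], psf_sigma_px)
    }
    if (!pol1_present && !is.null(occ)) {
      dep <- occ$complexes[!is.na(occ$complexes$t_depart), , drop = FALSE]
      hazard <- photo$frame_interval_s * photo$power_normal / photo$bleach_lifetime_s
      for (i in seq_len(nrow(dep))) {
        f0 <- findInterval(dep$t_depart[i], track$time_s)
        if (f0 < 1 || f0 > n_frames || dep$n_fluor[i] == 0) next
        frames_left <- n_frames - f0 + 1L
        # each fluorophore of the deposit bleaches independently
        alive <- findInterval(rexp(dep$n_fluor[i]), c(0, cumsum(rep(hazard, frames_left))),
                              left.open = TRUE)
        n_active <- vapply(seq_len(frames_left), function(k) sum(alive >= k), integer(1))
        prof <- dnorm(rows, pos[f0], psf_sigma_px)
        for (k in seq_len(frames_left)) {
          if (n_active[k] == 0) break
          img[, f0 + k - 1L] <- img[, f0 + k - 1L] +
            photo$unit_intensity * n_active[k] * prof
        }
      }
    }
    if (photo$bg_mean != 0 || photo$bg_sd > 0) {
      img <- img + matrix(rnorm(length(img), photo$bg_mean, photo$bg_sd),
                          nrow = n_rows)
      img[img < 0] <- 0
    }
    kymograph(img, pixel_size_um = pixel_size_um,
              frame_interval_s = traj$frame_interval_s,
              gamma_um_per_kb = gamma_um_per_kb,
              origin_px = kym0$origin_px, truth = traj)
  })
}
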