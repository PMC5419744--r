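#' Integrate spot intensity with local background subtraction
#'
#' Sums counts in a fixed-radius disc around the tracked spot position and
#' subtracts the median of a surrounding annulus times the disc area, per
#' frame -- the standard integrated-intensity measurement for single
#' fluorophore calibration and replisome-spot photometry.
#'
#' @param stack Numeric 3-D array `[x, y, frame]` (or a matrix for a single
#'   frame).
#' @param track Tibble with columns `frame`, `x`, `y` (pixel coordinates of
#'   the spot centre per frame).
#' @param r_disc Integration disc radius, pixels.
#' @param r_annulus Length-2 inner/outer radii of the background annulus.
#' @return Tibble `frame`, `intensity` (net counts), `edge` (flag: disc or
#'   annulus touched the image edge).
#' @export
integrate_spot <- function(stack, track, r_disc = 4, r_annulus = c(6, 9)) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3, all(c("frame", "x", "y") %in% names(track)))
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  purrr::pmap(track, function(frame, x, y, ...) {
    if (frame < 1 || frame > dim(stack)[3]) abort("track frame outside stack")
    img <- stack[, , frame]
    xr <- max(1, floor(x - r_annulus[2])):min(nx, ceiling(x + r_annulus[2]))
    yr <- max(1, floor(y - r_annulus[2])):min(ny, ceiling(y + r_annulus[2]))
    edge <- (x - r_annulus[2] < 1) || (x + r_annulus[2] > nx) ||
      (y - r_annulus[2] < 1) || (y + r_annulus[2] > ny)
    dd <- outer(xr - x, yr - y, function(a, b) sqrt(a^2 + b^2))
    sub <- img[xr, yr, drop = FALSE]
    disc <- dd <= r_disc
    ann <- dd > r_annulus[1] & dd <= r_annulus[2]
    bg <- if (any(ann)) median(sub[ann]) else 0
    tibble(frame = frame, intensity = sum(sub[disc]) - bg * sum(disc),
           edge = edge)
  }) |> purrr::list_rbind()
}

#' Calibrate the single-fluorophore (or single-core) intensity
#'
#' Gaussian fit (mean and sd) of a set of integrated single-spot
#' intensities. A bimodality heuristic (Gaussian mixture BIC, 1 vs 2
#' components) flags inputs that look like a mixture, e.g. double spots.
#'
#' @param intensities Numeric vector of integrated spot intensities
#'   (>= 20 values).
#' @param channel Optional channel label carried into the result.
#' @return A `calibration` object (fields `unit_mean`, `unit_sd`, `n`,
#'   `channel`, `flag`).
#' @export
calibrate_single <- function(intensities, channel = NA_character_) {
  intensities <- intensities[is.finite(intensities)]
  n <- length(intensities)
  if (n < 20) abort("need at least 20 spots to calibrate")
  flag <- NA_character_
  if (stats::sd(intensities) > 0) {
    bic <- tryCatch({
      m <- mclust::mclustBIC(intensities, G = 1:2, verbose = FALSE)
      suppressWarnings(c(max(m[1, ], na.rm = TRUE), max(m[2, ], na.rm = TRUE)))
    }, error = function(e) c(0, -Inf))
    if (is.finite(bic[2]) && bic[2] > bic[1] + 10) flag <- "bimodal"
  }
  new_fit("calibration",
          unit_mean = mean(intensities), unit_sd = stats::sd(intensities),
          n = n, channel = channel, flag = flag)
}

#' Convert a replisome-spot intensity trace into Pol III* counts
#'
#' Divides background-corrected spot intensities by the intensity of a
#' single Pol III* complex, `cores_per_complex * label_efficiency *
#' unit_mean` (the single-core calibration scaled to a full complex; set
#' `cores_per_complex = 1, label_efficiency = 1` to normalise by a single
#' core instead -- both conventions are reported in the result metadata).
#'
#' @param spot Intensity trace tibble with columns `frame`, `intensity`
#'   (single channel), e.g. from [integrate_spot()] or
#'   [apply_photophysics()].
#' @param cal A `calibration` from [calibrate_single()].
#' @param cores_per_complex,label_efficiency Complex-normalisation factors.
#' @return A `stoichiometry_result`: fields `counts` (tibble frame, count),
#'   `unit_per_complex`, `normalisation` metadata; see
#'   [fit_integer_mixture()] for the mixture-model summary.
#' @export
stoichiometry_series <- function(spot, cal, cores_per_complex = 3,
                                 label_efficiency = 0.85) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$unit_mean == 0) abort("calibration mean is zero")
  unit <- cores_per_complex * label_efficiency * cal$unit_mean
  counts <- tibble(frame = spot$frame, count = spot$intensity / unit)
  new_fit("stoichiometry_result",
          counts = counts, unit_per_complex = unit,
          normalisation = list(cores_per_complex = cores_per_complex,
                               label_efficiency = label_efficiency,
                               unit_mean = cal$unit_mean,
                               per_core_alternative = cal$unit_mean))
}

#' Fit an integer-centered Gaussian mixture to stoichiometry counts
#'
#' Mixture of `K` Gaussians with fixed means at the integers `1..K` and
#' fixed sds `sqrt(n) * rel_sd` (independent-emitter variance addition,
#' `rel_sd = unit_sd/unit_mean` from the calibration); only the component
#' weights are free, estimated by EM. The modal stoichiometry is the
#' component with the largest weight.
#'
#' @param counts Numeric vector of per-frame (or per-molecule) complex
#'   counts.
#' @param K Number of integer components (the 6.7 nM condition uses 4, the
#'   0.3 nM condition 3).
#' @param rel_sd Relative sd of a single-complex intensity.
#' @param tol,max_iter EM convergence controls.
#' @return An `integer_mixture` fit: `weights` (length K, sum 1), `K`,
#'   `mode` (argmax weight), `loglik`, `flag`.
#' @export
fit_integer_mixture <- function(counts, K = 4, rel_sd = 0.2,
                                tol = 1e-8, max_iter = 500) {
  counts <- counts[is.finite(counts)]
  if (!length(counts)) abort("`counts` is empty")
  check_number(K, "K", min = 1)
  K <- as.integer(K)
  flag <- if (K > max(counts) + 1) "K_exceeds_data" else NA_character_
  mu <- seq_len(K)
  sigma <- sqrt(mu) * rel_sd
  w <- rep(1 / K, K)
  dens <- vapply(seq_len(K), function(k) dnorm(counts, mu[k], sigma[k]),
                 numeric(length(counts)))
  dens <- pmax(dens, 1e-300)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, `*`)
    tot <- rowSums(num)
    r <- num / tot
    w <- colMeans(r)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  new_fit("integer_mixture",
          weights = as.numeric(w), K = K, mode = which.max(w),
          loglik = ll, rel_sd = rel_sd, n = length(counts), flag = flag)
}

#' Two-color spot colocalization fraction
#'
#' Fraction of A-spots with a B-spot within `radius`, using mutual
#' nearest-neighbor matching so that each spot is matched at most once (no
#' double counting).
#'
#' @param spotsA,spotsB Tibbles/data frames with columns `x`, `y` (pixels).
#' @param radius Matching radius, pixels.
#' @return Scalar fraction in `[0, 1]`; `NaN` with a warning when A is
#'   empty.
#' @export
colocalization_fraction <- function(spotsA, spotsB, radius) {
  if (nrow(spotsA) == 0) {
    warn("empty A-spot list; colocalization undefined")
    return(NaN)
  }
  if (nrow(spotsB) == 0) return(0)
  d <- outer(seq_len(nrow(spotsA)), seq_len(nrow(spotsB)), function(i, j) {
    sqrt((spotsA$x[i] - spotsB$x[j])^2 + (spotsA$y[i] - spotsB$y[j])^2)
  })
  matched <- 0L
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
    if (d[m[1], m[2]] > radius) break
    matched <- matched + 1L
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  matched / nrow(spotsA)
}
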