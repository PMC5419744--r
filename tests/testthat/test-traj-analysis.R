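test_that("fork tracking recovers the generative trajectory on clean kymographs", {
  traj <- simulate_replication_trajectory(processivity_mean = 20000, seed = 11)
  kym <- render_kymograph(traj, photo_params(bg_mean = 0, bg_sd = 0), seed = 12)
  rec <- track_fork(kym)
  half_px_bp <- 0.5 * kym$pixel_size_um / kym$gamma_um_per_kb * 1000
  expect_lt(max(abs(rec$track$length_bp - traj$track$length_bp)), half_px_bp)
})

test_that("the tracker follows the moving tip, not stationary deposits", {
  traj <- simulate_replication_trajectory(processivity_mean = 40000,
                                          rate_sd = 0, n_segments = 1, seed = 13)
  # sparse exchange so deposits appear as distinct horizontal lines
  occ <- simulate_exchange(exchange_params(conc = 0.3, k_off = 0.3),
                           duration = max(traj$track$time_s), seed = 14)
  kym <- render_kymograph(traj, photo_params(bg_mean = 5, bg_sd = 1),
                          occ = occ, pol1_present = FALSE, seed = 15)
  rec <- suppressWarnings(track_fork(kym))
  px_bp <- kym$pixel_size_um / kym$gamma_um_per_kb * 1000
  err_px <- abs(rec$track$length_bp - traj$track$length_bp) / px_bp
  # a deposit overlapping the fork perturbs the centroid briefly, but the
  # tracker must never lock onto one: a locked tracker's error would grow
  # without bound (~0.8 px/frame here), while tip-following keeps the error
  # within a few spot widths and ends on the tip
  expect_lt(max(err_px, na.rm = TRUE), 8)
  expect_lt(median(err_px, na.rm = TRUE), 2)
  expect_lt(tail(err_px[!is.na(err_px)], 1), 5)
})

test_that("a noiseless constant-slope trajectory yields exactly one exact segment", {
  traj <- make_piecewise(480, 100, noise_sd = 0)
  segs <- segment_trajectory(traj, min_duration = 2)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$slope_bp_s, 480, tolerance = 1e-9)
})

test_that("a two-segment trajectory is recovered with accurate breakpoint and slopes", {
  traj <- make_piecewise(c(500, 250), c(100, 100), noise_sd = 50, seed = 21)
  segs <- segment_trajectory(traj, min_duration = 2)
  expect_equal(nrow(segs), 2)
  true_break <- traj$track$time_s[100]
  expect_lt(abs(segs$t_end[1] - true_break), 3 * 0.5)
  expect_lt(abs(segs$slope_bp_s[1] - 500) / 500, 0.10)
  expect_lt(abs(segs$slope_bp_s[2] - 250) / 250, 0.10)
})

test_that("piecewise-linear segmentation equals exhaustive enumeration on short traces", {
  # independent reference: enumerate all breakpoint placements (<= 3) and
  # minimise the same RSS + penalty * segments cost with lm() fits
  brute_linear <- function(x, y, penalty, min_len) {
    n <- length(y)
    seg_rss <- function(i, j) {
      if (j - i + 1 < min_len) return(Inf)
      sum(resid(lm(y[i:j] ~ x[i:j]))^2)
    }
    best <- NULL; best_cost <- Inf
    for (k in 0:3) {
      combos <- if (k == 0) list(integer(0)) else
        utils::combn(n - 1, k, simplify = FALSE)
      for (b in combos) {
        starts <- c(1L, b + 1L); ends <- c(b, n)
        cost <- sum(mapply(seg_rss, starts, ends)) + penalty * (k + 1)
        if (cost < best_cost - 1e-9) { best_cost <- cost; best <- starts }
      }
    }
    best
  }
  set.seed(31)
  for (case in 1:12) {
    n_seg <- sample(1:3, 1)
    traj <- make_piecewise(runif(n_seg, 100, 800),
                           rep(8, n_seg) + sample(0:4, n_seg, replace = TRUE),
                           noise_sd = 30, seed = 300 + case)
    x <- traj$track$time_s; y <- traj$track$length_bp
    penalty <- 30^2 * 8
    segs <- segment_trajectory(traj, min_duration = 2 * 0.5, penalty = penalty)
    got_starts <- match(segs$t_start, x)
    want_starts <- brute_linear(x, y, penalty, min_len = 2)
    expect_equal(got_starts, want_starts)
  }
})

test_that("segment count grows and cost shrinks as the penalty decreases", {
  traj <- make_piecewise(c(600, 300, 500), c(40, 40, 40), noise_sd = 40, seed = 41)
  pens <- c(1e7, 1e6, 1e5, 1e4)
  fits <- purrr::map(pens, function(p) segment_trajectory(traj, min_duration = 1,
                                                          penalty = p))
  n_segs <- vapply(fits, nrow, integer(1))
  rss <- vapply(fits, function(f) sum(f$rss_bp), numeric(1))
  expect_true(all(diff(n_segs) >= 0))
  expect_true(all(diff(rss) <= 1e-6))
})

test_that("rate distributions are summarised as Gaussian mean with sem", {
  f0 <- fit_rate_distribution(rep(500, 20))
  expect_equal(f0$mean, 500)
  expect_equal(f0$sem, 0)
  slopes <- withr::with_seed(51, rnorm(500, 492, 120))
  f <- fit_rate_distribution(slopes)
  expect_lt(abs(f$mean - 492), 2 * f$sem + 2 * 120 / sqrt(500))
  expect_lt(abs(f$mean - mean(slopes)) / mean(slopes), 0.02)
  expect_equal(fit_rate_distribution(rnorm(3, 100))$flag, "n_too_small")
  expect_s3_class(tidy(f), "tbl_df")
})

test_that("processivity is fitted by the exponential MLE on final lengths", {
  lens <- withr::with_seed(61, rexp(1000, 1 / 73000))
  f <- fit_processivity(lens)
  expect_lt(abs(f$mean - 73000) / 73000, 0.10)
  expect_equal(f$mean, mean(lens), tolerance = 1e-12)  # MLE = sample mean
  expect_warning(fd <- fit_processivity(rep(5000, 20)), "degenerate")
  expect_equal(fd$mean, 5000)
  expect_error(fit_processivity(c(-1, rep(1, 20))), "positive")
})

test_that("challenge-level short processivities are recovered within 15%", {
  lens <- vapply(1:500, function(s) {
    simulate_replication_trajectory(processivity_mean = 3500,
                                    frame_interval_s = 5,
                                    seed = 700 + s)$processivity_bp
  }, numeric(1))
  f <- fit_processivity(lens)
  expect_lt(abs(f$mean - 3500) / 3500, 0.15)
})

test_that("simulate-render-track-segment round trip recovers rates and processivities", {
  res <- purrr::map(1:40, function(s) {
    traj <- simulate_replication_trajectory(processivity_mean = 15000,
                                            segment_mean_duration = 15, seed = s)
    if (nrow(traj$track) < 15) return(NULL)  # movie too short to segment
    kym <- render_kymograph(traj, photo_params(bg_mean = 2, bg_sd = 0.5), seed = s)
    rec <- suppressWarnings(track_fork(kym))
    segs <- segment_trajectory(rec, min_duration = 3)
    list(slopes = segs$slope_bp_s, weights = segs$n_frames,
         final = max(rec$track$length_bp), truth_final = traj$processivity_bp)
  }) |> purrr::compact()
  slopes <- unlist(purrr::map(res, "slopes"))
  weights <- unlist(purrr::map(res, "weights"))
  rate_hat <- sum(slopes * weights) / sum(weights)
  expect_lt(abs(rate_hat - 561) / 561, 0.05)
  finals <- vapply(res, `[[`, 0, "final")
  truth <- vapply(res, `[[`, 0, "truth_final")
  f <- fit_processivity(finals)
  expect_lt(abs(f$mean - mean(truth)) / mean(truth), 0.10)
})
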