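test_that("normalized CCF has exact unit peak, bounds, and swap symmetry", {
  x <- withr::with_seed(111, make_trace(rnorm(200), dt = 0.1))
  same <- cross_correlation(x, x, max_lag_s = 2)
  expect_equal(same$ccf[same$lag_frames == 0], 1, tolerance = 1e-12)
  neg <- x; neg$intensity <- -neg$intensity
  anti <- cross_correlation(x, neg, max_lag_s = 2)
  expect_equal(anti$ccf[anti$lag_frames == 0], -1, tolerance = 1e-12)
  for (s in 1:10) {
    a <- withr::with_seed(200 + s, make_trace(rnorm(150) + sin(1:150 / 9), dt = 0.1))
    b <- withr::with_seed(300 + s, make_trace(rnorm(150), dt = 0.1))
    ab <- cross_correlation(a, b, max_lag_s = 3)
    ba <- cross_correlation(b, a, max_lag_s = 3)
    expect_true(all(abs(ab$ccf) <= 1 + 1e-12))
    expect_equal(ab$ccf, rev(ba$ccf), tolerance = 1e-10)
  }
})

test_that("independent white noise stays inside the 4/sqrt(T) band", {
  T_len <- 400
  inside <- unlist(purrr::map(1:100, function(s) {
    a <- withr::with_seed(1000 + s, make_trace(rnorm(T_len), dt = 0.1))
    b <- withr::with_seed(2000 + s, make_trace(rnorm(T_len), dt = 0.1))
    cc <- cross_correlation(a, b, max_lag_s = 2)
    abs(cc$ccf) < 4 / sqrt(T_len)
  }))
  expect_gte(mean(inside), 0.95)
})

test_that("a zero-variance channel is flagged as undefined", {
  a <- make_trace(rep(5, 100), dt = 0.1)
  b <- withr::with_seed(7, make_trace(rnorm(100), dt = 0.1))
  expect_warning(cc <- cross_correlation(a, b, max_lag_s = 1), "zero-variance")
  expect_true(all(is.na(cc$ccf)))
})

test_that("moving-average preprocessing reduces white-noise variance as 1/n", {
  y <- withr::with_seed(121, rnorm(4000))
  tr <- make_trace(y, dt = 0.1)
  sm <- preprocess_focus_trace(tr, window_s = 2, detrend = "none")
  mid <- 100:3900  # full windows only
  ratio <- var(y[mid]) / var(sm$intensity[mid])
  expect_lt(abs(ratio - 20) / 20, 0.20)
  # identity cases
  expect_equal(preprocess_focus_trace(tr, window_s = 0.1, detrend = "none"),
               tr)
  const <- make_trace(rep(3, 50), dt = 0.1)
  expect_equal(preprocess_focus_trace(const, window_s = 1,
                                      detrend = "none")$intensity,
               rep(3, 50))
  expect_error(preprocess_focus_trace(const, window_s = 100), "window")
})

test_that("averaging identical pairs reproduces the single-pair curve", {
  tr <- simulate_invivo_pair("complex_exchange", n_foci = 1, n_frames = 200,
                             seed = 17)
  rep10 <- purrr::list_rbind(purrr::map(1:10, function(i) {
    d <- tr; d$focus_id <- i; d
  }))
  attr(rep10, "meta") <- attr(tr, "meta")
  c1 <- average_ccf(tr, max_lag_s = 2)
  c10 <- average_ccf(rep10, max_lag_s = 2)
  expect_equal(c1$ccf, c10$ccf, tolerance = 1e-12)
  expect_equal(attr(c10, "meta")$n_pairs, 10)
})

test_that("complex-exchange event logs depart synchronously in both channels", {
  tr <- simulate_invivo_pair("complex_exchange", n_foci = 20, n_frames = 300,
                             seed = 19)
  ev <- attr(tr, "events")
  for (f in unique(ev$focus_id)) {
    d1 <- ev$frame[ev$focus_id == f & ev$channel == "ch1" & ev$event == "depart"]
    d2 <- ev$frame[ev$focus_id == f & ev$channel == "ch2" & ev$event == "depart"]
    expect_identical(d1, d2)
  }
})

test_that("the CCF decay fit is exact on its own functional form and flags flat curves", {
  lags <- -20:20
  curve <- tibble::tibble(lag_frames = lags, lag_s = lags * 1.0,
                          ccf = 0.5 * exp(-abs(lags) / 4))
  attr(curve, "meta") <- list(n_pairs = 1, frame_interval_s = 1)
  class(curve) <- c("ccf_curve", class(curve))
  fit <- fit_ccf_decay(curve)
  expect_equal(fit$tau, 4, tolerance = 1e-6)
  flat <- curve; flat$ccf <- rep(-0.01, length(lags))
  expect_equal(fit_ccf_decay(flat)$flag, "no_decay")
})

test_that("the fitted CCF decay time tracks the generative residence time", {
  tr <- simulate_invivo_pair(
    "complex_exchange", k_on_frames = 0.0025, k_off_frames = 0.025,
    n_frames = 3000, n_foci = 300, seed = 23,
    photo = photo_params(bleach_lifetime_s = 1e5, unit_intensity = 150,
                         bg_sd = 10, frame_interval_s = 1))
  avg <- average_ccf(tr, max_lag_s = 100, preprocess = list(detrend = "none"))
  fit <- suppressWarnings(fit_ccf_decay(avg))
  expect_lt(abs(fit$tau - 40) / 40, 0.25)
})

test_that("randomized cross-cell pairing is reproducible and destroys same-cell correlation", {
  # synthetic cells: both channels share a per-cell latent signal
  n_cells <- 12; n_frames <- 200
  traces <- withr::with_seed(131, purrr::list_rbind(purrr::map(1:n_cells, function(c0) {
    latent <- cumsum(rnorm(n_frames))
    purrr::list_rbind(purrr::map(c("ch1", "ch2"), function(ch) {
      tibble::tibble(focus_id = c0, cell_id = c0, frame = 1:n_frames,
                     time_s = (1:n_frames) * 0.1, channel = ch,
                     intensity = latent + rnorm(n_frames, 0, 0.3))
    }))
  })))
  same <- average_ccf(traces, max_lag_s = 1, preprocess = list(detrend = "none"))
  expect_gt(same$ccf[same$lag_frames == 0], 0.8)
  r1 <- randomized_control(traces, max_lag_s = 1, seed = 5,
                           preprocess = list(detrend = "none"))
  r2 <- randomized_control(traces, max_lag_s = 1, seed = 5,
                           preprocess = list(detrend = "none"))
  expect_equal(r1$ccf, r2$ccf, tolerance = 1e-12)
  expect_lt(r1$ccf[r1$lag_frames == 0], 0.2)
  expect_error(randomized_control(dplyr::filter(traces, cell_id == 1), 1),
               "2 cells")
})

test_that("mechanism discrimination matches the expected qualitative pattern", {
  # scaled-down replicate study (100 foci per run)
  labels <- purrr::map(1:4, function(r) {
    vapply(c("complex_exchange", "no_exchange", "core_only_exchange",
             "uncoupled"), function(m) {
      classify_sim_mechanism(m, n_foci = 100, seed = 10000 * r)$label
    }, character(1))
  })
  lab <- do.call(rbind, labels)
  expect_true(all(lab[, "complex_exchange"] == "positive_peak"))
  n_null <- sum(lab[, c("no_exchange", "core_only_exchange", "uncoupled")] == "flat")
  expect_gte(n_null, 11)  # at most one stray call among 12 null runs
})

test_that("mismatched lag grids are rejected by the classifier", {
  tr <- simulate_invivo_pair("no_exchange", n_foci = 6, n_frames = 120,
                             cell_ids = rep(1:3, each = 2), seed = 31)
  avg <- average_ccf(tr, max_lag_s = 1)
  null <- ccf_null_distribution(tr, max_lag_s = 2, n_draws = 120,
                                n_single = 60, seed = 32)
  expect_error(classify_mechanism(avg, null), "lag grids")
})
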