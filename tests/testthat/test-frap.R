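test_that("pulses are found from metadata exactly and by detection within one frame", {
  traces <- simulate_frap_experiment(frap_params(5), frap_photo(25),
                                     n_replisomes = 1, duration = 90, seed = 3)
  meta_starts <- attr(traces, "meta")$pulse_starts
  expect_equal(locate_pulses(traces), meta_starts)
  one <- dplyr::filter(traces, trace_id == 1)
  attr(one, "meta") <- NULL  # force detection mode
  det <- locate_pulses(one)
  expect_equal(length(det), length(meta_starts))
  expect_true(all(abs(det - meta_starts) <= 2))
  flat <- make_trace(rep(1000, 200))
  expect_error(locate_pulses(flat), class = "polexchange_no_pulses")
})

test_that("recovery windows are normalized and averaged arithmetically", {
  # two single-pulse traces with hand-built post-pulse values; steady state 1
  build <- function(vals) {
    y <- c(rep(1, 12), 0, vals)
    tr <- make_trace(y)
    tr$trace_id <- 1L
    tr$channel <- "red"
    tr
  }
  a <- build(c(0.2, 0.6, 0.9)); b <- build(c(0.4, 0.6, 0.7))
  b$trace_id <- 2L
  both <- dplyr::bind_rows(a, b)
  curve <- extract_and_average_recovery(both, pulse_starts = 13, pulse_len = 1,
                                        background = 0)
  expect_equal(curve$intensity_norm, c(0.3, 0.6, 0.8), tolerance = 1e-12)
  expect_equal(attr(curve, "meta")$n_traces, 2)
})

test_that("ineffective pulses give a flat curve at unity", {
  ph <- frap_photo(25)
  ph$power_pulse <- ph$power_normal
  traces <- simulate_frap_experiment(frap_params(5), ph, n_replisomes = 10,
                                     duration = 90, seed = 5)
  curve <- extract_and_average_recovery(traces)
  expect_lt(mean(abs(curve$intensity_norm - 1)), 0.08)
})

test_that("the exchange-time fit is exact on its own functional form", {
  t <- seq(0, 10, by = 0.25)
  curve <- tibble::tibble(time_since_pulse_s = t,
                          intensity_norm = 1 - exp(-t / 2))
  class(curve) <- c("recovery_curve", class(curve))
  fit <- fit_exchange_time(curve)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
})

test_that("no recovery at zero concentration is flagged", {
  p0 <- exchange_params(n_sites = 2, conc = 0, k_off = 0)
  traces <- simulate_frap_experiment(p0, frap_photo(25), n_replisomes = 15,
                                     duration = 90, seed = 7)
  curve <- extract_and_average_recovery(traces)
  fit <- suppressWarnings(fit_exchange_time(curve))
  expect_equal(fit$flag, "no_recovery")
})

test_that("recovery curves are invariant to uniform intensity rescaling", {
  ph <- frap_photo(25); ph$bg_mean <- 0; ph$bg_sd <- 0
  traces <- simulate_frap_experiment(frap_params(5), ph, n_replisomes = 5,
                                     duration = 90, seed = 9)
  c1 <- extract_and_average_recovery(traces)
  scaled <- traces
  scaled$intensity <- scaled$intensity * 37
  attr(scaled, "meta") <- attr(traces, "meta")
  c2 <- extract_and_average_recovery(scaled)
  expect_equal(c1$intensity_norm, c2$intensity_norm, tolerance = 1e-6)
})

test_that("generative residence times are recovered end to end within 15%", {
  # study size (100 traces); the short residence time has the largest
  # relative Monte-Carlo error, so it gets the full ensemble
  fit2 <- fit_frap_tau(2, n_traces = 100, seed = 13)
  expect_lt(abs(fit2$tau - 2) / 2, 0.15)
  fit40 <- fit_frap_tau(40, n_traces = 100, seed = 51)
  expect_lt(abs(fit40$tau - 40) / 40, 0.15)
})

test_that("the concentration series recovers the saturating exchange model", {
  C <- c(0.03, 0.3, 3, 13)
  tbl <- tibble::tibble(conc = C, tau = 1 / (0.55 * C) + 1.7)
  res <- exchange_vs_concentration(tbl)
  expect_true(res$monotone_decreasing)
  expect_lt(abs(res$model$k_on - 0.55) / 0.55, 0.10)
  expect_lt(abs(res$model$k_handoff - 1 / 1.7) * 1.7, 0.10)
  single <- exchange_vs_concentration(tibble::tibble(conc = 3, tau = 2.3))
  expect_null(single$model)
  expect_warning(
    exchange_vs_concentration(tibble::tibble(conc = c(3, 3), tau = c(2, 3))),
    "duplicate"
  )
})
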