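test_that("field-background exponentials are fitted exactly when noiseless", {
  t <- seq(0, 60, by = 0.2)
  tr <- tibble::tibble(time_s = t, intensity = 800 * exp(-t / 30) + 100)
  fit <- fit_field_background(tr)
  expect_equal(fit$amplitude, 800, tolerance = 1e-6)
  expect_equal(fit$lifetime_s, 30, tolerance = 1e-6)
  expect_equal(fit$offset, 100, tolerance = 1e-6)
  noisy <- tr
  noisy$intensity <- noisy$intensity + withr::with_seed(1, rnorm(nrow(tr), 0, 20))
  expect_lt(abs(fit_field_background(noisy)$lifetime_s - 30) / 30, 0.10)
  expect_warning(flat <- fit_field_background(make_trace(rep(50, 30))),
                 "does not decay")
  expect_equal(flat$flag, "non_decaying")
})

test_that("cell traces are corrected and their bleach amplitude recovered", {
  t <- seq(0, 30, by = 0.1)
  bg <- 3000 * exp(-t / 30)
  field_fit <- fit_field_background(tibble::tibble(time_s = t, intensity = bg))
  truth_amp <- 16432
  cell <- tibble::tibble(
    time_s = t,
    intensity = truth_amp * exp(-t / 20) + 2000 + bg +
      withr::with_seed(3, rnorm(length(t), 0, 30)))
  fit <- correct_and_fit_cell(cell, autofluorescence = 2000, field_fit = field_fit)
  expect_lt(abs(fit$amplitude - truth_amp) / truth_amp, 0.05)
  # zero-copy cell: corrected amplitude at the noise floor
  zero <- tibble::tibble(time_s = t,
                         intensity = 2000 + bg +
                           withr::with_seed(4, rnorm(length(t), 0, 30)))
  fit0 <- suppressWarnings(correct_and_fit_cell(zero, 2000, field_fit))
  expect_lt(abs(fit0$amplitude), 150)
})

test_that("simulated autofluorescence is constant over time", {
  field <- simulate_cell_field(n_cells = 5, copies_per_cell = 0, seed = 5)
  bg_fit <- fit_field_background(field$field_trace)
  tr <- dplyr::filter(field$cell_traces, cell_id == 1)
  bg <- bg_fit$amplitude * exp(-tr$time_s / bg_fit$lifetime_s) + bg_fit$offset
  corrected <- tr$intensity - bg
  n <- length(corrected)
  early <- mean(corrected[1:(n %/% 5)]); late <- mean(corrected[(n - n %/% 5):n])
  expect_lt(abs(early - late) / mean(corrected), 0.05)
})

test_that("noiseless staircases give exact change points and step sizes", {
  tr <- make_staircase(c(300, 150, 0), c(10, 10, 10))
  fit <- detect_steps(tr)
  expect_equal(fit$changepoints, c(11, 21))
  expect_equal(fit$steps, c(150, 150), tolerance = 1e-9)
})

test_that("the step detector matches brute-force enumeration on random traces", {
  set.seed(141)
  for (case in 1:60) {
    n_steps <- sample(0:3, 1)
    n_frames <- sample(12:30, 1)
    seg <- diff(sort(unique(c(0, sample(seq_len(n_frames - 1), n_steps), n_frames))))
    levels <- sort(runif(length(seg), 0, 500), decreasing = TRUE)
    y <- rep(levels, seg) + rnorm(n_frames, 0, 20)
    penalty <- 20^2 * 10
    dp <- detect_steps(make_trace(y), penalty = penalty, min_step = 0)
    bf <- brute_force_steps(y, penalty = penalty)
    expect_equal(c(1L, dp$changepoints), bf$starts)
  }
})

test_that("bleaching-step histograms recover the single-molecule intensity", {
  field <- simulate_cell_field(n_cells = 1, n_foci = 300, seed = 7)
  steps <- unlist(purrr::map(
    split(field$focus_traces, field$focus_traces$focus_id),
    function(tr) detect_steps(tr[order(tr$frame), ])$steps))
  cal <- single_molecule_intensity(steps)
  expect_lt(abs(cal$unit_mean - 158) / 158, 0.05)
})

test_that("single-molecule intensity is a Gaussian fit of the step sizes", {
  c0 <- single_molecule_intensity(rep(130, 60))
  expect_equal(c0$unit_mean, 130)
  expect_equal(c0$sem, 0)
  steps <- withr::with_seed(151, rnorm(500, 130, 25))
  cal <- single_molecule_intensity(steps)
  expect_lt(abs(cal$unit_mean - 130), 2 * cal$sem + 2 * 25 / sqrt(500))
  expect_error(single_molecule_intensity(rnorm(10, 100)), "at least 50")
})

test_that("copy numbers follow the intensity / unit-intensity ratio", {
  cal <- single_molecule_intensity(rep(158, 60))
  cell <- tibble::tibble(mean_intensity = 10 * 158 / 400, area_px = 400,
                         amplitude = NA_real_)
  expect_equal(copy_number(cell, cal), 10, tolerance = 1e-12)
  cell2 <- tibble::tibble(amplitude = 158 * 25)
  expect_equal(copy_number(cell2, cal), 25, tolerance = 1e-12)
  expect_equal(copy_number(dplyr::mutate(cell2, amplitude = amplitude * 2), cal),
               50, tolerance = 1e-12)
})

test_that("copies convert to nanomolar with the configured cell volume", {
  geom <- cell_geometry(2.4)
  expect_equal(concentration(0, geom), 0)
  expect_equal(concentration(104, geom), 71.95, tolerance = 0.01)
  expect_equal(concentration(96, geom), 66.4, tolerance = 0.01)
  expect_error(cell_geometry(NULL), "volume_fL")
})

test_that("complex concentration averages the per-subunit estimates", {
  res <- complex_concentration(72, 67)
  expect_equal(res$complex_nM, 23)
  expect_equal(res$complex_nM_unrounded, (72 + 67) / 6, tolerance = 1e-12)
  expect_equal(res$limiting_nM, 22)
  expect_equal(complex_concentration(30, 30)$complex_nM, 10)
})

test_that("bleach lifetimes are fitted exactly and flat traces flagged", {
  t <- seq(0, 60, by = 0.5)
  fit <- fit_bleach_lifetime(tibble::tibble(time_s = t,
                                            intensity = exp(-t / 14.1)))
  expect_equal(fit$lifetime_s, 14.1, tolerance = 1e-6)
  expect_warning(
    up <- fit_bleach_lifetime(tibble::tibble(time_s = t, intensity = t)),
    "does not decay")
  expect_equal(up$flag, "non_decaying")
})

test_that("end-to-end counting recovers copies and concentration", {
  field <- simulate_cell_field(n_cells = 60, copies_per_cell = 104, seed = 9)
  res <- count_cells(field, cell_geometry(2.4))
  truth_mean <- mean(field$cells$copies_true)
  expect_lt(abs(res$summary$mean_copies - truth_mean) / truth_mean, 0.05)
  truth_conc <- concentration(truth_mean, cell_geometry(2.4))
  expect_lt(abs(res$summary$mean_conc_nM - truth_conc) / truth_conc, 0.05)
})

test_that("copy numbers are invariant under uniform gain rescaling", {
  field <- simulate_cell_field(n_cells = 20, seed = 11)
  gain <- 2.5
  scaled <- field
  scaled$cell_traces$intensity <- scaled$cell_traces$intensity * gain
  scaled$field_trace$intensity <- scaled$field_trace$intensity * gain
  scaled$focus_traces$intensity <- scaled$focus_traces$intensity * gain
  scaled$cells$autofluorescence <- scaled$cells$autofluorescence * gain
  r1 <- count_cells(field, cell_geometry(2.4))
  r2 <- count_cells(scaled, cell_geometry(2.4))
  expect_lt(abs(r2$summary$mean_copies - r1$summary$mean_copies) /
              r1$summary$mean_copies, 0.02)
})
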