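test_that("integrated spot intensity is background-invariant and accurate", {
  # uniform image: disc minus annulus-median * area = 0 everywhere
  flat <- array(7, dim = c(41, 41, 3))
  tr <- tibble::tibble(frame = 1:3, x = 21, y = 21)
  res <- integrate_spot(flat, tr)
  expect_equal(res$intensity, rep(0, 3), tolerance = 1e-9)

  # synthetic PSF with known total on flat background, with/without offset
  psf <- function(total, bg) {
    img <- matrix(bg, 41, 41)
    for (i in 1:41) for (j in 1:41) {
      img[i, j] <- img[i, j] +
        total * dnorm(i, 21, 1.3) * dnorm(j, 21, 1.3)
    }
    img
  }
  r1 <- integrate_spot(psf(5000, 100), tibble::tibble(frame = 1, x = 21, y = 21))
  expect_lt(abs(r1$intensity - 5000) / 5000, 0.02)
  r2 <- integrate_spot(psf(5000, 300), tibble::tibble(frame = 1, x = 21, y = 21))
  expect_lt(abs(r2$intensity - r1$intensity) / r1$intensity, 0.02)
  # near-edge tracks are flagged
  r3 <- integrate_spot(psf(5000, 0), tibble::tibble(frame = 1, x = 3, y = 21))
  expect_true(r3$edge)
})

test_that("single-spot calibration recovers Gaussian intensity distributions", {
  c0 <- calibrate_single(rep(5100, 30))
  expect_equal(c0$unit_mean, 5100)
  expect_equal(c0$unit_sd, 0)
  x <- withr::with_seed(71, pmax(rnorm(500, 5100, 2000), 0))
  cal <- calibrate_single(x, channel = "red")
  expect_lt(abs(cal$unit_mean - 5100) / 5100, 0.05)
  expect_equal(cal$unit_mean, mean(x), tolerance = 1e-12)
  expect_error(calibrate_single(rnorm(5, 100)), "at least 20")
  bim <- withr::with_seed(72, c(rnorm(250, 1000, 60), rnorm(250, 5000, 60)))
  expect_equal(calibrate_single(bim)$flag, "bimodal")
})

test_that("stoichiometry normalisation converts intensity to complex counts", {
  cal <- new_cal <- calibrate_single(rep(5100, 30))
  unit <- 3 * 0.85 * 5100
  sp <- tibble::tibble(frame = 1:5, intensity = rep(unit, 5))
  res <- stoichiometry_series(sp, cal)
  expect_equal(res$counts$count, rep(1, 5), tolerance = 1e-12)
  sp2 <- tibble::tibble(frame = 1, intensity = 2 * unit)
  expect_equal(stoichiometry_series(sp2, cal)$counts$count, 2, tolerance = 1e-12)
  zero_cal <- cal; zero_cal$unit_mean <- 0
  expect_error(stoichiometry_series(sp, zero_cal), "zero")
})

test_that("integer-mixture EM recovers component weights", {
  m0 <- fit_integer_mixture(rep(1, 200), K = 3, rel_sd = 0.2)
  expect_gte(m0$weights[1], 0.99)
  expect_equal(sum(m0$weights), 1, tolerance = 1e-6)

  truth_w <- c(0.6, 0.3, 0.1)
  counts <- withr::with_seed(81, {
    comp <- sample(1:3, 2000, replace = TRUE, prob = truth_w)
    rnorm(2000, comp, sqrt(comp) * 0.2)
  })
  m <- fit_integer_mixture(counts, K = 3, rel_sd = 0.2)
  expect_true(all(abs(m$weights - truth_w) <= 0.05))
  expect_equal(sum(m$weights), 1, tolerance = 1e-6)
  expect_equal(m$mode, 1)
  expect_equal(fit_integer_mixture(c(0.9, 1.1), K = 5)$flag, "K_exceeds_data")
})

test_that("estimated modal stoichiometry matches the true occupancy mode", {
  # scaled-down replicate study of the default high-concentration condition
  matches <- vapply(1:15, function(r) {
    counts <- unlist(purrr::map(1:10, function(i) {
      occ <- simulate_exchange(exchange_params(conc = 6.7), duration = 50,
                               seed = 1000 * r + i)
      ph <- photo_params(bleach_lifetime_s = 1e6, bg_sd = 300,
                         unit_intensity = 5100)
      tr <- apply_photophysics(occ, ph, seed = 5000 * r + i)
      tot <- tapply(tr$intensity, tr$frame, sum)
      tot / (3 * 0.85 * 5100)
    }))
    truth <- unlist(purrr::map(1:10, function(i) {
      simulate_exchange(exchange_params(conc = 6.7), duration = 50,
                        seed = 1000 * r + i)$frames$n_bound
    }))
    truth_mode <- as.integer(names(which.max(table(truth))))
    m <- fit_integer_mixture(counts, K = 4, rel_sd = 0.25)
    m$mode == truth_mode
  }, logical(1))
  expect_gte(mean(matches), 14 / 15)
})

test_that("counts are invariant under uniform gain rescaling with refit calibration", {
  x <- withr::with_seed(91, rnorm(200, 5100, 500))
  sp <- tibble::tibble(frame = 1:50,
                       intensity = withr::with_seed(92, rnorm(50, 2 * 3 * 0.85 * 5100, 100)))
  base <- stoichiometry_series(sp, calibrate_single(x))$counts$count
  scaled <- stoichiometry_series(
    dplyr::mutate(sp, intensity = intensity * 3.7),
    calibrate_single(x * 3.7))$counts$count
  expect_equal(base, scaled, tolerance = 1e-12)
})

test_that("colocalization uses mutual nearest-neighbor matching", {
  pts <- tibble::tibble(x = c(5, 20, 40), y = c(5, 25, 12))
  expect_equal(colocalization_fraction(pts, pts, radius = 2), 1)
  a <- tibble::tibble(x = 0, y = 0); b <- tibble::tibble(x = 30, y = 0)
  expect_equal(colocalization_fraction(a, b, radius = 3), 0)
  expect_warning(f <- colocalization_fraction(a[0, ], b, 3), "empty")
  expect_true(is.nan(f))
})

test_that("random colocalization follows the spatial Poisson expectation", {
  lambda <- 0.02; r <- 2; L <- 50
  p_expect <- 1 - exp(-lambda * pi * r^2)
  hits <- withr::with_seed(101, {
    unlist(purrr::map(1:40, function(f) {
      a <- tibble::tibble(x = runif(5, 10, 40), y = runif(5, 10, 40))
      nb <- rpois(1, lambda * L^2)
      b <- tibble::tibble(x = runif(nb, 0, L), y = runif(nb, 0, L))
      colocalization_fraction(a, b, radius = r)
    }))
  })
  n_a <- 40 * 5
  se <- sqrt(p_expect * (1 - p_expect) / n_a)
  expect_lt(abs(mean(hits) - p_expect), 3 * se)
})
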