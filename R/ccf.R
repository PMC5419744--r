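#' Preprocess a focus intensity trace
#'
#' Subtracts the local background, optionally removes the photobleaching
#' trend by dividing out a per-trace single-exponential fit (shared
#' bleaching otherwise induces spurious positive cross-correlation), and
#' optionally applies a centered moving average. Trace panels are typically
#' displayed with a 2 s moving average; correlation analysis runs on
#' unsmoothed traces by default.
#'
#' @param trace Single-channel trace tibble with `time_s` and `intensity`.
#' @param window_s Moving-average window, seconds (`0` or one frame =
#'   identity).
#' @param background Background level to subtract.
#' @param detrend One of `"divide"` (default: divide by the fitted
#'   exponential, floored at 5% of its initial value), `"subtract"`, or
#'   `"none"`.
#' @return The trace with `intensity` replaced by the processed signal.
#' @export
preprocess_focus_trace <- function(trace, window_s = 0, background = 0,
                                   detrend = c("none", "divide", "subtract")) {
  detrend <- match.arg(detrend)
  y <- trace$intensity - background
  n <- length(y)
  dt <- if (n > 1) median(diff(trace$time_s)) else 1
  k <- if (window_s > 0) round(window_s / dt) else 1L
  if (k > n) abort("smoothing window longer than the trace")
  if (detrend != "none" && stats::sd(y) > 0) {
    t <- trace$time_s
    fit <- lm_fit(
      function(p) y - (p$a * exp(-t / p$tau) + p$c0),
      start = list(a = max(y) - min(y), tau = max(t) / 2, c0 = min(y)),
      lower = c(0, 1e-6, -Inf)
    )
    if (!is.null(fit)) {
      trend <- fit$par$a * exp(-t / fit$par$tau) + fit$par$c0
      if (detrend == "divide") {
        floorv <- 0.05 * max(abs(trend))
        y <- y / pmax(trend, floorv) * mean(trend)
      } else {
        y <- y - trend + mean(trend)
      }
    }
  }
  if (k > 1L) y <- moving_average(y, k)
  out <- trace
  out$intensity <- y
  out
}

#' Normalized cross-correlation of two intensity traces
#'
#' For each lag, the Pearson correlation of the overlapping windows of the
#' two mean-subtracted traces (means and sds computed over the overlap), so
#' every value lies in `[-1, 1]`, `CCF(0) = 1` for identical traces, and
#' `CCF_ab(lag) = CCF_ba(-lag)` exactly. A positive peak near zero lag
#' indicates synchronized fluctuations of the two channels.
#'
#' @param a,b Single-channel trace tibbles (`time_s`, `intensity`) on equal
#'   frame grids.
#' @param max_lag_s Maximum lag, seconds; the trace must be at least twice
#'   this long.
#' @return A `ccf_curve`: tibble `lag_s`, `lag_frames`, `ccf`, with
#'   `n_pairs = 1` in `attr(, "meta")`. Zero-variance channels give `NA`
#'   values with a warning.
#' @export
cross_correlation <- function(a, b, max_lag_s) {
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  dt <- median(diff(a$time_s))
  max_lag <- floor(max_lag_s / dt)
  if (n < 2 * max_lag) abort("trace shorter than twice the maximum lag")
  ya <- a$intensity; yb <- b$intensity
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) {
    warn("zero-variance channel: correlation undefined")
    vals <- rep(NA_real_, 2 * max_lag + 1)
  } else {
    lags <- -max_lag:max_lag
    vals <- vapply(lags, function(l) {
      if (l >= 0) {
        x1 <- ya[1:(n - l)]; x2 <- yb[(1 + l):n]
      } else {
        x1 <- ya[(1 - l):n]; x2 <- yb[1:(n + l)]
      }
      if (stats::sd(x1) == 0 || stats::sd(x2) == 0) return(NA_real_)
      stats::cor(x1, x2)
    }, numeric(1))
  }
  curve <- tibble(lag_frames = -max_lag:max_lag,
                  lag_s = (-max_lag:max_lag) * dt, ccf = vals)
  attr(curve, "meta") <- list(n_pairs = 1L, frame_interval_s = dt)
  class(curve) <- c("ccf_curve", class(curve))
  curve
}

#' Average cross-correlation over many focus pairs
#'
#' Computes the per-pair normalized CCF of every two-channel focus and
#' averages pointwise, the standard estimator for detecting synchronized
#' subunit exchange across a population of replisome foci.
#'
#' @param traces Tibble of paired traces (`focus_id`, `frame`, `time_s`,
#'   `channel` with two levels, `intensity`), e.g. from
#'   [simulate_invivo_pair()].
#' @param max_lag_s Maximum lag, seconds.
#' @param preprocess Arguments passed to [preprocess_focus_trace()] as a
#'   list (default: exponential detrending, no smoothing).
#' @return A `ccf_curve` with `n_pairs` recorded; pairs with undefined
#'   correlation are dropped.
#' @export
average_ccf <- function(traces, max_lag_s,
                        preprocess = list(detrend = "divide")) {
  chs <- sort(unique(traces$channel))
  if (length(chs) != 2) abort("need exactly two channels")
  curves <- traces |>
    group_by(.data$focus_id) |>
    dplyr::group_map(function(tr, key) {
      t1 <- filter(tr, .data$channel == chs[1]) |> arrange(.data$frame)
      t2 <- filter(tr, .data$channel == chs[2]) |> arrange(.data$frame)
      nn <- min(nrow(t1), nrow(t2))
      if (nrow(t1) != nrow(t2)) {
        warn("pair of unequal length truncated to common length")
        t1 <- t1[seq_len(nn), ]; t2 <- t2[seq_len(nn), ]
      }
      p1 <- do.call(preprocess_focus_trace, c(list(t1), preprocess))
      p2 <- do.call(preprocess_focus_trace, c(list(t2), preprocess))
      suppressWarnings(cross_correlation(p1, p2, max_lag_s))
    })
  ccf_mean(curves)
}

# pointwise mean of a list of ccf_curves (NA pairs dropped per lag)
ccf_mean <- function(curves) {
  keep <- purrr::keep(curves, function(cv) !all(is.na(cv$ccf)))
  if (!length(keep)) abort("no usable pairs")
  mat <- vapply(keep, function(cv) cv$ccf, numeric(nrow(keep[[1]])))
  mat <- matrix(mat, ncol = length(keep))
  out <- keep[[1]]
  out$ccf <- rowMeans(mat, na.rm = TRUE)
  meta <- attr(keep[[1]], "meta")
  meta$n_pairs <- length(keep)
  attr(out, "meta") <- meta
  out
}

#' Randomized cross-cell control CCF
#'
#' Averaged CCF of channel-1/channel-2 trace pairs drawn uniformly from
#' *different* cells in the same field: any peak surviving this pairing
#' reflects global artifacts (e.g. laser fluctuations) rather than shared
#' molecular exchange, so correlated same-cell signals should flatten.
#'
#' @param traces As in [average_ccf()], with a `cell_id` column (>= 2
#'   cells).
#' @param max_lag_s Maximum lag, seconds.
#' @param n_pairs Number of random cross-cell pairs (default: number of
#'   foci).
#' @param seed Integer seed (same seed, same pairing).
#' @param preprocess Passed to [preprocess_focus_trace()].
#' @return A `ccf_curve`.
#' @export
randomized_control <- function(traces, max_lag_s, n_pairs = NULL, seed = NULL,
                               preprocess = list(detrend = "divide")) {
  curves <- randomized_pair_ccfs(traces, max_lag_s, n_pairs, seed, preprocess)
  ccf_mean(curves)
}

# Draw single randomized cross-cell pair CCFs (building block for the
# control average and the null distribution).
randomized_pair_ccfs <- function(traces, max_lag_s, n_pairs = NULL,
                                 seed = NULL,
                                 preprocess = list(detrend = "divide")) {
  chs <- sort(unique(traces$channel))
  if (length(chs) != 2) abort("need exactly two channels")
  foci <- distinct(traces, .data$focus_id, .data$cell_id)
  if (length(unique(foci$cell_id)) < 2) abort("need foci from at least 2 cells")
  if (is.null(n_pairs)) n_pairs <- nrow(foci)
  split1 <- split(traces[traces$channel == chs[1], ], traces$focus_id[traces$channel == chs[1]])
  split2 <- split(traces[traces$channel == chs[2], ], traces$focus_id[traces$channel == chs[2]])
  prep <- purrr::map(names(split1), function(id) {
    list(
      p1 = do.call(preprocess_focus_trace,
                   c(list(arrange(split1[[id]], .data$frame)), preprocess)),
      p2 = do.call(preprocess_focus_trace,
                   c(list(arrange(split2[[id]], .data$frame)), preprocess)),
      cell = foci$cell_id[match(as.numeric(id), foci$focus_id)]
    )
  })
  cells <- vapply(prep, function(p) p$cell, foci$cell_id[1])
  with_seed_if(seed, {
    purrr::map(seq_len(n_pairs), function(k) {
      repeat {
        i <- sample(length(prep), 1); j <- sample(length(prep), 1)
        if (cells[i] != cells[j]) break
      }
      suppressWarnings(
        cross_correlation(prep[[i]]$p1, prep[[j]]$p2, max_lag_s))
    })
  })
}

#' Bootstrap null band for mechanism classification
#'
#' Computes `n_single` randomized cross-cell single-pair CCFs and forms
#' `n_draws` bootstrap averages of `n_pairs` of them each, giving the null
#' distribution of the *averaged* CCF under no shared exchange.
#'
#' @inheritParams randomized_control
#' @param n_draws Number of bootstrap averaged-null draws (>= 100 for
#'   classification).
#' @param n_single Number of underlying single-pair CCFs.
#' @return List with `lags` (tibble lag_frames, lag_s) and `draws` (matrix,
#'   `n_draws` x lags).
#' @export
ccf_null_distribution <- function(traces, max_lag_s, n_pairs = NULL,
                                  n_draws = 200, n_single = 200, seed = NULL,
                                  preprocess = list(detrend = "divide")) {
  singles <- randomized_pair_ccfs(traces, max_lag_s, n_pairs = n_single,
                                  seed = seed, preprocess = preprocess)
  singles <- purrr::keep(singles, function(cv) !all(is.na(cv$ccf)))
  if (is.null(n_pairs)) n_pairs <- length(unique(traces$focus_id))
  mat <- vapply(singles, function(cv) cv$ccf, numeric(nrow(singles[[1]])))
  draws <- with_seed_if(derive_seed(seed, "null-boot"), {
    t(vapply(seq_len(n_draws), function(b) {
      rowMeans(mat[, sample(ncol(mat), n_pairs, replace = TRUE), drop = FALSE],
               na.rm = TRUE)
    }, numeric(nrow(mat))))
  })
  list(lags = singles[[1]][, c("lag_frames", "lag_s")], draws = draws)
}

#' Fit an exponential decay to the positive-lag CCF branch
#'
#' Least-squares fit of `A * exp(-lag / tau)` to the non-negative-lag
#' branch; `tau` is the characteristic exchange time of the synchronized
#' fluctuations.
#'
#' @param curve A `ccf_curve` with >= 6 non-negative lags.
#' @return An `exchange_time_fit` (`tau` in the lag units of `lag_s`);
#'   curves without a positive peak are flagged `"no_decay"`.
#' @export
fit_ccf_decay <- function(curve) {
  stopifnot(inherits(curve, "ccf_curve"))
  pos <- filter(curve, .data$lag_frames >= 0)
  if (nrow(pos) < 6) abort("need at least 6 non-negative lags")
  if (!is.finite(pos$ccf[1]) || pos$ccf[1] <= 0) {
    return(new_fit("exchange_time_fit", tau = NA_real_, tau_se = NA_real_,
                   amplitude = NA_real_, offset = 0, conc = NA_real_,
                   flag = "no_decay"))
  }
  l <- pos$lag_s; y <- pos$ccf
  fit <- lm_fit(
    function(p) y - p$A * exp(-l / p$tau),
    start = list(A = y[1], tau = max(max(l) / 5, 1e-6)),
    lower = c(1e-9, 1e-9)
  )
  if (is.null(fit)) {
    return(new_fit("exchange_time_fit", tau = NA_real_, tau_se = NA_real_,
                   amplitude = NA_real_, offset = 0, conc = NA_real_,
                   flag = "no_decay"))
  }
  new_fit("exchange_time_fit", tau = fit$par$tau,
          tau_se = unname(fit$se[["tau"]]), amplitude = fit$par$A, offset = 0,
          conc = NA_real_, flag = NA_character_)
}

#' Classify the exchange mechanism from an averaged CCF
#'
#' Calls `positive_peak` if and only if the observed averaged CCF within
#' `peak_window` frames of zero lag exceeds the per-lag 99th percentile of
#' the null distribution (bootstrap averages of randomized cross-cell
#' pairs); otherwise `flat`. Whole-complex exchange gives a positive peak;
#' no exchange, core-only exchange, and uncoupled exchange give flat
#' curves.
#'
#' @param observed A `ccf_curve` (averaged).
#' @param null A null distribution from [ccf_null_distribution()] (>= 100
#'   draws).
#' @param peak_window Lags (frames) around zero to search.
#' @param prob Null quantile (default 0.99).
#' @return A `mechanism_call`: `label` (`"positive_peak"`/`"flat"`),
#'   `peak`, `null_q` (per-lag quantiles in the window), `exceed`.
#' @export
classify_mechanism <- function(observed, null, peak_window = 3, prob = 0.99) {
  stopifnot(inherits(observed, "ccf_curve"))
  if (nrow(null$draws) < 100) abort("need at least 100 null draws")
  if (!identical(null$lags$lag_frames, observed$lag_frames)) {
    abort("lag grids of observed and null do not match")
  }
  win <- which(abs(observed$lag_frames) <= peak_window)
  # family-wise null: distribution of the windowed maximum across draws
  null_max <- apply(null$draws[, win, drop = FALSE], 1, max)
  q_max <- quantile(null_max, probs = prob, names = FALSE)
  q <- apply(null$draws[, win, drop = FALSE], 2, quantile, probs = prob,
             names = FALSE)
  obs <- observed$ccf[win]
  exceed <- max(obs) - q_max
  label <- if (is.finite(exceed) && exceed > 0) "positive_peak" else "flat"
  new_fit("mechanism_call", label = label, peak = max(obs),
          exceed = exceed, prob = prob,
          null_q = tibble(lag_frames = observed$lag_frames[win], q = q))
}
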