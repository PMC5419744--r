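#' Locate FRAP pulse frames in an intensity trace
#'
#' Uses the recorded pulse schedule when present (in `attr(trace, "meta")`
#' or passed explicitly); otherwise detects pulses as frames where the
#' intensity drops below `threshold_frac` (default 20%) of the running
#' median of the preceding frames. Consecutive detections are grouped into
#' one pulse.
#'
#' @param trace Single-trace tibble with columns `frame`, `intensity` (one
#'   channel).
#' @param pulse_starts Optional integer vector of known pulse start frames
#'   (metadata mode).
#' @param threshold_frac Detection threshold as a fraction of the running
#'   pre-frame median.
#' @param median_window Frames in the running median.
#' @param min_separation Minimum frames between distinct pulses.
#' @return Integer vector of pulse start frames.
#' @export
locate_pulses <- function(trace, pulse_starts = NULL, threshold_frac = 0.2,
                          median_window = 10, min_separation = 5) {
  meta <- attr(trace, "meta")
  if (is.null(pulse_starts) && !is.null(meta$pulse_starts) &&
      length(meta$pulse_starts)) {
    pulse_starts <- meta$pulse_starts
  }
  if (!is.null(pulse_starts)) return(as.integer(sort(unique(pulse_starts))))
  if ("channel" %in% names(trace) && length(unique(trace$channel)) > 1) {
    trace <- trace |>
      group_by(.data$frame) |>
      summarise(intensity = sum(.data$intensity), .groups = "drop") |>
      arrange(.data$frame)
  }
  y <- trace$intensity
  n <- length(y)
  if (n < 2 * median_window) abort("trace shorter than one pulse period")
  # falling-edge detector: frame drops below the threshold while the
  # preceding frame was still above it (gradual recovery cannot re-trigger)
  below <- rep(FALSE, n)
  for (f in (median_window + 1):n) {
    m <- median(y[max(1, f - median_window):(f - 1)])
    thr <- threshold_frac * m
    below[f] <- is.finite(m) && m > 0 && y[f] < thr && y[f - 1] >= thr
  }
  idx <- which(below)
  if (!length(idx)) abort("no pulses detected", class = "polexchange_no_pulses")
  starts <- idx[c(TRUE, diff(idx) > min_separation)]
  as.integer(starts)
}

#' Extract and average normalized FRAP recovery curves
#'
#' For every pulse in every trace: the pre-pulse steady state is the mean of
#' the `pre_window` frames before the pulse (pulse frames excluded), the
#' post-pulse window runs from the end of the pulse to the next pulse (or
#' trace end), and the background-subtracted window is normalized by the
#' background-subtracted pre-pulse steady state. Windows are averaged
#' within each trace over its pulses, then across traces.
#'
#' @param traces Tibble of traces (columns `trace_id`, `frame`, `time_s`,
#'   `channel`, `intensity`), e.g. from [simulate_frap_experiment()].
#'   Multi-channel traces are summed per frame first.
#' @param pulse_starts Pulse start frames (defaults to the recorded
#'   schedule in `attr(traces, "meta")`).
#' @param pulse_len Pulse duration in frames (frames inside a pulse are
#'   excluded from normalization and fitting).
#' @param background Background level to subtract; defaults to the recorded
#'   `bg_mean`.
#' @param pre_window Frames used for the pre-pulse steady state.
#' @return A `recovery_curve`: tibble `time_since_pulse_s`,
#'   `intensity_norm`, `n` (curves averaged at that lag), with concentration
#'   and trace count in `attr(, "meta")`.
#' @export
extract_and_average_recovery <- function(traces, pulse_starts = NULL,
                                         pulse_len = NULL, background = NULL,
                                         pre_window = 10) {
  meta <- attr(traces, "meta")
  if (is.null(pulse_starts)) pulse_starts <- meta$pulse_starts
  if (is.null(pulse_starts) || !length(pulse_starts)) {
    abort("no pulse schedule; supply `pulse_starts` or run pulse detection")
  }
  if (is.null(pulse_len)) {
    pulse_len <- if (!is.null(meta$photo)) {
      max(1L, round(meta$photo$pulse_duration_s / meta$photo$frame_interval_s))
    } else 1L
  }
  if (is.null(background)) {
    background <- if (!is.null(meta$photo)) meta$photo$bg_mean else 0
  }
  if (!"trace_id" %in% names(traces)) traces$trace_id <- 1L
  # collapse channels: total fluorophore signal per frame
  flat <- traces |>
    group_by(.data$trace_id, .data$frame) |>
    summarise(time_s = .data$time_s[1],
              intensity = sum(.data$intensity) -
                (dplyr::n() - 1) * background, # keep one background share
              .groups = "drop")
  dt <- median(diff(flat$time_s[flat$trace_id == flat$trace_id[1]]))
  if (pre_window < 5) warn("pre-pulse window shorter than 5 frames")

  per_trace <- flat |>
    group_by(.data$trace_id) |>
    dplyr::group_map(function(tr, key) {
      tr <- arrange(tr, .data$frame)
      y <- tr$intensity - background
      n <- nrow(tr)
      # one steady state per trace, pooled over all its pre-pulse windows:
      # robust against a trace that is still dark from the previous pulse
      # at the next pulse (its window is a valid recovery sample because
      # exchange arrivals are memoryless)
      pre_all <- unlist(purrr::map(pulse_starts, function(p0) {
        pre_idx <- max(1, p0 - pre_window):(p0 - 1)
        if (length(pre_idx) < 5) warn("pre-pulse window shorter than 5 frames")
        y[pre_idx]
      }))
      steady <- mean(pre_all)
      # significance floor from high-frequency noise (frame differences),
      # not window-to-window variance, which a dark post-pulse stretch
      # inflates without making the steady state unusable
      noise_hf <- stats::mad(diff(y)) / sqrt(2)
      floor_sig <- 5 * noise_hf / sqrt(length(pre_all))
      if (!is.finite(steady) || steady <= max(floor_sig, 0)) return(NULL)
      wins <- purrr::map(seq_along(pulse_starts), function(k) {
        p0 <- pulse_starts[k]
        start <- p0 + pulse_len
        stop <- if (k < length(pulse_starts)) pulse_starts[k + 1] - 1 else n
        if (start > stop) return(NULL)
        tibble(k = seq_len(stop - start + 1), value = y[start:stop] / steady)
      })
      wins <- purrr::compact(wins)
      if (!length(wins)) return(NULL)
      purrr::list_rbind(wins) |>
        group_by(.data$k) |>
        summarise(value = mean(.data$value), .groups = "drop")
    })
  per_trace <- purrr::compact(per_trace)
  if (!length(per_trace)) abort("no usable post-pulse windows")
  curve <- purrr::list_rbind(per_trace) |>
    group_by(.data$k) |>
    summarise(intensity_norm = mean(.data$value), n = dplyr::n(),
              .groups = "drop") |>
    mutate(time_since_pulse_s = (.data$k - 1) * dt, .before = 1) |>
    select(-"k")
  attr(curve, "meta") <- list(conc = meta$conc, n_traces = length(per_trace),
                              frame_interval_s = dt)
  class(curve) <- c("recovery_curve", class(curve))
  curve
}

#' Fit the characteristic exchange time to a recovery curve
#'
#' Saturating single-exponential model
#' `I(t) = offset + amplitude * (1 - exp(-t / tau))`, least squares via
#' Levenberg--Marquardt. Curves with no recovery (fit failure, negligible
#' amplitude, or `tau` beyond 10 times the window) are flagged.
#'
#' @param curve A `recovery_curve` (>= 8 post-pulse points).
#' @return An `exchange_time_fit`: `tau`, `tau_se`, `amplitude`, `offset`,
#'   `conc`, `flag` (`NA` or `"no_recovery"`).
#' @export
fit_exchange_time <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (nrow(curve) < 8) abort("need at least 8 post-pulse points")
  t <- curve$time_since_pulse_s
  y <- curve$intensity_norm
  meta <- attr(curve, "meta")
  window <- max(t)
  # multi-start over the time constant to avoid local minima
  resid_fn <- function(p) y - (p$offset + p$A * (1 - exp(-t / p$tau)))
  fits <- purrr::map(window / c(50, 20, 5, 2), function(tau0) {
    lm_fit(resid_fn,
           start = list(offset = y[1], A = max(max(y) - y[1], 0.05),
                        tau = max(tau0, 1e-3)),
           lower = c(-Inf, 0, 1e-6))
  }) |> purrr::compact()
  ssr <- vapply(fits, function(f) sum(resid_fn(f$par)^2), numeric(1))
  fit <- if (length(fits)) fits[[which.min(ssr)]] else NULL
  if (is.null(fit)) {
    return(new_fit("exchange_time_fit", tau = NA_real_, tau_se = NA_real_,
                   amplitude = NA_real_, offset = NA_real_,
                   conc = meta$conc %||% NA_real_, flag = "no_recovery"))
  }
  flag <- NA_character_
  if (fit$par$tau > 10 * window || fit$par$A < 0.02) flag <- "no_recovery"
  new_fit("exchange_time_fit",
          tau = fit$par$tau, tau_se = unname(fit$se[["tau"]]),
          amplitude = fit$par$A, offset = fit$par$offset,
          conc = meta$conc %||% NA_real_, flag = flag)
}

#' Exchange time versus concentration
#'
#' Collects exchange-time fits over a concentration series into a sorted
#' table, reports whether the exchange time decreases monotonically with
#' concentration, and optionally fits the multisite model
#' `tau(C) = 1/(k_on * C) + 1/k_handoff`.
#'
#' @param results Tibble/data frame with columns `conc` (nM) and `tau` (s)
#'   (duplicate concentrations are averaged with a warning), or a list of
#'   `exchange_time_fit` objects.
#' @param fit_model Fit the saturating model (needs >= 2 concentrations).
#' @return List with `table` (sorted tibble), `monotone_decreasing`
#'   (logical), and `model` (fields `k_on`, `k_handoff`) when fitted.
#' @export
exchange_vs_concentration <- function(results, fit_model = length(unique(tbl$conc)) >= 2) {
  tbl <- if (is.data.frame(results)) {
    as_tibble(results)
  } else {
    purrr::map(results, function(f) tibble(conc = f$conc, tau = f$tau)) |>
      purrr::list_rbind()
  }
  stopifnot(all(c("conc", "tau") %in% names(tbl)))
  if (anyDuplicated(tbl$conc)) {
    warn("duplicate concentrations merged (mean tau)")
    tbl <- tbl |> group_by(.data$conc) |>
      summarise(tau = mean(.data$tau), .groups = "drop")
  }
  tbl <- arrange(tbl, .data$conc)
  mono <- all(diff(tbl$tau) < 0)
  model <- NULL
  if (isTRUE(fit_model) && nrow(tbl) >= 2) {
    C <- tbl$conc; tau <- tbl$tau
    fit <- lm_fit(
      function(p) tau - (1 / (p$k_on * C) + 1 / p$k_handoff),
      start = list(k_on = 1 / (min(tau) * max(C)), k_handoff = 1 / min(tau)),
      lower = c(1e-9, 1e-9)
    )
    if (!is.null(fit)) model <- fit$par
  }
  list(table = tbl, monotone_decreasing = mono, model = model)
}
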