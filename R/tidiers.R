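# broom-style tidiers for the package's fit objects.

#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = "rate_mean", estimate = x$mean, std.error = x$sem)
}

#' @export
glance.rate_fit <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, sem = x$sem, n = x$n,
         bin_width = x$bin_width, flag = x$flag)
}

#' @export
tidy.processivity_fit <- function(x, ...) {
  tibble(term = "processivity_mean", estimate = x$mean, std.error = x$se)
}

#' @export
glance.processivity_fit <- function(x, ...) {
  tibble(mean = x$mean, se = x$se, n = x$n, flag = x$flag)
}

#' @export
tidy.calibration <- function(x, ...) {
  tibble(term = c("unit_mean", "unit_sd"),
         estimate = c(x$unit_mean, x$unit_sd))
}

#' @export
glance.calibration <- function(x, ...) {
  tibble(unit_mean = x$unit_mean, unit_sd = x$unit_sd, n = x$n,
         channel = x$channel %||% NA_character_, flag = x$flag)
}

#' @export
tidy.integer_mixture <- function(x, ...) {
  tibble(component = seq_len(x$K), weight = x$weights)
}

#' @export
glance.integer_mixture <- function(x, ...) {
  tibble(K = x$K, mode = x$mode, loglik = x$loglik, n = x$n, flag = x$flag)
}

#' @export
tidy.exchange_time_fit <- function(x, ...) {
  tibble(term = c("tau", "amplitude", "offset"),
         estimate = c(x$tau, x$amplitude, x$offset),
         std.error = c(x$tau_se, NA_real_, NA_real_))
}

#' @export
glance.exchange_time_fit <- function(x, ...) {
  tibble(tau = x$tau, tau_se = x$tau_se, amplitude = x$amplitude,
         offset = x$offset, conc = x$conc, flag = x$flag)
}

#' @export
tidy.step_fit <- function(x, ...) {
  if (!length(x$changepoints)) {
    return(tibble(changepoint = integer(0), step = numeric(0)))
  }
  tibble(changepoint = x$changepoints, step = x$steps)
}

#' @export
glance.step_fit <- function(x, ...) {
  tibble(n_steps = length(x$steps), residual_var = x$residual_var,
         penalty = x$penalty, min_step = x$min_step)
}

#' @export
tidy.expdecay_fit <- function(x, ...) {
  tibble(term = c("amplitude", "lifetime_s", "offset"),
         estimate = c(x$amplitude, x$lifetime_s, x$offset))
}

#' @export
glance.expdecay_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, lifetime_s = x$lifetime_s,
         lifetime_se = x$lifetime_se %||% NA_real_,
         offset = x$offset, flag = x$flag)
}

#' @export
glance.mechanism_call <- function(x, ...) {
  tibble(label = x$label, peak = x$peak, exceed = x$exceed, prob = x$prob)
}
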