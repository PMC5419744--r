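# Shared fixture builders (all fixtures are generated in code).

# replication_trajectory from explicit time/length vectors
make_traj <- function(time_s, length_bp) {
  structure(
    list(track = tibble::tibble(frame = seq_along(time_s), time_s = time_s,
                                length_bp = length_bp),
         segments = NULL, processivity_bp = max(length_bp),
         frame_interval_s = median(diff(time_s)), seed = NULL),
    class = "replication_trajectory"
  )
}

# piecewise-linear series with Gaussian noise
make_piecewise <- function(slopes, seg_frames, dt = 0.5, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- numeric(0); last <- 0
    for (k in seq_along(slopes)) {
      t_loc <- seq_len(seg_frames[k]) * dt
      y <- c(y, last + slopes[k] * t_loc)
      last <- tail(y, 1)
    }
    t <- seq_along(y) * dt
    make_traj(t, y + rnorm(length(y), 0, noise_sd))
  })
}

# single-channel trace tibble
make_trace <- function(intensity, dt = 0.5) {
  tibble::tibble(frame = seq_along(intensity),
                 time_s = (seq_along(intensity) - 1) * dt,
                 intensity = intensity)
}

# noisy staircase for step detection: levels down to 0
make_staircase <- function(levels, seg_frames, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(levels, seg_frames) + rnorm(sum(seg_frames), 0, noise_sd)
    make_trace(y, dt = 0.1)
  })
}

# FRAP photo params used across tests: low imaging power, saturating pulse
# (pulse hazard 10 per frame regardless of the frame interval)
frap_photo <- function(period, frame_interval_s = 0.2) {
  photo_params(bleach_lifetime_s = 3000,
               power_pulse = 10 * 3000 / frame_interval_s,
               pulse_period_s = period, pulse_duration_s = 2 * frame_interval_s,
               bg_sd = 5, bg_mean = 20, unit_intensity = 1000,
               frame_interval_s = frame_interval_s)
}

# arrival-dominated two-site exchange with target residence time tau;
# perfect labeling so window normalisation is free of binomial noise
frap_params <- function(tau, frac_arrival = 0.98) {
  exchange_params(n_sites = 2, k_on = 1 / (frac_arrival * tau), k_off = 0,
                  k_handoff = 1 / ((1 - frac_arrival) * tau), conc = 1,
                  label_efficiency = 1)
}

# run a FRAP simulation + fit for a target residence time (eight recovery
# windows of 4 residence times each per trace; 20 frames per residence time)
fit_frap_tau <- function(tau, n_traces, seed) {
  period <- max(20, 4 * tau)
  dt <- max(0.1, tau / 20)
  traces <- simulate_frap_experiment(frap_params(tau), frap_photo(period, dt),
                                     n_replisomes = n_traces,
                                     duration = 8.3 * period, seed = seed)
  suppressWarnings(fit_exchange_time(extract_and_average_recovery(traces)))
}

# mechanism run: simulate + average CCF + null + classify
classify_sim_mechanism <- function(mechanism, n_foci, seed,
                                   n_frames = 300, max_lag_s = 3) {
  tr <- simulate_invivo_pair(mechanism, n_foci = n_foci, n_frames = n_frames,
                             cell_ids = rep(seq_len(n_foci / 2), each = 2),
                             seed = seed)
  avg <- average_ccf(tr, max_lag_s)
  null <- ccf_null_distribution(tr, max_lag_s, n_draws = 1000, n_single = 800,
                                seed = seed + 1)
  suppressWarnings(classify_mechanism(avg, null))
}
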