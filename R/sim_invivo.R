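#' Simulate paired two-color replisome focus traces under an exchange mechanism
#'
#' Generates `n_foci` pairs of intensity traces for the polymerase-core
#' channel (channel 1, epsilon-like) and the clamp-loader channel (channel
#' 2, tau-like) under one of four mechanisms, with per-frame binding rates:
#'
#' * `complex_exchange`: both channels' occupants arrive and depart together
#'   (whole Pol III* exchanges) at the set `k_on_frames` / `k_off_frames`.
#' * `no_exchange`: stable binding of everything (`k_on = 1`,
#'   `k_off = 1e-6` per frame).
#' * `core_only_exchange`: channel 1 exchanges at the set rates while
#'   channel 2 stays stably bound.
#' * `uncoupled`: both channels exchange independently at the set rates.
#'
#' Each arriving occupant carries a fresh fluorophore; bound fluorophores
#' photobleach per frame according to `photo`, and Gaussian background noise
#' is added, so synchronized intensity fluctuations appear only when
#' arrivals/departures are shared between the channels.
#'
#' @param mechanism One of `"complex_exchange"`, `"no_exchange"`,
#'   `"core_only_exchange"`, `"uncoupled"`.
#' @param k_on_frames,k_off_frames Per-frame binding/unbinding probabilities
#'   in `[0, 1]` (defaults 0.01, the simulated-mechanism reference rates).
#' @param n_frames Frames per trace.
#' @param n_foci Number of focus pairs (default 300).
#' @param photo A [photo_params()] object; `frame_interval_s` sets the time
#'   axis and `bleach_lifetime_s` the in-frame bleaching.
#' @param cell_ids Optional integer vector assigning each focus to a cell
#'   (defaults to one cell per focus), used by randomized controls.
#' @param seed Integer root seed.
#' @return A tibble of two-channel traces (`focus_id`, `cell_id`, `frame`,
#'   `time_s`, `channel` in `"ch1"`/`"ch2"`, `intensity`, `truth_count`)
#'   with the per-focus event logs in `attr(, "events")` (tibble: focus_id,
#'   channel, frame, event).
#' @export
#' @examples
#' tr <- simulate_invivo_pair("complex_exchange", n_foci = 5,
#'                            n_frames = 100, seed = 1)
simulate_invivo_pair <- function(mechanism = c("complex_exchange", "no_exchange",
                                               "core_only_exchange", "uncoupled"),
                                 k_on_frames = 0.01, k_off_frames = 0.01,
                                 n_frames = 300, n_foci = 300,
                                 photo = photo_params(bleach_lifetime_s = 10,
                                                      unit_intensity = 150,
                                                      bg_sd = 15,
                                                      frame_interval_s = 0.1),
                                 cell_ids = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  check_number(k_on_frames, "k_on_frames", min = 0, max = 1)
  check_number(k_off_frames, "k_off_frames", min = 0, max = 1)
  check_number(n_foci, "n_foci", min = 1)
  n_frames <- as.integer(n_frames); n_foci <- as.integer(n_foci)
  if (is.null(cell_ids)) cell_ids <- seq_len(n_foci)
  stopifnot(length(cell_ids) == n_foci)
  stable <- c(k_on = 1, k_off = 1e-6)  # "k_off << 1" documented constant
  rates <- switch(mechanism,
    complex_exchange = list(shared = c(k_on = k_on_frames, k_off = k_off_frames),
                            ch1 = NULL, ch2 = NULL),
    no_exchange = list(shared = stable, ch1 = NULL, ch2 = NULL),
    core_only_exchange = list(shared = NULL,
                              ch1 = c(k_on = k_on_frames, k_off = k_off_frames),
                              ch2 = stable),
    uncoupled = list(shared = NULL,
                     ch1 = c(k_on = k_on_frames, k_off = k_off_frames),
                     ch2 = c(k_on = k_on_frames, k_off = k_off_frames))
  )
  p_bleach <- 1 - exp(-photo$frame_interval_s * photo$power_normal /
                        photo$bleach_lifetime_s)

  # Single-site binary occupancy chain with fresh-fluorophore arrivals.
  # Returns list(bound, active, events).
  sim_channel <- function(occ_chain) {
    n <- length(occ_chain$bound)
    active <- logical(n)
    is_active <- FALSE
    for (f in seq_len(n)) {
      if (occ_chain$arrive[f]) is_active <- TRUE      # fresh fluorophore
      if (!occ_chain$bound[f]) is_active <- FALSE
      active[f] <- occ_chain$bound[f] && is_active
      if (active[f] && runif(1) < p_bleach) is_active <- FALSE
    }
    active
  }
  occupancy_chain <- function(k) {
    bound <- logical(n_frames); arrive <- logical(n_frames)
    b <- TRUE  # start bound (focus exists)
    for (f in seq_len(n_frames)) {
      if (b) {
        if (runif(1) < k[["k_off"]]) { b <- FALSE }
      } else {
        if (runif(1) < k[["k_on"]]) { b <- TRUE; arrive[f] <- TRUE }
      }
      bound[f] <- b
    }
    # initial occupant is an arrival at frame 1 for fluorophore bookkeeping
    if (bound[1]) arrive[1] <- TRUE
    list(bound = bound, arrive = arrive)
  }
  chain_events <- function(ch, focus, channel) {
    d <- diff(c(ch$bound[1], ch$bound))
    ev <- tibble(
      focus_id = focus, channel = channel,
      frame = c(which(ch$arrive), which(d == -1)),
      event = rep(c("arrive", "depart"),
                  c(length(which(ch$arrive)), length(which(d == -1))))
    )
    arrange(ev, .data$frame)
  }

  with_seed_if(seed, {
    res <- vector("list", n_foci); evs <- vector("list", n_foci)
    for (i in seq_len(n_foci)) {
      if (!is.null(rates$shared)) {
        ch <- occupancy_chain(rates$shared)
        ch1 <- ch; ch2 <- ch
      } else {
        ch1 <- occupancy_chain(rates$ch1)
        ch2 <- occupancy_chain(rates$ch2)
      }
      a1 <- sim_channel(ch1); a2 <- sim_channel(ch2)
      tt <- (seq_len(n_frames) - 1) * photo$frame_interval_s
      res[[i]] <- tibble(
        focus_id = i, cell_id = cell_ids[i],
        frame = rep(seq_len(n_frames), 2),
        time_s = rep(tt, 2),
        channel = rep(c("ch1", "ch2"), each = n_frames),
        intensity = photo$unit_intensity * c(a1, a2) +
          rnorm(2 * n_frames, photo$bg_mean, photo$bg_sd),
        truth_count = as.integer(c(ch1$bound, ch2$bound))
      )
      evs[[i]] <- bind_rows(chain_events(ch1, i, "ch1"),
                            chain_events(ch2, i, "ch2"))
    }
    out <- purrr::list_rbind(res)
    attr(out, "events") <- purrr::list_rbind(evs)
    attr(out, "meta") <- list(mechanism = mechanism, k_on = k_on_frames,
                              k_off = k_off_frames, photo = photo, seed = seed)
    out
  })
}
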