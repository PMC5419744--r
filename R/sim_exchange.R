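#' Simulate multisite Pol III* exchange at a single replisome
#'
#' Exact event-driven (Gillespie) simulation of the resident + auxiliary-site
#' exchange model described in [exchange_params()]. The trace starts with one
#' resident complex bound (a pre-assembled replisome) and all auxiliary sites
#' empty. Empty auxiliary sites fill from solution at `k_on * conc` each and
#' empty at `k_off`; whenever at least one auxiliary occupant is present, the
#' resident is replaced at `k_handoff`: the old resident departs and a
#' uniformly chosen auxiliary occupant becomes the new resident.
#'
#' With `n_sites = 2` and `k_off = 0` the mean resident residence time has
#' the closed form `1/(k_on * conc) + 1/k_handoff`; with `k_handoff = 0` each
#' auxiliary site is an independent two-state process with equilibrium
#' occupancy `k_on * conc / (k_on * conc + k_off)`.
#'
#' @param params An [exchange_params()] object.
#' @param duration Simulated time, seconds (> 0).
#' @param frame_interval_s Discretisation interval for the per-frame
#'   occupancy table, seconds.
#' @param seed Integer seed for reproducibility (optional).
#' @param max_events Guard on the expected event count; simulations whose
#'   `duration * total rate` exceeds this abort with a resource error.
#' @return An object of class `occupancy_trace`: a list with
#'   `frames` (tibble: frame, time_s, n_bound, n_aux),
#'   `complexes` (tibble: complex_id, color, n_fluor, t_arrive, t_depart),
#'   `events` (tibble: time_s, event, complex_id, site, promoted_id),
#'   `residencies` (tibble: complex_id, t_start, t_end), plus the call
#'   parameters. Complex identities are never reused; event timestamps are
#'   strictly increasing.
#' @export
#' @examples
#' occ <- simulate_exchange(exchange_params(conc = 6.7), duration = 60, seed = 1)
#' head(occ$frames)
simulate_exchange <- function(params, duration, frame_interval_s = 0.5,
                              seed = NULL, max_events = 5e6) {
  stopifnot(inherits(params, "exchange_params"))
  check_number(duration, "duration", min = 1e-12)
  rates <- c(params$k_on, params$k_off, params$k_handoff, params$conc)
  if (any(!is.finite(rates))) abort("non-finite rates are not allowed")
  n_aux <- params$n_sites - 1L
  r_fill <- params$k_on * params$conc
  max_rate <- n_aux * max(r_fill, params$k_off) + params$k_handoff
  if (duration * max_rate > max_events) {
    abort(sprintf(
      "expected event count (~%.3g) exceeds `max_events` (%.3g); shorten the run or raise the guard",
      duration * max_rate, max_events
    ), class = "polexchange_resource_error")
  }

  with_seed_if(seed, {
    # growable event store
    cap <- 1024L
    ev_t <- numeric(cap); ev_type <- character(cap)
    ev_id <- integer(cap); ev_site <- integer(cap); ev_prom <- integer(cap)
    n_ev <- 0L
    push_event <- function(t, type, id, site = NA_integer_, prom = NA_integer_) {
      n_ev <<- n_ev + 1L
      if (n_ev > cap) {
        cap <<- cap * 2L
        length(ev_t) <<- cap; length(ev_type) <<- cap
        length(ev_id) <<- cap; length(ev_site) <<- cap; length(ev_prom) <<- cap
      }
      ev_t[n_ev] <<- t; ev_type[n_ev] <<- type
      ev_id[n_ev] <<- id; ev_site[n_ev] <<- site; ev_prom[n_ev] <<- prom
    }

    cx_color <- character(0); cx_fluor <- integer(0)
    cx_arrive <- numeric(0); cx_depart <- numeric(0)
    new_complex <- function(t) {
      id <- length(cx_arrive) + 1L
      cx_color[id] <<- sample(names(params$color_fractions), 1,
                              prob = params$color_fractions)
      cx_fluor[id] <<- rbinom(1, params$cores_per_complex, params$label_efficiency)
      cx_arrive[id] <<- t; cx_depart[id] <<- NA_real_
      id
    }

    res_id <- new_complex(0)          # pre-assembled resident
    res_start <- 0
    residencies <- list()
    aux <- rep(0L, n_aux)             # 0 = empty, else complex id

    t <- 0
    repeat {
      empties <- which(aux == 0L)
      occupied <- which(aux != 0L)
      r <- c(
        fill = length(empties) * r_fill,
        empty = length(occupied) * params$k_off,
        handoff = if (length(occupied)) params$k_handoff else 0
      )
      total <- sum(r)
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= duration) break
      what <- sample(names(r), 1, prob = r)
      if (what == "fill") {
        site <- if (length(empties) == 1) empties else sample(empties, 1)
        id <- new_complex(t)
        aux[site] <- id
        push_event(t, "arrive", id, site)
      } else if (what == "empty") {
        site <- if (length(occupied) == 1) occupied else sample(occupied, 1)
        id <- aux[site]
        aux[site] <- 0L
        cx_depart[id] <- t
        push_event(t, "depart", id, site)
      } else { # handoff
        site <- if (length(occupied) == 1) occupied else sample(occupied, 1)
        old <- res_id
        promoted <- aux[site]
        aux[site] <- 0L
        cx_depart[old] <- t
        residencies[[length(residencies) + 1L]] <-
          c(id = old, t_start = res_start, t_end = t)
        res_id <- promoted
        res_start <- t
        push_event(t, "handoff", old, site, prom = promoted)
      }
    }
    # close open residency (censored)
    residencies[[length(residencies) + 1L]] <-
      c(id = res_id, t_start = res_start, t_end = NA_real_)

    complexes <- tibble(
      complex_id = seq_along(cx_arrive),
      color = cx_color, n_fluor = cx_fluor,
      t_arrive = cx_arrive, t_depart = cx_depart
    )
    events <- if (n_ev) {
      tibble(
        time_s = ev_t[seq_len(n_ev)], event = ev_type[seq_len(n_ev)],
        complex_id = ev_id[seq_len(n_ev)], site = ev_site[seq_len(n_ev)],
        promoted_id = ev_prom[seq_len(n_ev)]
      )
    } else {
      tibble(time_s = numeric(0), event = character(0),
             complex_id = integer(0), site = integer(0),
             promoted_id = integer(0))
    }
    res_tbl <- tibble(
      complex_id = vapply(residencies, `[[`, 0, "id"),
      t_start = vapply(residencies, `[[`, 0, "t_start"),
      t_end = vapply(residencies, `[[`, 0, "t_end")
    )

    grid <- frame_grid(duration, frame_interval_s)
    dep <- ifelse(is.na(complexes$t_depart), Inf, complexes$t_depart)
    n_bound <- vapply(grid$time_s, function(tt) {
      sum(complexes$t_arrive <= tt & dep > tt)
    }, integer(1))
    # resident is always exactly one; auxiliaries are the rest
    frames <- mutate(grid, n_bound = n_bound, n_aux = n_bound - 1L)

    structure(
      list(
        frames = frames, complexes = complexes, events = events,
        residencies = res_tbl, params = params, duration = duration,
        frame_interval_s = frame_interval_s, seed = seed
      ),
      class = "occupancy_trace"
    )
  })
}

#' Completed resident residence times of an occupancy trace
#'
#' Durations of residencies that ended in a replacement event within the
#' simulated window (the final, right-censored residency is excluded).
#'
#' @param occ An `occupancy_trace`.
#' @return Numeric vector of residence times, seconds.
#' @export
residence_times <- function(occ) {
  stopifnot(inherits(occ, "occupancy_trace"))
  r <- occ$residencies
  r <- r[!is.na(r$t_end), , drop = FALSE]
  r$t_end - r$t_start
}

#' Time-averaged auxiliary-site occupancy fraction
#'
#' Exact time-weighted fraction of auxiliary sites occupied over the run,
#' computed from the event log (not the discretised frames).
#'
#' @param occ An `occupancy_trace`.
#' @return Fraction in `[0, 1]`.
#' @export
aux_occupancy <- function(occ) {
  stopifnot(inherits(occ, "occupancy_trace"))
  n_aux <- occ$params$n_sites - 1L
  if (n_aux == 0L) return(0)
  ev <- occ$events
  # auxiliary occupancy changes: arrive +1; depart -1; handoff -1 (promotion
  # empties the site)
  delta <- c(arrive = 1L, depart = -1L, handoff = -1L)[ev$event]
  times <- c(0, ev$time_s, occ$duration)
  occ_level <- c(0L, cumsum(delta))
  sum(occ_level * diff(times)) / (occ$duration * n_aux)
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat("<occupancy_trace> ", nrow(x$frames), " frames, ",
      nrow(x$complexes), " complexes, ", nrow(x$events), " events",
      " (conc = ", x$params$conc, " nM)\n", sep = "")
  invisible(x)
}
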