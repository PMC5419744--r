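#' Simulate a field of fluorescent cells for copy-number counting
#'
#' Emulates the measurables of an in vivo copy-number experiment: per-cell
#' total fluorescence (copies times unit brightness, photobleaching as a
#' single exponential, plus constant cellular autofluorescence), a
#' field-of-view coverslip background decaying single-exponentially, and
#' per-focus traces that bleach in discrete single-molecule steps.
#'
#' @param n_cells Number of cells.
#' @param copies_per_cell Mean true copies per cell (default 104, the
#'   epsilon-subunit-like channel; Poisson cell-to-cell variation).
#' @param unit_intensity Counts per molecule per frame (default 158).
#' @param autofluorescence Constant autofluorescence per cell, counts.
#' @param coverslip_bg0 Initial coverslip background, counts.
#' @param coverslip_decay_s Coverslip background bleaching lifetime, s.
#' @param bleach_lifetime_s Cellular-signal bleaching lifetime, s.
#' @param n_frames Frames per trace.
#' @param frame_interval_s Seconds per frame.
#' @param noise_sd Additive Gaussian noise sd on every trace, counts.
#' @param mols_per_focus Molecules per simulated focus (stepwise bleaching).
#' @param n_foci Number of focus traces.
#' @param area_px Cell area in pixels (scalar or per cell).
#' @param seed Integer root seed.
#' @return List with `cells` (tibble: cell_id, area_px, copies_true,
#'   autofluorescence), `cell_traces` (cell_id, frame, time_s, intensity --
#'   total cell counts including autofluorescence and coverslip background),
#'   `field_trace` (frame, time_s, intensity -- coverslip background),
#'   `focus_traces` (focus_id, frame, time_s, intensity, truth_active), and
#'   the generator parameters.
#' @export
#' @examples
#' field <- simulate_cell_field(n_cells = 10, seed = 1)
simulate_cell_field <- function(n_cells = 100, copies_per_cell = 104,
                                unit_intensity = 158, autofluorescence = 2000,
                                coverslip_bg0 = 3000, coverslip_decay_s = 30,
                                bleach_lifetime_s = 20, n_frames = 300,
                                frame_interval_s = 0.1, noise_sd = 30,
                                mols_per_focus = 3, n_foci = 50,
                                area_px = 400, seed = NULL) {
  check_number(n_cells, "n_cells", min = 1)
  check_number(copies_per_cell, "copies_per_cell", min = 0)
  check_number(unit_intensity, "unit_intensity", min = 1e-12)
  tt <- (seq_len(n_frames) - 1) * frame_interval_s
  with_seed_if(seed, {
    copies <- rpois(n_cells, copies_per_cell)
    areas <- rep_len(area_px, n_cells)
    cells <- tibble(cell_id = seq_len(n_cells), area_px = areas,
                    copies_true = copies, autofluorescence = autofluorescence)
    bg_field <- coverslip_bg0 * exp(-tt / coverslip_decay_s)
    field_trace <- tibble(frame = seq_len(n_frames), time_s = tt,
                          intensity = bg_field + rnorm(n_frames, 0, noise_sd))
    cell_traces <- purrr::map(seq_len(n_cells), function(i) {
      signal <- copies[i] * unit_intensity * exp(-tt / bleach_lifetime_s)
      tibble(cell_id = i, frame = seq_len(n_frames), time_s = tt,
             intensity = signal + autofluorescence + bg_field +
               rnorm(n_frames, 0, noise_sd))
    }) |> purrr::list_rbind()
    p_bleach_frame <- frame_interval_s / bleach_lifetime_s
    focus_traces <- purrr::map(seq_len(n_foci), function(j) {
      haz <- rep(p_bleach_frame, n_frames)
      act <- bleach_matrix(mols_per_focus, haz)
      n_active <- rowSums(act)
      tibble(focus_id = j, frame = seq_len(n_frames), time_s = tt,
             intensity = unit_intensity * n_active +
               rnorm(n_frames, 0, noise_sd),
             truth_active = n_active)
    }) |> purrr::list_rbind()
    list(cells = cells, cell_traces = cell_traces, field_trace = field_trace,
         focus_traces = focus_traces,
         params = list(copies_per_cell = copies_per_cell,
                       unit_intensity = unit_intensity,
                       autofluorescence = autofluorescence,
                       coverslip_bg0 = coverslip_bg0,
                       coverslip_decay_s = coverslip_decay_s,
                       bleach_lifetime_s = bleach_lifetime_s,
                       noise_sd = noise_sd, frame_interval_s = frame_interval_s,
                       seed = seed))
  })
}
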