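# Readers and writers for the package's standard formats: trace CSV with a
# documented column dictionary, multi-page 16-bit TIFF for images, JSON for
# fits/truth/manifests, YAML for configs. Every writer records the seed and
# a parameter hash in a sidecar or header comment so runs are reproducible.

trace_columns <- c("focus_id", "frame", "time_s", "channel", "intensity",
                   "truth_count")

#' Write intensity traces to CSV
#'
#' Columns: `focus_id` (or `trace_id`, renamed), `frame`, `time_s`,
#' `channel`, `intensity`, `truth_count` plus any extras. Metadata (seed,
#' parameter hash, pulse schedule) goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param traces Trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  tr <- as_tibble(traces)
  if ("trace_id" %in% names(tr) && !"focus_id" %in% names(tr)) {
    tr <- rename(tr, focus_id = "trace_id")
  }
  if (!"focus_id" %in% names(tr)) tr$focus_id <- 1L
  miss <- setdiff(trace_columns, names(tr))
  for (m in miss) tr[[m]] <- NA
  tr <- select(tr, dplyr::all_of(trace_columns),
               dplyr::any_of(setdiff(names(tr), trace_columns)))
  readr::write_csv(tr, path)
  meta <- attr(traces, "meta")
  if (!is.null(meta)) {
    meta_out <- meta[!vapply(meta, is.function, logical(1))]
    meta_out$param_hash <- param_hash(meta_out)
    jsonlite::write_json(serialize_meta(meta_out), paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read intensity traces from CSV (with optional metadata sidecar)
#'
#' @param path CSV path written by [write_traces()].
#' @return Trace tibble with `attr(, "meta")` restored when the sidecar
#'   exists.
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$photo)) {
      meta$photo <- do.call(photo_params, meta$photo[setdiff(
        names(meta$photo), character(0))])
    }
    attr(tr, "meta") <- meta
  }
  tr
}

serialize_meta <- function(meta) {
  purrr::map(meta, function(x) {
    if (inherits(x, "photo_params") || inherits(x, "exchange_params")) {
      unclass(x)
    } else x
  })
}

# Stable content hash of a parameter list (order-normalised JSON -> md5).
param_hash <- function(params) {
  j <- jsonlite::toJSON(serialize_meta(params), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(j, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a kymograph as 16-bit TIFF with a JSON metadata sidecar
#'
#' The image is scaled to the 16-bit range; the scale factor and geometry
#' (`pixel_size_um`, `frame_interval_s`, `gamma_um_per_kb`, `origin_px`)
#' are stored in `<path>.meta.json` so [read_kymograph()] restores counts.
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  scale <- max(img, 1e-12)
  tiff::writeTIFF(pmax(img, 0) / scale, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = kymo$pixel_size_um,
         frame_interval_s = kymo$frame_interval_s,
         gamma_um_per_kb = kymo$gamma_um_per_kb,
         origin_px = kymo$origin_px, scale = scale),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph TIFF written by [write_kymograph()]
#'
#' @param path TIFF path (expects the `<path>.meta.json` sidecar).
#' @return A `kymograph`.
#' @export
read_kymograph <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  kymograph(img * meta$scale, pixel_size_um = meta$pixel_size_um,
            frame_interval_s = meta$frame_interval_s,
            gamma_um_per_kb = meta$gamma_um_per_kb,
            origin_px = meta$origin_px)
}

#' Write any fit or result object as JSON
#'
#' @param x A fit object or list (tibbles become row-wise records).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "polexchange_fit")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}
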