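#' Write a recording block as flat binary + JSON sidecar
#'
#' Traces are stored sample-major per channel block (channels x time matrix
#' written column-wise) as little-endian `float32`, or `int16` with a uV
#' scale factor; the sidecar (`<path>.json`) carries rate, channel count and
#' geometry so the file is self-describing.
#'
#' @param block A [recording_block()].
#' @param path Output path for the binary (`.bin` recommended).
#' @param dtype `"float32"` or `"int16"`.
#' @param scale_uV uV per integer unit when `dtype = "int16"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(block, path, dtype = c("float32", "int16"),
                        scale_uV = 0.195) {
  dtype <- match.arg(dtype)
  con <- file(path, "wb")
  on.exit(close(con))
  x <- as.vector(block$samples)
  if (dtype == "int16") {
    writeBin(as.integer(round(x / scale_uV)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  sidecar <- list(
    dtype = dtype, scale_uV = if (dtype == "int16") scale_uV else 1,
    rate = block$rate, n_channels = nrow(block$samples),
    n_samples = ncol(block$samples),
    channel_positions = block$channel_positions,
    shank_id = block$shank_id,
    order = "channel-fastest"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording block written by [write_trace()]
#' @param path Path to the binary file (sidecar expected at `<path>.json`).
#' @return A [recording_block()].
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- if (meta$dtype == "int16") {
    readBin(con, "integer", n = n, size = 2, endian = "little") * meta$scale_uV
  } else {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  }
  recording_block(matrix(x, meta$n_channels, meta$n_samples), rate = meta$rate,
                  channel_positions = meta$channel_positions,
                  shank_id = meta$shank_id)
}

#' Write / read pulse events as CSV
#'
#' Columns: `fiber_id`, `shank_id` (optional, NA when detection precedes
#' grouping), `onset_sample`, `offset_sample`, `intensity_summary`.
#'
#' @param pulses Pulse tibble.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_pulses_csv <- function(pulses, path) {
  if (!"shank_id" %in% names(pulses)) pulses$shank_id <- NA_integer_
  readr::write_csv(dplyr::select(pulses, fiber_id, shank_id, onset_sample,
                                 offset_sample, intensity_summary), path)
  invisible(path)
}

#' @rdname write_pulses_csv
#' @export
read_pulses_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    fiber_id = readr::col_integer(), shank_id = readr::col_integer(),
    onset_sample = readr::col_integer(), offset_sample = readr::col_integer(),
    intensity_summary = readr::col_double()
  ))
}

#' Write / read a blackout mask as CSV
#'
#' Columns: `snippet_id`, `channel`, `start_sample`, `end_sample` (0-based,
#' half-open, base rate).
#'
#' @param mask Mask tibble.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_mask_csv <- function(mask, path) {
  readr::write_csv(mask, path)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    snippet_id = readr::col_integer(), channel = readr::col_integer(),
    start_sample = readr::col_integer(), end_sample = readr::col_integer()
  ))
}

#' Write / read spike events as CSV
#' @param spikes Spike-event tibble from [match_spikes()].
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_spikes_csv <- function(spikes, path) {
  readr::write_csv(spikes, path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    snippet_id = readr::col_integer(), time_sample = readr::col_integer(),
    block_sample = readr::col_integer(), channel = readr::col_integer(),
    unit_id = readr::col_integer(), error = readr::col_double(),
    valid = readr::col_logical()
  ))
}

#' Write a PSTH as CSV
#' @param psth A `psth_tbl`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_psth_csv <- function(psth, path) {
  readr::write_csv(tibble::as_tibble(psth), path)
  invisible(path)
}
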