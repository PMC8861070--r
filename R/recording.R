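#' Multichannel extracellular recording block
#'
#' Container for a continuous multichannel voltage trace with its channel
#' geometry. Voltages are stored as a channels-by-time numeric matrix in
#' microvolts; each channel carries a depth along its shank and a shank id, as
#' on a linear silicon probe.
#'
#' @param samples Numeric matrix, channels x time, in uV.
#' @param rate Sampling rate in samples/second (default 30000).
#' @param channel_positions Numeric vector of per-channel depth along the shank
#'   (um), strictly monotone within each shank.
#' @param shank_id Integer vector assigning each channel to a shank.
#'
#' @return An object of class `recording_block` with elements `samples`,
#'   `rate`, `channel_positions`, `shank_id`.
#' @export
#' @examples
#' blk <- recording_block(matrix(rnorm(200), nrow = 2), rate = 30000,
#'                        channel_positions = c(0, 50), shank_id = c(1, 1))
#' blk
recording_block <- function(samples, rate = 30000, channel_positions = NULL,
                            shank_id = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix.")
  }
  nch <- nrow(samples)
  if (is.null(channel_positions)) channel_positions <- seq_len(nch) * 50
  if (is.null(shank_id)) shank_id <- rep(1L, nch)
  shank_id <- as.integer(shank_id)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  if (length(channel_positions) != nch || length(shank_id) != nch) {
    abort("`channel_positions` and `shank_id` must have one entry per channel.")
  }
  for (s in unique(shank_id)) {
    pos <- channel_positions[shank_id == s]
    if (length(pos) > 1 && !(all(diff(pos) > 0) || all(diff(pos) < 0))) {
      abort(sprintf("channel_positions must be strictly monotone within shank %d", s))
    }
  }
  structure(
    list(samples = samples, rate = rate,
         channel_positions = as.numeric(channel_positions),
         shank_id = shank_id),
    class = "recording_block"
  )
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf(
    "<recording_block> %d channels x %d samples @ %g Hz (%.2f s), %d shank(s)\n",
    nrow(x$samples), ncol(x$samples), x$rate, ncol(x$samples) / x$rate,
    length(unique(x$shank_id))
  ))
  invisible(x)
}

#' @export
dim.recording_block <- function(x) dim(x$samples)

#' Per-fiber light-intensity log
#'
#' Photodiode intensity traces for each stimulation fiber, on their own
#' timebase (converted to the recording timebase at pulse detection).
#'
#' @param intensity Numeric matrix, fibers x time, non-negative photodiode
#'   units; a vector is treated as a single fiber.
#' @param rate Sampling rate of the light log in samples/second.
#' @param fiber_ids Integer ids, one per fiber row.
#'
#' @return An object of class `light_log`.
#' @export
light_log <- function(intensity, rate = 30000, fiber_ids = NULL) {
  if (is.vector(intensity) && is.numeric(intensity)) {
    intensity <- matrix(intensity, nrow = 1)
  }
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric fibers x time matrix or vector.")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    abort("light intensities must be finite.")
  }
  if (any(intensity < 0)) abort("light intensities must be non-negative.")
  if (is.null(fiber_ids)) fiber_ids <- seq_len(nrow(intensity))
  if (length(fiber_ids) != nrow(intensity)) {
    abort("`fiber_ids` must have one entry per fiber row.")
  }
  structure(
    list(intensity = intensity, rate = rate, fiber_ids = as.integer(fiber_ids)),
    class = "light_log"
  )
}

#' @export
print.light_log <- function(x, ...) {
  cat(sprintf("<light_log> %d fiber(s) x %d samples @ %g Hz\n",
              nrow(x$intensity), ncol(x$intensity), x$rate))
  invisible(x)
}
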