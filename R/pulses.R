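#' Detect light pulses from a photodiode log
#'
#' Finds one pulse per contiguous supra-half-maximum excursion of each fiber's
#' intensity trace. Onset and offset are placed at the first and last crossing
#' of half of that pulse's own plateau peak, so trials of different commanded
#' intensity are each referenced to their own half-maximum.
#'
#' All sample indices are 0-based on the recording timebase and intervals are
#' half-open `[onset, offset)`. A light log sampled at a different rate is
#' linearly interpolated onto `target_rate` before detection.
#'
#' @param light A [light_log()].
#' @param min_separation Minimum separation between distinct pulses, seconds;
#'   supra-floor excursions closer than this are merged into one pulse.
#' @param target_rate Recording sampling rate the indices should refer to;
#'   defaults to the light log's own rate.
#' @param floor_frac Fraction of the fiber's global maximum used to segment
#'   candidate excursions before the per-pulse half-maximum rule is applied.
#'
#' @return A tibble with columns `fiber_id`, `onset_sample`, `offset_sample`,
#'   `intensity_summary` (peak photodiode value during the pulse), sorted by
#'   fiber then onset. An all-zero trace yields zero rows.
#' @export
detect_pulses <- function(light, min_separation = 0, target_rate = NULL,
                          floor_frac = 0.01) {
  stopifnot(inherits(light, "light_log"))
  if (min_separation < 0) abort("`min_separation` must be >= 0.")
  target_rate <- target_rate %||% light$rate

  out <- purrr::map_dfr(seq_len(nrow(light$intensity)), function(i) {
    x <- light$intensity[i, ]
    if (!all(is.finite(x))) abort("non-finite intensity samples in light log.")
    if (light$rate != target_rate) {
      n_out <- max(2L, round(length(x) * target_rate / light$rate))
      x <- stats::approx(seq_along(x), x, n = n_out)$y
    }
    peak_global <- max(x)
    if (peak_global <= 0) return(tibble::tibble())
    above <- x > floor_frac * peak_global
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) return(tibble::tibble())
    # merge excursions closer than min_separation
    min_gap <- round(min_separation * target_rate)
    if (length(starts) > 1 && min_gap > 0) {
      merged_s <- starts[1]; merged_e <- ends[1]
      for (j in 2:length(starts)) {
        if (starts[j] - merged_e[length(merged_e)] - 1 < min_gap) {
          merged_e[length(merged_e)] <- ends[j]
        } else {
          merged_s <- c(merged_s, starts[j]); merged_e <- c(merged_e, ends[j])
        }
      }
      starts <- merged_s; ends <- merged_e
    }
    purrr::map_dfr(seq_along(starts), function(j) {
      seg <- x[starts[j]:ends[j]]
      peak <- max(seg)
      thr <- peak / 2
      idx <- which(seg >= thr)
      tibble::tibble(
        fiber_id = light$fiber_ids[i],
        onset_sample = starts[j] + idx[1] - 2L,          # 0-based
        offset_sample = starts[j] + idx[length(idx)] - 1L, # half-open
        intensity_summary = peak
      )
    })
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(fiber_id = integer(), onset_sample = integer(),
                          offset_sample = integer(), intensity_summary = double()))
  }
  dplyr::arrange(out, fiber_id, onset_sample)
}
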