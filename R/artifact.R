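#' Configuration for photovoltaic-artifact management
#'
#' Holds the constants of the artifact-removal procedure: how many
#' nearest-neighbour pulses enter each template, the onset/offset template
#' overlap, the residual-detector window and threshold, and the blackout
#' expansion margins.
#'
#' @param k_neighbors Number of pulses averaged into each template (the pulse
#'   being cleaned is itself a candidate), default 20.
#' @param overlap_samples Overlap between onset and offset templates, in
#'   base-rate samples (100 samples at 30 kHz = 3.3 ms).
#' @param residual_window_trials Width of the intensity-ordered moving window
#'   of trials in the residual detector (odd, >= 3), default 7.
#' @param residual_threshold_sd Threshold on the windowed rectified-derivative
#'   statistic, in pre-stimulation SDs, default 4.
#' @param blackout_expand_back,blackout_expand_fwd Expansion of flagged
#'   regions backward/forward in time, base-rate samples (40 / 20).
#' @param supersample_factor Supersampling factor used during cleaning.
#' @param hp_cutoff_hz High-pass cutoff applied before cleaning (Hz).
#' @param resample_method `"fourier"` (band-limited) or `"spline"`.
#'
#' @return A list of class `pvr_config`.
#' @export
pvr_config <- function(k_neighbors = 20, overlap_samples = 100,
                       residual_window_trials = 7, residual_threshold_sd = 4,
                       blackout_expand_back = 40, blackout_expand_fwd = 20,
                       supersample_factor = 4, hp_cutoff_hz = 1,
                       resample_method = c("fourier", "spline")) {
  resample_method <- match.arg(resample_method)
  cfg <- list(
    k_neighbors = as.integer(k_neighbors),
    overlap_samples = as.integer(overlap_samples),
    residual_window_trials = as.integer(residual_window_trials),
    residual_threshold_sd = residual_threshold_sd,
    blackout_expand_back = as.integer(blackout_expand_back),
    blackout_expand_fwd = as.integer(blackout_expand_fwd),
    supersample_factor = as.integer(supersample_factor),
    hp_cutoff_hz = hp_cutoff_hz,
    resample_method = resample_method
  )
  problems <- character()
  if (cfg$k_neighbors < 2) problems <- c(problems, "k_neighbors must be >= 2")
  if (cfg$residual_window_trials < 3 || cfg$residual_window_trials %% 2 == 0) {
    problems <- c(problems, "residual_window_trials must be odd and >= 3")
  }
  if (cfg$residual_threshold_sd <= 0) problems <- c(problems, "residual_threshold_sd must be > 0")
  if (cfg$overlap_samples <= 0) problems <- c(problems, "overlap_samples must be > 0")
  if (cfg$blackout_expand_back < 0 || cfg$blackout_expand_fwd < 0) {
    problems <- c(problems, "blackout expansions must be >= 0")
  }
  if (cfg$supersample_factor < 1) problems <- c(problems, "supersample_factor must be >= 1")
  if (length(problems)) abort(paste0("invalid pvr_config: ", paste(problems, collapse = "; ")))
  structure(cfg, class = "pvr_config")
}

# left-aligned flattening of a group's snippets over a common length
flatten_left <- function(snips, len) {
  t(vapply(snips, function(m) as.vector(m[, 1:len, drop = FALSE]),
           numeric(nrow(snips[[1]]) * len)))
}

#' Build onset/offset artifact templates for one pulse
#'
#' The template for a pulse is the per-channel mean of the `k_neighbors`
#' snippets in its group with the smallest mean squared error to the pulse of
#' interest (computed onset-aligned over all of the group's channels; the
#' pulse itself is a candidate and always selected, its distance being zero).
#' Because pulse durations vary, onset-aligned and offset-aligned templates
#' are computed separately and joined later by [merge_onset_offset()].
#'
#' A spike present in exactly one of the `k` averaged snippets enters the
#' template with weight `1/k`, so subtraction attenuates it by about 5% at the
#' default `k = 20`.
#'
#' @param group A (typically preprocessed) `snippet_group`.
#' @param pulse_index Index of the pulse of interest within the group.
#' @param cfg A [pvr_config()].
#'
#' @return An object of class `pulse_template` with onset-aligned and
#'   offset-aligned channels x time matrices, the selected neighbour indices,
#'   and the pulse index.
#' @export
build_pulse_template <- function(group, pulse_index, cfg = pvr_config()) {
  stopifnot(inherits(group, "snippet_group"))
  n <- length(group$snippets)
  k <- cfg$k_neighbors
  if (n < k) {
    abort(sprintf(
      "group has %d snippets but k_neighbors = %d; use a smaller k_neighbors.", n, k))
  }
  if (pulse_index < 1 || pulse_index > n) abort("`pulse_index` out of range.")
  lens <- vapply(group$snippets, ncol, integer(1))
  lmin <- min(lens)
  X <- flatten_left(group$snippets, lmin)
  d <- rowMeans(sweep(X, 2, X[pulse_index, ])^2)
  sel <- order(d)[1:k]

  nch <- length(group$channels)
  lsel <- min(lens[sel])
  onset <- matrix(0, nch, lsel)
  offset <- matrix(0, nch, lsel)
  for (i in sel) {
    m <- group$snippets[[i]]
    onset <- onset + m[, 1:lsel, drop = FALSE]
    offset <- offset + m[, (ncol(m) - lsel + 1):ncol(m), drop = FALSE]
  }
  structure(
    list(onset_template = onset / k, offset_template = offset / k,
         pulse_index = pulse_index, neighbors = sel, factor = group$factor),
    class = "pulse_template"
  )
}

#' Join onset and offset templates across the overlap region
#'
#' The onset-aligned and offset-aligned templates are merged into a single
#' template spanning the pulse's snippet. Inside an overlap region centred on
#' the pulse midpoint, weights ramp linearly from 1 to 0 (onset) and 0 to 1
#' (offset), summing to one at every sample, so no discontinuity is
#' introduced. The overlap is `overlap_samples` at base rate (3.3 ms at
#' 30 kHz) and scales with the supersampling factor.
#'
#' @param tpl A `pulse_template` from [build_pulse_template()].
#' @param group The `snippet_group` the template was built from.
#' @param cfg A [pvr_config()].
#'
#' @return A channels x time matrix spanning the pulse-of-interest snippet.
#' @export
merge_onset_offset <- function(tpl, group, cfg = pvr_config()) {
  stopifnot(inherits(tpl, "pulse_template"), inherits(group, "snippet_group"))
  i <- tpl$pulse_index
  f <- group$factor
  L <- ncol(group$snippets[[i]])
  dur <- (group$offset_sample[i] - group$onset_sample[i]) * f
  ov <- cfg$overlap_samples * f
  if (dur < ov) {
    abort(sprintf("pulse duration (%d samples) is shorter than the template overlap (%d).",
                  dur, ov))
  }
  mid <- group$pre_samples * f + round(dur / 2)
  a <- mid - floor(ov / 2)           # 0-based start of overlap
  b <- a + ov                        # exclusive end
  L_on <- ncol(tpl$onset_template)
  L_off <- ncol(tpl$offset_template)
  if (b > L_on) abort("onset template does not cover the overlap region.")
  if (L - L_off > a) abort("offset template does not cover the overlap region.")

  shift <- L - L_off                  # offset template position in snippet coords
  merged <- matrix(0, nrow(tpl$onset_template), L)
  if (a > 0) merged[, 1:a] <- tpl$onset_template[, 1:a, drop = FALSE]
  if (b < L) merged[, (b + 1):L] <- tpl$offset_template[, (b + 1 - shift):L_off, drop = FALSE]
  w <- seq(0, 1, length.out = ov)     # offset weight across overlap
  idx <- (a + 1):b
  merged[, idx] <- sweep(tpl$onset_template[, idx, drop = FALSE], 2, 1 - w, `*`) +
    sweep(tpl$offset_template[, idx - shift, drop = FALSE], 2, w, `*`)
  merged
}

#' Subtract a merged artifact template from a snippet
#'
#' @param snippet Channels x time matrix.
#' @param merged_template Matrix of identical shape from [merge_onset_offset()].
#' @return The residual snippet (same shape).
#' @export
subtract_template <- function(snippet, merged_template) {
  if (!all(dim(snippet) == dim(merged_template))) {
    abort("snippet and template shapes do not match.")
  }
  snippet - merged_template
}

#' Clean every snippet of a group by per-pulse template subtraction
#'
#' Convenience wrapper looping [build_pulse_template()],
#' [merge_onset_offset()] and [subtract_template()] over all pulses of a
#' preprocessed group.
#'
#' @param group A preprocessed `snippet_group`.
#' @param cfg A [pvr_config()].
#' @return The group with `snippets` replaced by residuals (and the original
#'   traces retained as `raw_snippets`).
#' @export
clean_group <- function(group, cfg = pvr_config()) {
  stopifnot(inherits(group, "snippet_group"))
  n <- length(group$snippets)
  k <- cfg$k_neighbors
  if (n < k) {
    abort(sprintf(
      "group has %d snippets but k_neighbors = %d; use a smaller k_neighbors.", n, k))
  }
  lens <- vapply(group$snippets, ncol, integer(1))
  lmin <- min(lens)
  X <- flatten_left(group$snippets, lmin)
  # pairwise squared distances in one pass (||a||^2 + ||b||^2 - 2 a.b)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  nch <- length(group$channels)

  cleaned <- purrr::map(seq_len(n), function(i) {
    sel <- order(D[i, ])[1:k]
    lsel <- min(lens[sel])
    onset <- matrix(0, nch, lsel); offset <- matrix(0, nch, lsel)
    for (j in sel) {
      m <- group$snippets[[j]]
      onset <- onset + m[, 1:lsel, drop = FALSE]
      offset <- offset + m[, (ncol(m) - lsel + 1):ncol(m), drop = FALSE]
    }
    tpl <- structure(
      list(onset_template = onset / k, offset_template = offset / k,
           pulse_index = i, neighbors = sel, factor = group$factor),
      class = "pulse_template")
    subtract_template(group$snippets[[i]], merge_onset_offset(tpl, group, cfg))
  })
  group$raw_snippets <- group$snippets
  group$snippets <- cleaned
  group
}
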