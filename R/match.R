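#' Configuration for template-matching spike recovery
#'
#' @param detect_sd Events must exceed this many (per-channel) SDs in negative
#'   amplitude to be considered (default 4).
#' @param max_error Accept a unit match if the mean squared error (over 3
#'   probe-adjacent channels and 61 samples, in SD units) is below this
#'   (default 1).
#' @param window_pre,window_post Spike window around the trough, samples.
#' @param n_channels Channels centred on the event used in the comparison
#'   (default 3, clamped at probe edges).
#' @param exclusion_radius Samples around a picked trough marked consumed so
#'   the same trough is not re-picked; defaults to half the spike window.
#' @param max_shift Alignment search: the window is compared at trough shifts
#'   of up to this many samples and the best alignment is kept, absorbing the
#'   +/- 1 sample trough jitter that noise induces (default 2).
#' @param amplitude_tolerance_sd Reject a match whose event trough differs
#'   from the template trough by more than this many SDs, or 35% of the
#'   template trough for deep templates, whichever is larger (default 4,
#'   mirroring the detection criterion); prevents shallow noise dips from
#'   matching deep templates on a lucky window while tolerating the larger
#'   absolute fluctuations of large spikes. `Inf` disables.
#' @return A list of class `match_config`.
#' @export
match_config <- function(detect_sd = 4, max_error = 1, window_pre = 20,
                         window_post = 40, n_channels = 3,
                         exclusion_radius = NULL, max_shift = 2,
                         amplitude_tolerance_sd = 4) {
  wlen <- window_pre + window_post + 1
  structure(list(
    detect_sd = detect_sd, max_error = max_error,
    window_pre = as.integer(window_pre), window_post = as.integer(window_post),
    n_channels = as.integer(n_channels),
    exclusion_radius = as.integer(exclusion_radius %||% floor(wlen / 2)),
    max_shift = as.integer(max_shift),
    amplitude_tolerance_sd = amplitude_tolerance_sd
  ), class = "match_config")
}

#' Recover spikes inside cleaned peri-pulse windows by template matching
#'
#' Greedy per-snippet loop mirroring the event-matching stage of the artifact
#' management procedure: channels are normalized to unit standard deviation
#' (computed on unmasked samples), the most negative unmasked sample is
#' picked and marked consumed, the three probe-adjacent channels centred on
#' it (clamped at probe edges) are compared over the -20/+40 sample window
#' against each sorted unit's correspondingly normalized waveform, and the
#' best unit is accepted if its mean squared error is below one. The loop
#' stops when no unconsumed event exceeds `detect_sd` SDs in magnitude.
#'
#' Accepted events whose spike window intersects the expanded blackout mask
#' are emitted with `valid = FALSE`; they are excluded from rate estimates
#' but retained for bookkeeping.
#'
#' @param group A cleaned, base-rate `snippet_group` (see [clean_group()] and
#'   [decimate_group()]).
#' @param mask An expanded blackout mask for the group (base-rate indices).
#' @param units A `sorted_units` object (or anything with `templates`).
#' @param cfg A [match_config()].
#'
#' @return A tibble of spike events: `snippet_id`, `time_sample` (0-based
#'   within the snippet), `block_sample` (0-based in recording coordinates),
#'   `channel` (within-group index of the picked trough), `unit_id`, `error`,
#'   `valid`. Deterministic for identical input.
#' @export
match_spikes <- function(group, mask, units, cfg = match_config()) {
  stopifnot(inherits(group, "snippet_group"))
  if (group$factor != 1) {
    abort("spike matching operates at base rate; call decimate_group() first.")
  }
  tpls <- units$templates
  if (length(tpls) == 0) abort("no unit templates supplied.")
  nch <- length(group$channels)
  wpre <- cfg$window_pre; wpost <- cfg$window_post
  wlen <- wpre + wpost + 1L
  half_w <- cfg$exclusion_radius
  side <- (cfg$n_channels - 1L) %/% 2L

  out <- purrr::map_dfr(seq_along(group$snippets), function(si) {
    X <- group$snippets[[si]]
    L <- ncol(X)
    M <- mask_to_logical(mask, si, nch, L)
    if (all(M)) {
      inform(sprintf("snippet %d fully masked; no spikes recovered.", si))
      return(tibble::tibble())
    }
    sd_c <- vapply(seq_len(nch), function(c) {
      v <- X[c, !M[c, ]]
      if (length(v) > 1) sd(v) else NA_real_
    }, numeric(1))
    usable <- is.finite(sd_c) & sd_c > 0
    Xn <- X / sd_c
    Xn[!usable, ] <- NA_real_
    avail <- !M & usable
    consumed <- matrix(FALSE, nch, L)

    rows <- list()
    repeat {
      cand <- Xn
      cand[!avail | consumed] <- Inf
      v <- min(cand)
      if (!is.finite(v) || v > -cfg$detect_sd) break
      pos <- arrayInd(which.min(cand), dim(cand))
      c0 <- pos[1, 1]; t0 <- pos[1, 2]          # 1-based
      chs <- unique(pmin(pmax((c0 - side):(c0 + side), 1L), nch))
      # mark the pick consumed so it cannot seed again; the full exclusion
      # radius is only applied once a match is accepted (below), so a
      # rejected pick does not swallow a genuine neighbouring spike
      consumed[chs, max(1L, t0 - 2L):min(L, t0 + 2L)] <- TRUE
      shifts <- (-cfg$max_shift):cfg$max_shift
      shifts <- shifts[t0 + shifts - wpre >= 1 & t0 + shifts + wpost <= L]
      if (length(shifts) == 0) next               # window leaves the snippet
      chs_ok <- chs[usable[chs]]
      if (length(chs_ok) == 0) next
      errs <- vapply(tpls, function(u) {
        tw <- u$waveform_norm[group$channels[chs_ok], , drop = FALSE]
        # the unit must actually have an event-scale trough on the compared
        # channels (comparing noise against a flat template is meaningless),
        # and its amplitude must be consistent with the picked event
        if (min(tw) > -cfg$detect_sd) return(Inf)
        amp_tol <- max(cfg$amplitude_tolerance_sd, 0.35 * abs(min(tw)))
        if (abs(min(tw) - v) > amp_tol) return(Inf)
        min(vapply(shifts, function(s) {
          win <- (t0 + s - wpre):(t0 + s + wpost)
          mean((Xn[chs_ok, win, drop = FALSE] - tw)^2)
        }, numeric(1)))
      }, numeric(1))
      best <- which.min(errs)
      if (length(best) == 0 || errs[best] >= cfg$max_error) next
      tlo <- max(1L, t0 - half_w); thi <- min(L, t0 + half_w)
      consumed[chs, tlo:thi] <- TRUE
      win <- (max(1, t0 - cfg$max_shift - wpre)):(min(L, t0 + cfg$max_shift + wpost))
      valid <- !any(M[chs, win])
      rows[[length(rows) + 1]] <- tibble::tibble(
        snippet_id = si, time_sample = t0 - 1L,
        block_sample = group$onset_sample[si] - group$pre_samples + t0 - 1L,
        channel = c0, unit_id = tpls[[best]]$unit_id,
        error = errs[best], valid = valid
      )
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(snippet_id = integer(), time_sample = integer(),
                          block_sample = integer(), channel = integer(),
                          unit_id = integer(), error = double(), valid = logical()))
  }
  dplyr::arrange(out, snippet_id, time_sample)
}
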