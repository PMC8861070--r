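#' Blackout-aware weighted peri-stimulus time histogram
#'
#' For each time bin the firing rate is averaged only over trials whose bin is
#' fully unmasked, and the percentage of trials masked in that bin (the
#' "remaining PVR trial percentage") is reported alongside so the reader can
#' judge how much data each bin rests on. A bin masked in every trial is
#' undefined (`NA` rate, `undefined = TRUE`); its neighbours are unaffected.
#'
#' @param spikes Spike-event tibble from [match_spikes()] (only `valid`
#'   events are counted).
#' @param mask Expanded blackout mask for the group.
#' @param group The base-rate `snippet_group` the spikes came from.
#' @param bin_ms Bin width in milliseconds (> 0).
#' @param channels Within-group channel indices whose masking invalidates a
#'   trial-bin; defaults to all channels of the group.
#' @param unit_id Optional unit id(s) to restrict to.
#'
#' @return A tibble of class `psth_tbl` with `bin_start_ms`, `bin_end_ms`
#'   (relative to light onset), `rate_hz`, `pct_masked_trials`,
#'   `n_trials_used`, `undefined`.
#' @export
weighted_psth <- function(spikes, mask, group, bin_ms = 1, channels = NULL,
                          unit_id = NULL) {
  stopifnot(inherits(group, "snippet_group"))
  if (bin_ms <= 0) abort("`bin_ms` must be > 0.")
  n_trials <- length(group$snippets)
  if (n_trials == 0) abort("no trials in group.")
  rate <- group$rate
  nch <- length(group$channels)
  channels <- channels %||% seq_len(nch)
  if (!is.null(unit_id)) spikes <- dplyr::filter(spikes, .data$unit_id %in% !!unit_id)

  pre_ms <- group$pre_samples / rate * 1000
  post_ms <- group$post_samples / rate * 1000
  dur_ms <- min(group$offset_sample - group$onset_sample) / rate * 1000
  edges <- seq(-pre_ms, dur_ms + post_ms, by = bin_ms)
  if (length(edges) < 2) abort("bin_ms larger than the snippet span.")
  nb <- length(edges) - 1

  # per trial x bin: masked if the mask touches the bin on any watched channel
  masked <- matrix(FALSE, n_trials, nb)
  sub <- mask[mask$channel %in% channels, , drop = FALSE]
  if (nrow(sub)) {
    bin_start_smp <- round((edges[-length(edges)] + pre_ms) / 1000 * rate)
    bin_end_smp <- round((edges[-1] + pre_ms) / 1000 * rate)
    for (i in seq_len(nrow(sub))) {
      tr <- sub$snippet_id[i]
      if (tr > n_trials) next
      hit <- sub$start_sample[i] < bin_end_smp & sub$end_sample[i] > bin_start_smp
      masked[tr, hit] <- TRUE
    }
  }

  counts <- matrix(0, n_trials, nb)
  sv <- dplyr::filter(spikes, valid)
  if (nrow(sv)) {
    t_ms <- sv$time_sample / rate * 1000 - pre_ms
    b <- findInterval(t_ms, edges, rightmost.closed = FALSE)
    ok <- b >= 1 & b <= nb & sv$snippet_id <= n_trials
    for (i in which(ok)) counts[sv$snippet_id[i], b[i]] <- counts[sv$snippet_id[i], b[i]] + 1
  }

  n_used <- colSums(!masked)
  rate_hz <- vapply(seq_len(nb), function(j) {
    if (n_used[j] == 0) return(NA_real_)
    mean(counts[!masked[, j], j]) / (bin_ms / 1000)
  }, numeric(1))

  structure(
    tibble::tibble(
      bin_start_ms = edges[-length(edges)], bin_end_ms = edges[-1],
      rate_hz = rate_hz,
      pct_masked_trials = 100 * colSums(masked) / n_trials,
      n_trials_used = n_used,
      undefined = n_used == 0
    ),
    class = c("psth_tbl", class(tibble::tibble()))
  )
}

#' Plot a weighted PSTH
#'
#' Firing rate per bin with the per-bin percentage of blacked-out trials shown
#' as a shaded band along the bottom.
#'
#' @param object A `psth_tbl` from [weighted_psth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psth_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (bin_start_ms + bin_end_ms) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = rate_hz), width = object$bin_end_ms[1] - object$bin_start_ms[1],
                      fill = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = pct_masked_trials / 100 * max(rate_hz, na.rm = TRUE)),
                       colour = "seagreen") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "orange") +
    ggplot2::labs(x = "time from light onset (ms)", y = "rate (Hz)",
                  caption = "green: remaining-PVR trial percentage (scaled)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
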