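#' Blackout masks
#'
#' A blackout mask is a tibble of half-open, 0-based, base-rate sample
#' intervals `[start_sample, end_sample)` that are invalid for spike
#' detection, keyed by snippet (trial) and channel within a group. Intervals
#' are stored run-length style rather than as sentinel values so they can be
#' serialized, merged and queried exactly.
#'
#' @param snippet_id,channel,start_sample,end_sample Equal-length vectors.
#' @return A normalized (sorted, merged) mask tibble.
#' @export
blackout_mask <- function(snippet_id = integer(), channel = integer(),
                          start_sample = integer(), end_sample = integer()) {
  normalize_mask(tibble::tibble(
    snippet_id = as.integer(snippet_id), channel = as.integer(channel),
    start_sample = as.integer(start_sample), end_sample = as.integer(end_sample)
  ))
}

#' Sort and merge the intervals of a blackout mask
#'
#' Overlapping or touching intervals of the same snippet and channel are
#' merged; empty intervals are dropped.
#'
#' @param mask A mask tibble (columns snippet_id, channel, start_sample,
#'   end_sample).
#' @return The normalized mask.
#' @export
normalize_mask <- function(mask) {
  mask <- dplyr::filter(mask, end_sample > start_sample)
  if (nrow(mask) == 0) {
    return(tibble::tibble(snippet_id = integer(), channel = integer(),
                          start_sample = integer(), end_sample = integer()))
  }
  mask |>
    dplyr::arrange(snippet_id, channel, start_sample) |>
    dplyr::group_by(snippet_id, channel) |>
    dplyr::group_modify(function(df, key) {
      s <- df$start_sample; e <- df$end_sample
      ks <- s[1]; ke <- e[1]; out_s <- integer(); out_e <- integer()
      if (length(s) > 1) {
        for (i in 2:length(s)) {
          if (s[i] <= ke) ke <- max(ke, e[i])
          else { out_s <- c(out_s, ks); out_e <- c(out_e, ke); ks <- s[i]; ke <- e[i] }
        }
      }
      tibble::tibble(start_sample = c(out_s, ks), end_sample = c(out_e, ke))
    }) |>
    dplyr::ungroup() |>
    dplyr::select(snippet_id, channel, start_sample, end_sample)
}

#' Detect residual artifacts after template subtraction
#'
#' Residual photovoltaic transients concentrate where the artifact's temporal
#' derivative is strongest. Per channel, the cleaned traces are differentiated
#' in time and rectified; trials are ordered by light intensity and, for each
#' trial and time point, the rectified values are averaged over a centred
#' window of `residual_window_trials` intensity-adjacent trials *excluding the
#' single largest value* (which protects genuine spikes from triggering the
#' detector). Samples where this statistic exceeds
#' `residual_threshold_sd` times its own standard deviation over the
#' pre-stimulation span (pooled across trials, per channel) are flagged.
#'
#' At the extremes of the intensity ordering the window shrinks symmetrically,
#' never below 3 trials. Flagged supersampled indices are reported at base
#' rate (floored), ready for [expand_blackout()].
#'
#' @param group A cleaned (residual) `snippet_group`, e.g. from
#'   [clean_group()].
#' @param cfg A [pvr_config()].
#'
#' @return A normalized blackout mask tibble (base-rate indices relative to
#'   each snippet's start).
#' @export
detect_residual_pvr <- function(group, cfg = pvr_config()) {
  stopifnot(inherits(group, "snippet_group"))
  n <- length(group$snippets)
  w <- cfg$residual_window_trials
  if (n < w) {
    abort(sprintf("group has %d trials; residual detection needs at least %d.", n, w))
  }
  f <- group$factor
  nch <- length(group$channels)
  lens <- vapply(group$snippets, ncol, integer(1))
  lmin <- min(lens)
  Tn <- lmin - 1                      # derivative length
  pre_idx <- seq_len(min(group$pre_samples * f, Tn))
  ord <- order(group$intensity_summary)
  half <- (w - 1) %/% 2

  rows <- list()
  for (c in seq_len(nch)) {
    # rectified derivative, trials (intensity order) x time
    A <- t(vapply(ord, function(i) {
      x <- group$snippets[[i]][c, 1:lmin]
      abs(diff(x))
    }, numeric(Tn)))
    S <- matrix(0, n, Tn)
    for (p in seq_len(n)) {
      h <- min(half, p - 1, n - p)
      lo <- p - h; hi <- p + h
      while (hi - lo + 1 < 3) {       # asymmetric extension at the extremes
        if (lo > 1) lo <- lo - 1 else hi <- hi + 1
      }
      W <- A[lo:hi, , drop = FALSE]
      m <- nrow(W)
      S[p, ] <- (colSums(W) - do.call(pmax, asplit(W, 1))) / (m - 1)
    }
    mu_c <- mean(S[, pre_idx])
    sd_c <- sd(S[, pre_idx])
    if (!is.finite(sd_c) || sd_c == 0) next
    # the rectified statistic has a positive baseline, so the k-SD criterion
    # is referenced to its pre-stimulation mean
    flag <- S > mu_c + cfg$residual_threshold_sd * sd_c
    for (p in seq_len(n)) {
      idx <- which(flag[p, ])
      if (length(idx) == 0) next
      base_idx <- unique((idx - 1L) %/% f)   # 0-based base-rate samples
      # convert runs of consecutive samples into intervals
      starts <- base_idx[c(1L, which(diff(base_idx) > 1L) + 1L)]
      ends_i <- base_idx[c(which(diff(base_idx) > 1L), length(base_idx))]
      rows[[length(rows) + 1]] <- tibble::tibble(
        snippet_id = ord[p], channel = c,
        start_sample = starts, end_sample = ends_i + 1L
      )
    }
  }
  if (length(rows) == 0) return(blackout_mask())
  normalize_mask(dplyr::bind_rows(rows))
}

#' Expand blackout intervals around flagged samples
#'
#' Every interval `[a, b)` becomes `[a - back, b + fwd)` (defaults 40 samples
#' back, 20 forward, at base rate), clipped to the snippet span and merged.
#' This labels all periods in which no spike window could be fully clean.
#'
#' @param mask A blackout mask tibble.
#' @param cfg A [pvr_config()].
#' @param snippet_len Snippet length(s) in base-rate samples used for
#'   clipping: a single value or a vector indexed by `snippet_id`.
#' @return The expanded, normalized mask.
#' @export
expand_blackout <- function(mask, cfg = pvr_config(), snippet_len = Inf) {
  if (nrow(mask) == 0) return(blackout_mask())
  len_of <- function(id) {
    if (length(snippet_len) == 1) snippet_len else snippet_len[id]
  }
  mask |>
    dplyr::mutate(
      start_sample = pmax(0L, start_sample - cfg$blackout_expand_back),
      end_sample = as.integer(pmin(len_of(snippet_id), end_sample + cfg$blackout_expand_fwd))
    ) |>
    normalize_mask()
}

#' Logical mask for one snippet
#'
#' @param mask A blackout mask tibble.
#' @param snippet_id Snippet to extract.
#' @param n_channels,len Dimensions of the snippet (base rate).
#' @return A channels x time logical matrix, TRUE where blacked out.
#' @export
mask_to_logical <- function(mask, snippet_id, n_channels, len) {
  out <- matrix(FALSE, n_channels, len)
  sub <- mask[mask$snippet_id == snippet_id, ]
  if (nrow(sub)) {
    for (i in seq_len(nrow(sub))) {
      a <- max(0L, sub$start_sample[i]); b <- min(len, sub$end_sample[i])
      if (b > a) out[sub$channel[i], (a + 1):b] <- TRUE
    }
  }
  out
}

#' Total number of samples covered by a mask
#' @param mask A blackout mask tibble.
#' @return Integer count of (snippet, channel) samples covered.
#' @export
mask_coverage <- function(mask) {
  if (nrow(mask) == 0) return(0L)
  sum(mask$end_sample - mask$start_sample)
}
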