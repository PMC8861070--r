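#' Bootstrap estimation of optogenetic inhibition latency
#'
#' Builds peri-inhibition time histograms pooled over sorted units and asks,
#' for each requested percentage level of the pre-onset baseline rate, when
#' the rate first falls to that level after light onset. Uncertainty comes
#' from bootstrapping units with replacement (1000 repetitions by default);
#' trial-level resampling is available as an option.
#'
#' The crossing rule is: the first post-onset bin whose rate is at or below
#' `level/100 * baseline`, with the latency reported at the bin's start.
#'
#' @param spikes Tibble of peri-pulse spike times with columns `unit_id`,
#'   `trial`, `time_ms` (relative to light onset; negative = before onset).
#' @param n_trials Number of trials each unit was observed over.
#' @param levels Percentages of the pre-inhibition rate, in (0, 100).
#' @param n_boot Bootstrap repetitions (default 1000).
#' @param bin_ms Histogram bin width, ms.
#' @param pre_ms,post_ms Histogram span before/after onset, ms.
#' @param resample Resample `"units"` (default) or `"trials"` within units.
#' @param seed Seed for the bootstrap.
#'
#' @return A tibble of class `latency_result`: `level`, `median_ms`,
#'   `q25_ms`, `q75_ms`, `n_defined` (replicates in which the level was
#'   reached). Attributes carry `n_boot`, `bin_ms` and the per-replicate
#'   latencies (`boot_ms`, levels x replicates).
#' @export
bootstrap_latency <- function(spikes, n_trials, levels = c(80, 60, 40, 20),
                              n_boot = 1000, bin_ms = 0.5, pre_ms = 30,
                              post_ms = 30, resample = c("units", "trials"),
                              seed = 1L) {
  resample <- match.arg(resample)
  stopifnot(all(c("unit_id", "trial", "time_ms") %in% names(spikes)))
  if (any(levels <= 0 | levels >= 100)) abort("levels must lie in (0, 100).")
  units <- sort(unique(spikes$unit_id))
  if (length(units) < 2) abort("need at least 2 units to bootstrap.")
  edges <- seq(-pre_ms, post_ms, by = bin_ms)
  nb <- length(edges) - 1
  pre_bins <- which(edges[-1] <= 0)
  post_bins <- which(edges[-length(edges)] >= 0)

  # per-unit histograms (counts), units x bins
  H <- t(vapply(units, function(u) {
    tu <- spikes$time_ms[spikes$unit_id == u]
    tu <- tu[tu >= -pre_ms & tu < post_ms]
    tabulate(findInterval(tu, edges, rightmost.closed = FALSE), nbins = nb)
  }, numeric(nb)))
  per_trial <- if (resample == "trials") {
    purrr::map(units, function(u) {
      su <- spikes[spikes$unit_id == u, ]
      purrr::map(seq_len(n_trials), function(tr) {
        tt <- su$time_ms[su$trial == tr]
        tt <- tt[tt >= -pre_ms & tt < post_ms]
        tabulate(findInterval(tt, edges, rightmost.closed = FALSE), nbins = nb)
      })
    })
  }

  baseline_all <- sum(H[, pre_bins]) / (length(units) * n_trials * pre_ms / 1000)
  if (baseline_all == 0) abort("baseline (pre-onset) rate is zero.")

  lat <- matrix(NA_real_, length(levels), n_boot)
  with_private_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample(length(units), replace = TRUE)
      if (resample == "units") {
        h <- colSums(H[idx, , drop = FALSE])
      } else {
        h <- colSums(t(vapply(idx, function(i) {
          trs <- sample(n_trials, replace = TRUE)
          Reduce(`+`, per_trial[[i]][trs])
        }, numeric(nb))))
      }
      rate <- h / (length(idx) * n_trials * bin_ms / 1000)
      base <- mean(rate[pre_bins])
      if (base == 0) next
      for (li in seq_along(levels)) {
        hit <- post_bins[which(rate[post_bins] <= levels[li] / 100 * base)[1]]
        if (!is.na(hit)) lat[li, b] <- edges[hit]
      }
    }
  })

  out <- tibble::tibble(
    level = levels,
    median_ms = apply(lat, 1, median, na.rm = TRUE),
    q25_ms = apply(lat, 1, quantile, probs = 0.25, na.rm = TRUE, names = FALSE),
    q75_ms = apply(lat, 1, quantile, probs = 0.75, na.rm = TRUE, names = FALSE),
    n_defined = rowSums(!is.na(lat))
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "bin_ms") <- bin_ms
  attr(out, "boot_ms") <- lat
  class(out) <- c("latency_result", class(tibble::tibble()))
  out
}

#' @export
tidy.latency_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot bootstrapped inhibition latencies per level
#' @param object A `latency_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.latency_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(level), median_ms)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = q25_ms, ymax = q75_ms)) +
    ggplot2::labs(x = "% of pre-inhibition rate", y = "latency (ms)") +
    ggplot2::theme_minimal()
}

#' Pre-inhibition split analysis
#'
#' Asks whether trials with high pre-inhibition activity also show higher
#' activity after inhibition onset. For each unit, trials are split at the
#' unit's median pre-onset spike count (strictly above vs strictly below;
#' units with a degenerate split are excluded and logged); the unit's effect
#' is the mean post-onset rate of high trials minus low trials. Units are
#' then assigned to firing-rate terciles (low/moderate/high) and, per
#' tercile, a two-sided one-sample t-test of the effects against zero is
#' performed with no multiple-comparison adjustment.
#'
#' @param counts Tibble with columns `unit_id`, `trial`, `pre_count`,
#'   `post_count`.
#' @param pre_window_s,post_window_s Durations of the pre/post count windows,
#'   seconds (convert counts to Hz).
#' @param boundaries Optional two rate boundaries (Hz) separating the groups;
#'   defaults to the data-driven terciles of the units' pre-onset rates.
#'
#' @return A tibble of class `split_result`: `group` (low/moderate/high),
#'   `n_units`, `effect_hz` (mean of high-minus-low), `sem_hz`, `p_value`.
#'   Attribute `per_unit` carries the unit-level effects.
#' @export
pre_split_analysis <- function(counts, pre_window_s, post_window_s,
                               boundaries = NULL) {
  stopifnot(all(c("unit_id", "trial", "pre_count", "post_count") %in% names(counts)))
  per_unit <- counts |>
    dplyr::group_by(unit_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 4) abort(sprintf("unit %s has fewer than 4 trials.", key$unit_id))
      med <- median(df$pre_count)
      hi <- df$pre_count > med
      lo <- df$pre_count < med
      if (!any(hi) || !any(lo)) {
        return(tibble::tibble(rate_hz = NA_real_, effect_hz = NA_real_))
      }
      tibble::tibble(
        rate_hz = mean(df$pre_count) / pre_window_s,
        effect_hz = mean(df$post_count[hi]) / post_window_s -
          mean(df$post_count[lo]) / post_window_s
      )
    }) |>
    dplyr::ungroup()

  dropped <- sum(is.na(per_unit$effect_hz))
  if (dropped > 0) {
    inform(sprintf("%d unit(s) excluded (degenerate pre-count split).", dropped))
  }
  per_unit <- dplyr::filter(per_unit, !is.na(effect_hz))
  if (nrow(per_unit) < 2) abort("fewer than 2 usable units after exclusion.")

  boundaries <- boundaries %||%
    quantile(per_unit$rate_hz, c(1 / 3, 2 / 3), names = FALSE)
  grp <- cut(per_unit$rate_hz, c(-Inf, boundaries, Inf),
             labels = c("low", "moderate", "high"))

  out <- purrr::map_dfr(levels(grp), function(g) {
    e <- per_unit$effect_hz[grp == g]
    if (length(e) < 2) {
      return(tibble::tibble(group = g, n_units = length(e),
                            effect_hz = mean(e), sem_hz = NA_real_,
                            p_value = NA_real_))
    }
    tt <- t.test(e, mu = 0, alternative = "two.sided")
    tibble::tibble(group = g, n_units = length(e), effect_hz = mean(e),
                   sem_hz = sd(e) / sqrt(length(e)), p_value = tt$p.value)
  })
  attr(out, "per_unit") <- per_unit
  class(out) <- c("split_result", class(tibble::tibble()))
  out
}
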