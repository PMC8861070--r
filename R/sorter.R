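# run expr with a private RNG state so sorting/clustering is deterministic
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the built-in spike sorter
#'
#' @param threshold_uV Negative detection threshold in uV (default -30).
#' @param window_pre,window_post Samples before/after the trough kept in each
#'   waveform (-20 to +40, i.e. 61 samples at base rate).
#' @param clusters Number of clusters requested; defaults to twice the number
#'   of channels.
#' @param refractory_samples Minimum spacing between detections on a channel.
#' @param merge_cor Template correlation above which clusters are candidates
#'   for merging.
#' @param merge_max_diff_sd Clusters are only merged if their mean waveforms
#'   additionally differ nowhere by more than this many channel-SDs
#'   (default 1): split halves of one unit agree to within the noise,
#'   co-located units of different size do not.
#' @param curate_max_trough_uV Drop units whose trough is more negative than
#'   this (unphysiological amplitude; default 400).
#' @param curate_min_trough_uV Drop units whose trough is shallower than this
#'   (clusters of bare noise crossings; default 60). `NA` disables.
#' @param curate_artifact_channels,curate_artifact_uV Drop units for which at
#'   least `curate_artifact_channels` pairwise non-adjacent channels exceed
#'   `curate_artifact_uV` (positive) at the same sample -- the signature of a
#'   synchronous light artifact spanning the probe, as opposed to a spike's
#'   contiguous footprint. Either filter can be disabled with `NA`.
#' @param curate_min_spikes Drop units with fewer member spikes than this in
#'   the inter-pulse data (unstable templates; default 10).
#' @param min_interpulse_s Minimum total inter-pulse duration required.
#' @param seed Seed for the clustering stage.
#' @return A list of class `sorter_config`.
#' @export
sorter_config <- function(threshold_uV = -30, window_pre = 20, window_post = 40,
                          clusters = NULL, refractory_samples = 30,
                          merge_cor = 0.95, merge_max_diff_sd = 1,
                          curate_max_trough_uV = 400,
                          curate_min_trough_uV = 60,
                          curate_artifact_channels = 3, curate_artifact_uV = 20,
                          curate_min_spikes = 10, min_interpulse_s = 0.5,
                          seed = 1L) {
  structure(list(
    threshold_uV = threshold_uV, window_pre = as.integer(window_pre),
    window_post = as.integer(window_post), clusters = clusters,
    refractory_samples = as.integer(refractory_samples), merge_cor = merge_cor,
    merge_max_diff_sd = merge_max_diff_sd,
    curate_max_trough_uV = curate_max_trough_uV,
    curate_min_trough_uV = curate_min_trough_uV,
    curate_artifact_channels = curate_artifact_channels,
    curate_artifact_uV = curate_artifact_uV,
    curate_min_spikes = as.integer(curate_min_spikes),
    min_interpulse_s = min_interpulse_s, seed = as.integer(seed)
  ), class = "sorter_config")
}

# local-minimum threshold crossings on one trace; returns 1-based indices
detect_on_channel <- function(x, threshold_uV, refractory) {
  below <- which(x < threshold_uV)
  if (length(below) == 0) return(integer())
  n <- length(x)
  is_min <- below[below > 1 & below < n]
  is_min <- is_min[x[is_min] <= x[is_min - 1] & x[is_min] < x[is_min + 1]]
  if (length(is_min) == 0) return(integer())
  # enforce refractory spacing, keeping the more negative trough
  keep <- integer()
  last <- -Inf
  for (t in is_min) {
    if (t - last >= refractory) {
      keep <- c(keep, t); last <- t
    } else if (x[t] < x[keep[length(keep)]]) {
      keep[length(keep)] <- t; last <- t
    }
  }
  keep
}

#' Threshold spike detection on a multichannel matrix
#'
#' Finds local minima below `threshold_uV` per channel and collapses
#' near-coincident detections across channels (a spike spread over
#' neighbouring channels counts once, on its most negative channel).
#'
#' @param mat Channels x time matrix (uV).
#' @param threshold_uV Detection threshold (default -30).
#' @param refractory Per-channel refractory spacing, samples.
#' @param coincidence Cross-channel coincidence window, samples.
#' @return Tibble with `time_sample` (0-based), `channel`, `amplitude_uV`.
#' @export
detect_threshold_events <- function(mat, threshold_uV = -30, refractory = 30,
                                    coincidence = 15) {
  ev <- purrr::map_dfr(seq_len(nrow(mat)), function(c) {
    t <- detect_on_channel(mat[c, ], threshold_uV, refractory)
    tibble::tibble(time_sample = t - 1L, channel = c, amplitude_uV = mat[c, t])
  })
  if (nrow(ev) == 0) return(ev)
  ev <- dplyr::arrange(ev, time_sample)
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    close <- which(keep & abs(ev$time_sample - ev$time_sample[i]) <= coincidence)
    best <- close[which.min(ev$amplitude_uV[close])]
    keep[setdiff(close, best)] <- FALSE
  }
  ev[keep, ]
}

#' Sort units from the artifact-free periods between light pulses
#'
#' Concatenates the inter-pulse segments of the recording (the spans outside
#' every peri-pulse snippet window) and runs a pluggable spike sorter on them.
#' The built-in sorter detects threshold crossings, clusters the waveforms
#' into twice as many clusters as there are channels, merges near-identical
#' clusters, and curates units with unphysiological amplitudes. External
#' sorter output (unit waveforms + spike times) can be supplied instead via
#' [as_unit_templates()].
#'
#' @param block A [recording_block()].
#' @param pulses Pulse tibble from [detect_pulses()].
#' @param config A [sorter_config()].
#' @param pre_ms,post_ms Peri-pulse margins excluded from the inter-pulse
#'   data; match the snippet margins.
#' @return A list of class `sorted_units` with `templates` (list of
#'   `unit_template`: `waveform` in uV, `waveform_norm` in per-channel SD
#'   units, `primary_channel`, `unit_id`, `n_spikes`) and `detections`
#'   (tibble of `time_sample` in block coordinates, `unit_id`).
#' @export
sort_interpulse <- function(block, pulses, config = sorter_config(),
                            pre_ms = 30, post_ms = 30) {
  stopifnot(inherits(block, "recording_block"))
  pre <- round(pre_ms / 1000 * block$rate)
  post <- round(post_ms / 1000 * block$rate)
  n <- ncol(block$samples)

  # complement of the peri-pulse windows, as 0-based half-open intervals
  busy <- tibble::tibble(
    s = pmax(0, pulses$onset_sample - pre),
    e = pmin(n, pulses$offset_sample + post)
  ) |> dplyr::arrange(s)
  segs <- list(); cur <- 0
  for (i in seq_len(nrow(busy))) {
    if (busy$s[i] > cur) segs[[length(segs) + 1]] <- c(cur, busy$s[i])
    cur <- max(cur, busy$e[i])
  }
  if (cur < n) segs[[length(segs) + 1]] <- c(cur, n)
  if (length(segs) == 0) abort("no inter-pulse data available for sorting.")
  total_s <- sum(vapply(segs, function(z) z[2] - z[1], numeric(1))) / block$rate
  if (total_s < config$min_interpulse_s) {
    abort(sprintf("only %.2f s of inter-pulse data; %.2f s required.",
                  total_s, config$min_interpulse_s))
  }

  cat_mat <- do.call(cbind, purrr::map(segs, function(z) {
    block$samples[, (z[1] + 1):z[2], drop = FALSE]
  }))
  seg_len <- vapply(segs, function(z) as.integer(z[2] - z[1]), integer(1))
  seg_end_cat <- cumsum(seg_len)              # concatenated coords (1-based ends)
  seg_start_cat <- seg_end_cat - seg_len
  seg_start_orig <- vapply(segs, function(z) as.integer(z[1]), integer(1))

  ev <- detect_threshold_events(cat_mat, config$threshold_uV,
                                config$refractory_samples)
  wpre <- config$window_pre; wpost <- config$window_post
  wlen <- wpre + wpost + 1L
  # drop events whose window leaves its segment (would span a pulse gap)
  seg_of <- findInterval(ev$time_sample, seg_start_cat)
  ok <- ev$time_sample - wpre >= seg_start_cat[seg_of] &
    ev$time_sample + wpost < seg_end_cat[seg_of]
  ev <- ev[ok, ]; seg_of <- seg_of[ok]
  if (nrow(ev) < 2) abort("too few threshold events in inter-pulse data to sort.")

  nch <- nrow(cat_mat)
  W <- vapply(ev$time_sample, function(t) {
    as.vector(cat_mat[, (t - wpre + 1):(t + wpost + 1), drop = FALSE])
  }, numeric(nch * wlen))                      # (nch*wlen) x n_events

  # cluster events per peak channel (clusters_per_channel x nch clusters in
  # total, i.e. twice the channel count by default), on the waveform restricted
  # to the event's channel neighbourhood -- this keeps the feature space local
  # and prevents distant channels' noise from washing out the spike shape
  k_req <- config$clusters %||% (2L * nch)
  Warr <- array(W, dim = c(nch, wlen, nrow(ev)))
  # distribute the overall cluster budget (twice the channel count by
  # default) over peak channels: shallow threshold scrapes on every channel
  # get one cluster each, and the rest of the budget goes to channels in
  # proportion to their counts of deep (unit-scale) events, so a channel
  # carrying several units can be split further while silent channels do
  # not waste budget
  deep_cut <- if (is.na(config$curate_min_trough_uV)) 2 * abs(config$threshold_uV)
              else config$curate_min_trough_uV
  act <- sort(unique(ev$channel))
  n_deep_ch <- vapply(act, function(c0) {
    sum(ev$channel == c0 & ev$amplitude_uV <= -deep_cut)
  }, numeric(1))
  budget_deep <- max(length(act), k_req - length(act))
  k_deep <- ifelse(n_deep_ch == 0, 0L,
                   pmax(1L, as.integer(round(budget_deep * n_deep_ch /
                                               max(1, sum(n_deep_ch))))))
  k_ch <- pmax(1L, pmin(k_deep + 1L,
                        vapply(act, function(c0) sum(ev$channel == c0) %/% 4L,
                               numeric(1)) + 1L))
  cl <- integer(nrow(ev))
  next_id <- 0L
  with_private_seed(config$seed, {
    for (ci in seq_along(act)) {
      c0 <- act[ci]
      idx <- which(ev$channel == c0)
      chs <- pmin(pmax((c0 - 1):(c0 + 1), 1L), nch)
      feats <- t(vapply(idx, function(i) as.vector(Warr[chs, , i]),
                        numeric(3 * wlen)))
      if (length(idx) >= 4) {
        # realign events to the channel mean before clustering: trough
        # jitter otherwise dominates the within-cluster variance and masks
        # genuine shape/amplitude differences between co-located units
        chan_mean <- colMeans(feats)
        feats <- t(vapply(seq_along(idx), function(ii) {
          t <- ev$time_sample[idx[ii]]
          shifts <- (-2):2
          shifts <- shifts[t + shifts - wpre >= 0 & t + shifts + wpost < ncol(cat_mat)]
          cand <- vapply(shifts, function(s) {
            as.vector(cat_mat[chs, (t + s - wpre + 1):(t + s + wpost + 1)])
          }, numeric(3 * wlen))
          cand[, which.min(colSums((cand - chan_mean)^2))]
        }, numeric(3 * wlen)))
      }
      k_c <- k_ch[ci]
      if (k_c == 1 || length(idx) < 4) {
        next_id <- next_id + 1L
        cl[idx] <- next_id
      } else {
        # amplitude-stratified initialization: co-located units differing
        # mainly in size are otherwise easily lumped by random starts; the
        # shallow (noise-scrape) events form their own stratum so they do
        # not dilute the unit strata
        amp <- ev$amplitude_uV[idx]
        shallow <- amp > -deep_cut
        strata <- integer(length(amp))
        rank_strata <- function(x, k) {
          if (k <= 1) rep(1L, length(x))
          else cut(rank(x, ties.method = "first"), breaks = k, labels = FALSE)
        }
        if (any(shallow) && any(!shallow) && k_c >= 2) {
          strata[shallow] <- 1L
          strata[!shallow] <- 1L + rank_strata(amp[!shallow], k_c - 1L)
        } else {
          strata <- rank_strata(amp, k_c)
        }
        strata <- match(strata, sort(unique(strata)))
        k_c <- max(strata)
        init <- t(vapply(seq_len(k_c), function(s) {
          colMeans(feats[strata == s, , drop = FALSE])
        }, numeric(ncol(feats))))
        init <- init[!duplicated(init), , drop = FALSE]
        km <- tryCatch(
          stats::kmeans(feats, centers = init, iter.max = 100),
          error = function(e) stats::kmeans(feats, centers = min(k_c, nrow(feats) - 1),
                                            iter.max = 100, nstart = 5))
        cl[idx] <- next_id + km$cluster
        next_id <- next_id + max(km$cluster)
      }
    }
  })

  ch_sd <- apply(cat_mat, 1, sd)

  # merge clusters whose mean waveforms are statistically indistinguishable:
  # similar in shape (correlation) and nowhere further apart than the noise
  # scale. Correlation alone is blind to amplitude and would collapse
  # co-located units that differ mainly in size.
  merge_tol_uV <- config$merge_max_diff_sd * mean(ch_sd)
  centers <- vapply(sort(unique(cl)), function(j) rowMeans(W[, cl == j, drop = FALSE]),
                    numeric(nch * wlen))
  cl <- match(cl, sort(unique(cl)))
  repeat {
    if (ncol(centers) < 2) break
    cm <- stats::cor(centers)
    k_now <- ncol(centers)
    for (a in seq_len(k_now - 1)) for (b in (a + 1):k_now) {
      if (max(abs(centers[, a] - centers[, b])) > merge_tol_uV) {
        cm[a, b] <- cm[b, a] <- -Inf
      }
    }
    diag(cm) <- -Inf
    if (max(cm) < config$merge_cor) break
    ij <- arrayInd(which.max(cm), dim(cm))
    a <- min(ij); b <- max(ij)
    cl[cl == b] <- a
    cl[cl > b] <- cl[cl > b] - 1L
    ks <- sort(unique(cl))
    centers <- vapply(ks, function(j) rowMeans(W[, cl == j, drop = FALSE]),
                      numeric(nch * wlen))
  }

  # realigned cluster mean: noise jitters each detected trough by a sample or
  # so, which smears a plain average; iteratively shift members onto the
  # running mean before averaging
  aligned_mean <- function(times) {
    t_al <- times
    wf <- NULL
    for (iter in 1:3) {
      Wj <- vapply(t_al, function(t) {
        as.vector(cat_mat[, (t - wpre + 1):(t + wpost + 1), drop = FALSE])
      }, numeric(nch * wlen))
      wf <- rowMeans(Wj)
      if (iter == 3) break
      t_al <- vapply(seq_along(t_al), function(i) {
        t <- t_al[i]
        shifts <- (-2):2
        shifts <- shifts[t + shifts - wpre >= 0 & t + shifts + wpost < ncol(cat_mat)]
        sse <- vapply(shifts, function(s) {
          sum((as.vector(cat_mat[, (t + s - wpre + 1):(t + s + wpost + 1)]) - wf)^2)
        }, numeric(1))
        t + shifts[which.min(sse)]
      }, numeric(1))
    }
    matrix(wf, nch, wlen)
  }

  templates <- list()
  det_rows <- list()
  uid <- 0L
  for (j in sort(unique(cl))) {
    if (sum(cl == j) < config$curate_min_spikes) next
    wf <- aligned_mean(ev$time_sample[cl == j])
    trough <- min(wf)
    if (is.finite(config$curate_max_trough_uV) &&
        !is.na(config$curate_max_trough_uV) &&
        trough < -config$curate_max_trough_uV) next
    # sub-threshold clusters are scrapes of noise crossings, not units
    if (!is.na(config$curate_min_trough_uV) &&
        trough > -config$curate_min_trough_uV) next
    if (!is.na(config$curate_artifact_channels)) {
      # count pairwise non-adjacent channels exceeding the limit at one
      # sample: a spike's positive lobe sits on a contiguous run of channels,
      # a light artifact deflects channels across the whole probe
      n_hot <- max(vapply(seq_len(wlen), function(s) {
        hot <- wf[, s] > config$curate_artifact_uV
        if (!any(hot)) return(0)
        r <- rle(hot)
        sum(ceiling(r$lengths[r$values] / 2))
      }, numeric(1)))
      if (n_hot >= config$curate_artifact_channels) next
    }
    uid <- uid + 1L
    templates[[uid]] <- structure(list(
      waveform = wf,
      waveform_norm = wf / ch_sd,
      primary_channel = which(wf == trough, arr.ind = TRUE)[1, 1],
      unit_id = uid, n_spikes = sum(cl == j)
    ), class = "unit_template")
    t_cat <- ev$time_sample[cl == j]
    sj <- seg_of[cl == j]
    det_rows[[uid]] <- tibble::tibble(
      time_sample = t_cat - seg_start_cat[sj] + seg_start_orig[sj],
      unit_id = uid
    )
  }
  structure(list(
    templates = templates,
    detections = if (length(det_rows)) dplyr::arrange(dplyr::bind_rows(det_rows), time_sample)
                 else tibble::tibble(time_sample = integer(), unit_id = integer()),
    channel_sd = ch_sd,
    clusters_requested = k_req
  ), class = "sorted_units")
}

#' @export
print.sorted_units <- function(x, ...) {
  cat(sprintf("<sorted_units> %d unit(s), %d detections\n",
              length(x$templates), nrow(x$detections)))
  invisible(x)
}

#' Adapt external sorter output to unit templates
#'
#' The pipeline treats spike sorting as a pluggable stage: any sorter that can
#' provide per-unit mean waveforms can feed the spike-recovery step.
#'
#' @param waveforms List of channels x 61 matrices (uV), one per unit
#'   (-20..+40 samples around the trough).
#' @param channel_sd Per-channel SD of the data the waveforms came from, used
#'   for the normalized representation.
#' @return A `sorted_units` object without detections.
#' @export
as_unit_templates <- function(waveforms, channel_sd) {
  templates <- purrr::imap(waveforms, function(wf, i) {
    structure(list(
      waveform = wf, waveform_norm = wf / channel_sd,
      primary_channel = which(wf == min(wf), arr.ind = TRUE)[1, 1],
      unit_id = as.integer(i), n_spikes = NA_integer_
    ), class = "unit_template")
  })
  structure(list(templates = templates,
                 detections = tibble::tibble(time_sample = integer(), unit_id = integer()),
                 channel_sd = channel_sd),
            class = "sorted_units")
}
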