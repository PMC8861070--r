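#' Clean every snippet group of a session
#'
#' Runs preprocess, per-pulse template subtraction, residual detection and
#' blackout expansion over all `(fiber, shank)` groups of a recording.
#'
#' @param block A [recording_block()].
#' @param pulses Pulse tibble from [detect_pulses()].
#' @param cfg A [pvr_config()].
#' @param pre_ms,post_ms Snippet margins, ms.
#' @return A list with `groups` (raw `snippet_groups`), `cleaned` (base-rate
#'   residual groups) and `masks` (expanded blackout mask per group).
#' @export
clean_session <- function(block, pulses, cfg = pvr_config(), pre_ms = 30,
                          post_ms = 30) {
  groups <- extract_snippets(block, pulses, pre_ms, post_ms)
  cleaned <- list(); masks <- list()
  for (key in names(groups)) {
    g <- preprocess(groups[[key]], hp_cutoff_hz = cfg$hp_cutoff_hz,
                    supersample_factor = cfg$supersample_factor,
                    method = cfg$resample_method)
    g <- clean_group(g, cfg)
    m <- detect_residual_pvr(g, cfg)
    lens <- vapply(groups[[key]]$snippets, ncol, integer(1))
    masks[[key]] <- expand_blackout(m, cfg, snippet_len = lens)
    cleaned[[key]] <- decimate_group(g)
  }
  list(groups = groups, cleaned = cleaned, masks = masks)
}

#' Residual artifact energy after template subtraction
#'
#' Using the generator's ground-truth artifact trace, measures the RMS of the
#' artifact before subtraction and of the residual artifact after
#' subtraction, over the 2 ms following light onset and light offset (where
#' the transients live), pooled over all snippets of all groups.
#'
#' @param session A `synth_session`.
#' @param cleaned Output of [clean_session()] on that session.
#' @param cfg The [pvr_config()] used.
#' @param window_ms Post-onset/post-offset measurement window, ms.
#' @return A list with `rms_before_uV`, `rms_after_uV` and
#'   `reduction_percent`.
#' @export
artifact_energy_reduction <- function(session, cleaned, cfg = pvr_config(),
                                      window_ms = 2) {
  e_pre <- 0; e_post <- 0; n_pre <- 0
  for (key in names(cleaned$groups)) {
    g0 <- cleaned$groups[[key]]
    gc1 <- cleaned$cleaned[[key]]          # base rate residuals
    rate <- g0$rate
    pre <- g0$pre_samples
    wlen <- round(window_ms / 1000 * rate)
    for (si in seq_along(g0$snippets)) {
      st <- g0$onset_sample[si] - pre
      L <- ncol(g0$snippets[[si]])
      art <- session$truth$artifact[g0$channels, (st + 1):(st + L), drop = FALSE]
      # the cleaned trace minus the artifact-free ground truth is exactly the
      # residual artifact (plus the filtering difference, negligible at 1 Hz)
      clean_truth <- g0$snippets[[si]] - art
      resid <- gc1$snippets[[si]] - preprocess.matrix(
        clean_truth, hp_cutoff_hz = cfg$hp_cutoff_hz, supersample_factor = 1,
        rate = rate)
      dur <- g0$offset_sample[si] - g0$onset_sample[si]
      win <- c((pre + 1):(pre + wlen), (pre + dur + 1):(pre + dur + wlen))
      win <- win[win <= L]
      e_pre <- e_pre + sum(art[, win]^2)
      e_post <- e_post + sum(resid[, win]^2)
      n_pre <- n_pre + length(win) * nrow(art)
    }
  }
  list(rms_before_uV = sqrt(e_pre / n_pre), rms_after_uV = sqrt(e_post / n_pre),
       reduction_percent = 100 * (1 - sqrt(e_post / e_pre)))
}

#' Score recovered spikes against ground truth inside pulse windows
#'
#' True positives and false negatives are counted over the *assessable*
#' ground-truth spikes: those falling inside a pulse window whose spike
#' window does not intersect the expanded blackout mask (the mask is the
#' method's explicit abstention, so recovery there is not graded). Recovered
#' valid events matching no ground-truth spike at all (masked or not) count
#' as false positives; events matching a masked-out truth are boundary cases
#' and are not graded either way.
#'
#' @param session A `synth_session`.
#' @param cleaned Output of [clean_session()].
#' @param spikes_by_group Named list of [match_spikes()] outputs, one per
#'   group key.
#' @param tolerance_samples Matching tolerance between recovered and true
#'   spike times (default 30 samples = 1 ms at 30 kHz).
#' @return A list with `tp`, `fp`, `fn`, `n_assessable`, `n_masked_truth`,
#'   `precision`, `recall`, `f1`.
#' @export
score_spike_recovery <- function(session, cleaned, spikes_by_group,
                                 tolerance_samples = 30) {
  truth <- session$truth$spikes
  prim <- vapply(session$truth$units, function(u) u$primary_channel, numeric(1))
  tp <- 0; fp <- 0; fn <- 0; n_assess <- 0; n_masked <- 0
  for (key in names(cleaned$cleaned)) {
    gg <- cleaned$cleaned[[key]]
    m <- cleaned$masks[[key]]
    sp <- spikes_by_group[[key]]
    nch <- length(gg$channels)
    for (si in seq_along(gg$snippets)) {
      a <- gg$onset_sample[si]; b <- gg$offset_sample[si]
      st <- a - gg$pre_samples
      L <- ncol(gg$snippets[[si]])
      M <- mask_to_logical(m, si, nch, L)
      # truths slightly outside the pulse window can still absorb recovered
      # events at the window edge; only in-window truths are graded
      tt_pad <- truth[truth$time_sample >= a - 2 * tolerance_samples &
                        truth$time_sample < b + 2 * tolerance_samples &
                        prim[truth$unit_id] %in% gg$channels, , drop = FALSE]
      tt <- tt_pad[tt_pad$time_sample >= a & tt_pad$time_sample < b, , drop = FALSE]
      assessable <- logical(nrow(tt))
      if (nrow(tt)) {
        assessable <- vapply(seq_len(nrow(tt)), function(i) {
          tl <- tt$time_sample[i] - st
          ci <- match(prim[tt$unit_id[i]], gg$channels)
          chs <- unique(pmin(pmax((ci - 1):(ci + 1), 1), nch))
          win <- (tl - 22):(tl + 42) + 1
          win <- win[win >= 1 & win <= L]
          !any(M[chs, win])
        }, logical(1))
      }
      n_masked <- n_masked + sum(!assessable)
      n_assess <- n_assess + sum(assessable)
      rec <- sp[sp$snippet_id == si & sp$valid &
                  sp$block_sample >= a & sp$block_sample < b, , drop = FALSE]
      used <- rep(FALSE, nrow(rec))
      if (nrow(tt)) {
        # match assessable truths first (TP/FN), then masked truths (ungraded)
        for (pass in c(TRUE, FALSE)) {
          for (i in which(assessable == pass)) {
            d <- abs(rec$block_sample - tt$time_sample[i])
            hit <- which(!used & d <= tolerance_samples)
            if (length(hit)) {
              used[hit[which.min(d[hit])]] <- TRUE
              if (pass) tp <- tp + 1
            } else if (pass) fn <- fn + 1
          }
        }
      }
      # absolve events that correspond to truths just outside the window
      if (any(!used) && nrow(tt_pad)) {
        edge <- tt_pad[tt_pad$time_sample < a | tt_pad$time_sample >= b, ,
                       drop = FALSE]
        for (t in edge$time_sample) {
          d <- abs(rec$block_sample - t)
          hit <- which(!used & d <= tolerance_samples)
          if (length(hit)) used[hit[which.min(d[hit])]] <- TRUE
        }
      }
      fp <- fp + sum(!used)
    }
  }
  list(tp = tp, fp = fp, fn = fn, n_assessable = n_assess,
       n_masked_truth = n_masked,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}
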