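test_that("sorter requests twice as many clusters as channels", {
  ses <- small_session(seed = 13)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  units <- sort_interpulse(ses$block, p, sorter_config())
  expect_equal(units$clusters_requested, 2 * nrow(ses$block$samples))
})

test_that("curation drops units with unphysiological amplitudes", {
  # a -450 uV unit is removed (negative amplitude larger than 400 uV)
  ses <- small_session(seed = 21, n_units = 2, trough_uV = c(440, 460))
  p <- detect_pulses(ses$light, min_separation = 0.01)
  units <- sort_interpulse(ses$block, p, sorter_config())
  troughs <- vapply(units$templates, function(u) min(u$waveform), numeric(1))
  expect_true(all(troughs > -400))
  # with the filter disabled the deep units survive
  units2 <- sort_interpulse(ses$block, p,
                            sorter_config(curate_max_trough_uV = Inf))
  troughs2 <- vapply(units2$templates, function(u) min(u$waveform), numeric(1))
  expect_true(any(troughs2 < -400))
})

test_that("two well-separated units are recovered with high assignment accuracy", {
  ses <- synth_scenario("artifact-free", seed = 31, n_pulses = 20, channels = 8,
                        n_units = 2, fibers = 2, trough_uV = c(120, 180),
                        unit_rate_hz = c(8, 12), gap_ms = 300)
  # force distinct primary channels by regenerating until separated (seeded)
  prim <- vapply(ses$truth$units, function(u) u$primary_channel, numeric(1))
  expect_true(length(unique(prim)) == 2)   # seed chosen to give separation
  p <- detect_pulses(ses$light, min_separation = 0.01)
  units <- sort_interpulse(ses$block, p, sorter_config())
  det <- units$detections
  truth <- ses$truth$spikes
  # inter-pulse truth only (spikes inside peri-pulse windows are not sorted)
  pre <- 900; post <- 900
  busy <- vapply(seq_len(nrow(truth)), function(i) {
    any(truth$time_sample[i] >= p$onset_sample - pre - 61 &
          truth$time_sample[i] < p$offset_sample + post + 61)
  }, logical(1))
  hit <- vapply(which(!busy), function(i) {
    any(abs(det$time_sample - truth$time_sample[i]) <= 3)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("matching recovers a pure template exactly and respects the mask", {
  # a biphasic 3-channel unit waveform, trough -150 uV at the middle channel
  t_rel <- -20:40
  shape <- -exp(-(t_rel + 2)^2 / (2 * 2.5^2)) + 0.25 * exp(-(t_rel - 8)^2 / 72)
  wf <- rbind(shape * 75, shape * 150, shape * 75)
  L <- 2100; t0 <- 1001
  set.seed(1)
  X <- matrix(rnorm(3 * L, sd = 2), 3)      # faint noise floor breaks ties
  X[, (t0 - 20):(t0 + 40)] <- X[, (t0 - 20):(t0 + 40)] + wf
  g <- toy_group(list(X))
  # templates share the snippet's normalization, so a self-match is near-exact
  units <- as_unit_templates(list(wf), channel_sd = apply(X, 1, sd))
  sp <- match_spikes(g, blackout_mask(), units, match_config())
  expect_equal(nrow(sp), 1)
  expect_equal(sp$unit_id, 1L)
  expect_lt(abs(sp$time_sample - (t0 - 1L)), 4)   # the waveform trough
  expect_lt(sp$error, 0.5)    # self-match: far below the acceptance threshold
  expect_true(sp$valid)

  # an event whose -20/+40 window overlaps a blackout interval is invalid
  m <- blackout_mask(1, 2, (t0 - 1) + 30, (t0 - 1) + 32)
  sp2 <- match_spikes(g, m, units, match_config())
  expect_equal(nrow(sp2), 1)
  expect_false(sp2$valid)

  # a fully masked snippet yields no events (and says so)
  mfull <- blackout_mask(rep(1, 3), 1:3, rep(0, 3), rep(L, 3))
  expect_message(sp3 <- match_spikes(g, mfull, units, match_config()),
                 "fully masked")
  expect_equal(nrow(sp3), 0)
})

test_that("matching is deterministic and invariant to positive rescaling", {
  ses <- small_session(seed = 19)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  units <- sort_interpulse(ses$block, p, sorter_config())
  cfg <- pvr_config(k_neighbors = 10)
  g <- extract_snippets(ses$block, p)[[1]]
  gc1 <- decimate_group(clean_group(preprocess(g), cfg))
  m <- expand_blackout(detect_residual_pvr(clean_group(preprocess(g), cfg), cfg),
                       cfg, snippet_len = ncol(g$snippets[[1]]))
  a <- match_spikes(gc1, m, units, match_config())
  b <- match_spikes(gc1, m, units, match_config())
  expect_identical(a, b)

  g2 <- gc1
  g2$snippets <- lapply(g2$snippets, function(x) x * 3.7)
  u2 <- units
  u2$templates <- lapply(u2$templates, function(u) {
    u$waveform <- u$waveform * 3.7
    u$waveform_norm <- u$waveform / (units$channel_sd * 3.7)
    u
  })
  c2 <- match_spikes(g2, m, u2, match_config())
  expect_equal(a$time_sample, c2$time_sample)
  expect_equal(a$unit_id, c2$unit_id)
  expect_equal(a$error, c2$error, tolerance = 1e-10)
})

test_that("no valid spike's window intersects the expanded mask", {
  ses <- small_session(seed = 23)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  units <- sort_interpulse(ses$block, p, sorter_config())
  cfg <- pvr_config(k_neighbors = 10)
  cl <- clean_session(ses$block, p, cfg)
  for (key in names(cl$cleaned)) {
    g <- cl$cleaned[[key]]; m <- cl$masks[[key]]
    sp <- match_spikes(g, m, units, match_config())
    sp <- sp[sp$valid, ]
    for (i in seq_len(nrow(sp))) {
      M <- mask_to_logical(m, sp$snippet_id[i], length(g$channels),
                           ncol(g$snippets[[sp$snippet_id[i]]]))
      win <- (sp$time_sample[i] - 20):(sp$time_sample[i] + 40) + 1
      win <- win[win >= 1 & win <= ncol(M)]
      chs <- unique(pmin(pmax(sp$channel[i] + (-1:1), 1), length(g$channels)))
      expect_false(any(M[chs, win]))
    }
  }
})

test_that("weighted PSTH averages only unmasked trials per bin", {
  g <- toy_group(replicate(4, matrix(rnorm(2 * 2100), 2), simplify = FALSE))
  g$onset_sample <- c(900, 3900, 6900, 9900)
  g$offset_sample <- g$onset_sample + 300
  spikes <- tibble::tibble(
    snippet_id = c(1L, 2L, 3L, 4L, 1L),
    time_sample = c(950L, 950L, 950L, 950L, 1500L),
    block_sample = 0L, channel = 1L, unit_id = 1L, error = 0.1,
    valid = TRUE
  )
  # no blackout anywhere: plain PSTH; bin 1.667..3.33 ms holds one spike per
  # trial at sample 950 (50 samples = 1.667 ms after onset)
  p0 <- weighted_psth(spikes, blackout_mask(), g, bin_ms = 2)
  b <- which(p0$bin_start_ms <= 1.7 & p0$bin_end_ms > 1.7)
  expect_equal(p0$rate_hz[b], 1 / 0.002)       # 1 spike / 2 ms in every trial
  expect_true(all(p0$pct_masked_trials == 0))

  # the same bin masked in half the trials: mean over the unmasked half and
  # a reported 50% masked-trial percentage
  m <- blackout_mask(c(1L, 2L), c(1L, 1L), c(945L, 945L), c(960L, 960L))
  p1 <- weighted_psth(spikes, m, g, bin_ms = 2)
  expect_equal(p1$pct_masked_trials[b], 50)
  expect_equal(p1$rate_hz[b], 1 / 0.002)       # both unmasked trials had a spike
  expect_equal(p1$n_trials_used[b], 2)

  # a bin masked in all trials is undefined; neighbours are unaffected
  mall <- blackout_mask(1:4, rep(1L, 4), rep(945L, 4), rep(960L, 4))
  p2 <- weighted_psth(spikes, mall, g, bin_ms = 2)
  expect_true(p2$undefined[b])
  expect_true(is.na(p2$rate_hz[b]))
  expect_false(p2$undefined[b + 2])
  expect_error(weighted_psth(spikes, mall, g, bin_ms = 0), "bin_ms")
})
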