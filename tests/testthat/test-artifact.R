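test_that("pvr_config validates its invariants", {
  expect_s3_class(pvr_config(), "pvr_config")
  expect_error(pvr_config(k_neighbors = 1), "k_neighbors")
  expect_error(pvr_config(residual_window_trials = 4), "odd")
  expect_error(pvr_config(residual_threshold_sd = 0), "residual_threshold_sd")
})

test_that("template is the mean of the k nearest snippets, including self", {
  # all snippets identical -> template equals any snippet exactly
  base <- matrix(rnorm(2 * 2100), 2)
  g <- toy_group(replicate(6, base, simplify = FALSE))
  tpl <- build_pulse_template(g, 3, pvr_config(k_neighbors = 5))
  expect_equal(tpl$onset_template, base)
  expect_equal(tpl$offset_template, base)

  # k = 2, snippets {x, x + d}: template = x + d/2, residual = -d/2
  x <- matrix(rnorm(2 * 2100), 2)
  d <- matrix(rnorm(2 * 2100, sd = 0.1), 2)
  g2 <- toy_group(list(x, x + d))
  tpl2 <- build_pulse_template(g2, 1, pvr_config(k_neighbors = 2))
  expect_equal(tpl2$onset_template, x + d / 2)
  merged <- merge_onset_offset(tpl2, g2, pvr_config(k_neighbors = 2))
  expect_equal(subtract_template(g2$snippets[[1]], merged), -d / 2)

  expect_error(build_pulse_template(g2, 1, pvr_config(k_neighbors = 20)),
               "smaller k")
})

test_that("a spike in one of k averaged snippets is attenuated by 1/k", {
  base <- matrix(0, 2, 2100)
  base[1, 901:1200] <- 1000                       # rectangular artifact
  spike <- numeric(2100); spike[1050:1060] <- -c(1:6, 5:1) / 6 * 150
  for (k in c(5, 10, 20)) {
    snips <- replicate(k, base, simplify = FALSE)
    snips[[1]][2, ] <- snips[[1]][2, ] + spike    # spike in the cleaned pulse
    g <- toy_group(snips)
    cfg <- pvr_config(k_neighbors = k)
    tpl <- build_pulse_template(g, 1, cfg)
    res <- subtract_template(g$snippets[[1]], merge_onset_offset(tpl, g, cfg))
    reduction <- 1 - min(res[2, ]) / min(spike)
    expect_equal(reduction, 1 / k, tolerance = 1e-10)
  }
})

test_that("onset/offset templates are joined by a linear ramp over the overlap", {
  cfg <- pvr_config()
  # 100 samples at 30 kHz = 3.3 ms
  expect_equal(round(cfg$overlap_samples / 30000 * 1000, 1), 3.3)

  # identical onset and offset templates -> merged equals either everywhere
  base <- matrix(rnorm(2100), 1)
  g <- toy_group(replicate(3, base, simplify = FALSE))
  tpl <- build_pulse_template(g, 1, pvr_config(k_neighbors = 3))
  merged <- merge_onset_offset(tpl, g, pvr_config(k_neighbors = 3))
  expect_equal(merged, base)

  # constant-0 onset and constant-1 offset -> linear 0 to 1 ramp inside the
  # overlap (closed form), constants outside
  tpl2 <- tpl
  tpl2$onset_template <- matrix(0, 1, 2100)
  tpl2$offset_template <- matrix(1, 1, 2100)
  m2 <- merge_onset_offset(tpl2, g, pvr_config(k_neighbors = 3))
  dur <- 300; ov <- 100
  mid <- 900 + dur / 2
  a <- mid - ov / 2
  expect_equal(m2[1, 1:a], rep(0, a))
  expect_equal(m2[1, (a + 1):(a + ov)], seq(0, 1, length.out = ov))
  expect_equal(m2[1, (a + ov + 1):2100], rep(1, 2100 - a - ov))

  # pulse shorter than the overlap is refused
  gs <- toy_group(replicate(3, base, simplify = FALSE), pulse_samples = 50)
  tps <- build_pulse_template(gs, 1, pvr_config(k_neighbors = 3))
  expect_error(merge_onset_offset(tps, gs, pvr_config(k_neighbors = 3)),
               "shorter than")
})

test_that("subtraction handles trivial cases and shape mismatch", {
  x <- matrix(rnorm(40), 4)
  expect_equal(subtract_template(x, x), matrix(0, 4, 10))
  expect_equal(subtract_template(x, matrix(0, 4, 10)), x)
  expect_error(subtract_template(x, matrix(0, 4, 9)), "shape")
})

test_that("residual detector excludes the largest trial and flags shared transients", {
  set.seed(42)
  n <- 15; nch <- 2; L <- 2100
  mk <- function() replicate(n, matrix(rnorm(nch * L), nch), simplify = FALSE)
  cfg <- pvr_config(k_neighbors = 5)

  # a huge transient in exactly one trial: it is the window maximum and is
  # dropped, so neighbouring trials stay unflagged
  snips <- mk()
  snips[[8]][1, 1001:1004] <- 80
  g <- toy_group(snips, intensities = seq_len(n))
  m <- detect_residual_pvr(g, cfg)
  others <- m[m$snippet_id != 8 & m$channel == 1 &
                m$start_sample >= 995 & m$end_sample <= 1010, ]
  expect_equal(nrow(others), 0)

  # the same transient in 7 intensity-adjacent trials is flagged in most
  snips2 <- mk()
  for (i in 5:11) snips2[[i]][1, 1001:1004] <- 80
  g2 <- toy_group(snips2, intensities = seq_len(n))
  m2 <- detect_residual_pvr(g2, cfg)
  hit <- vapply(5:11, function(i) {
    any(m2$snippet_id == i & m2$channel == 1 &
          m2$start_sample < 1005 & m2$end_sample > 1000)
  }, logical(1))
  expect_gte(sum(hit), 6)
})

test_that("white-noise false-positive rate matches a permuted-order rerun", {
  set.seed(1)
  n <- 21; L <- 2100
  snips <- replicate(n, matrix(rnorm(L), 1), simplify = FALSE)
  g <- toy_group(snips, intensities = seq_len(n))
  cfg <- pvr_config()
  m <- detect_residual_pvr(g, cfg)
  rate_obs <- mask_coverage(m) / (n * L)

  # permutation oracle: the intensity order carries no structure for white
  # noise, so a shuffled order must give a statistically equal rate
  set.seed(2)
  g_perm <- toy_group(snips, intensities = sample(n))
  rate_perm <- mask_coverage(detect_residual_pvr(g_perm, cfg)) / (n * L)
  expect_lt(rate_obs, max(2 * rate_perm, 0.01))
})

test_that("residual mask is monotone in the detection threshold", {
  ses <- small_session(seed = 9)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  g <- extract_snippets(ses$block, p)
  gp <- preprocess(g[[1]])
  gc1 <- clean_group(gp, pvr_config(k_neighbors = 10))
  m4 <- detect_residual_pvr(gc1, pvr_config(k_neighbors = 10, residual_threshold_sd = 4))
  m5 <- detect_residual_pvr(gc1, pvr_config(k_neighbors = 10, residual_threshold_sd = 5))
  # every interval of the 5-SD mask lies inside an interval of the 4-SD mask
  for (i in seq_len(nrow(m5))) {
    inside <- m4$snippet_id == m5$snippet_id[i] & m4$channel == m5$channel[i] &
      m4$start_sample <= m5$start_sample[i] & m4$end_sample >= m5$end_sample[i]
    expect_true(any(inside))
  }
  expect_lte(mask_coverage(m5), mask_coverage(m4))
})

test_that("blackout expansion widens, clips and merges intervals", {
  cfg <- pvr_config()
  # a single flagged sample at t becomes [t - 40, t + 21)
  m <- blackout_mask(1, 1, 100, 101)
  e <- expand_blackout(m, cfg, snippet_len = 2100)
  expect_equal(e$start_sample, 60)
  expect_equal(e$end_sample, 121)

  expect_equal(nrow(expand_blackout(blackout_mask(), cfg, 2100)), 0)

  # two intervals 30 samples apart merge after expansion (40 + 20 > 30)
  m2 <- blackout_mask(c(1, 1), c(1, 1), c(100, 131), c(101, 132))
  e2 <- expand_blackout(m2, cfg, snippet_len = 2100)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$start_sample, 60)
  expect_equal(e2$end_sample, 152)

  # clipped at the snippet bounds
  e3 <- expand_blackout(blackout_mask(1, 1, 10, 11), cfg, snippet_len = 20)
  expect_equal(e3$start_sample, 0)
  expect_equal(e3$end_sample, 20)
})

test_that("masking bookkeeping never alters data and normalization merges", {
  m <- normalize_mask(tibble::tibble(snippet_id = c(1L, 1L), channel = c(1L, 1L),
                                     start_sample = c(5L, 8L), end_sample = c(10L, 12L)))
  expect_equal(nrow(m), 1)
  expect_equal(m$start_sample, 5L)
  expect_equal(m$end_sample, 12L)
  lg <- mask_to_logical(m, 1, 2, 20)
  expect_equal(sum(lg), 7)
  expect_equal(mask_coverage(m), 7L)
})
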