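test_that("pulse detection places onset and offset at the half-maximum", {
  rate <- 30000
  tr <- numeric(3000)
  tr[1001:1300] <- 1                      # ideal rectangular 10 ms pulse
  p <- detect_pulses(light_log(tr, rate))
  expect_equal(nrow(p), 1)
  expect_equal(p$onset_sample, 1000)      # 0-based rising edge
  expect_equal(p$offset_sample, 1300)     # half-open: duration = 300 = 10 ms
  expect_equal(p$intensity_summary, 1)

  # 0.1 ms linear rise to plateau: onset at the first sample >= half max,
  # i.e. mid-slope (closed form: ramp value i/3 crosses 0.5 at i = 2)
  tr2 <- numeric(3000)
  tr2[1001:1003] <- (1:3) / 3
  tr2[1004:1300] <- 1
  p2 <- detect_pulses(light_log(tr2, rate))
  expect_equal(p2$onset_sample, 1001)     # 0-based index of the 2/3 sample

  expect_equal(nrow(detect_pulses(light_log(numeric(500), rate))), 0)
})

test_that("pulse detection is exact for K rectangular pulses per fiber", {
  rate <- 30000
  k <- 7
  tr <- numeric(40000)
  onsets <- 2000 + (0:(k - 1)) * 5000
  for (o in onsets) tr[(o + 1):(o + 300)] <- runif(1, 0.5, 2)
  p <- detect_pulses(light_log(tr, rate), min_separation = 0.01)
  expect_equal(nrow(p), k)
  expect_true(all(abs(p$onset_sample - onsets) <= 1))
  expect_true(all(p$offset_sample - p$onset_sample == 300))
})

test_that("light logs at a different rate are interpolated to the recording", {
  tr <- numeric(1000); tr[301:400] <- 1    # 10 kHz log
  p <- detect_pulses(light_log(tr, rate = 10000), target_rate = 30000)
  expect_equal(nrow(p), 1)
  expect_equal(p$offset_sample - p$onset_sample, 300, tolerance = 0.02)
})

test_that("non-finite light intensities are rejected", {
  expect_error(light_log(c(0, 1, NA, 0)), "finite")
  expect_error(light_log(c(0, -1, 0)), "non-negative")
})

test_that("snippet extraction yields 70 ms snippets in eight groups", {
  ses <- synth_scenario("default", seed = 11, n_pulses = 16, channels = 8,
                        n_units = 0, fibers = 4)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  g <- extract_snippets(ses$block, p)
  expect_length(g, 8)                      # 4 fibers x 2 shanks
  lens <- unlist(lapply(g, function(gg) vapply(gg$snippets, ncol, integer(1))))
  durs_ms <- lens / ses$block$rate * 1000
  expect_true(all(abs(durs_ms - 70) <= 0.1))  # 10 ms pulse + 30 + 30 margins
})

test_that("a pulse whose window leaves the recording is dropped with a warning", {
  blk <- recording_block(matrix(rnorm(2 * 5000), 2), rate = 30000,
                         channel_positions = c(0, 50), shank_id = c(1, 1))
  pulses <- tibble::tibble(fiber_id = 1L, onset_sample = c(10L, 2000L),
                           offset_sample = c(310L, 2300L),
                           intensity_summary = c(1, 1))
  expect_warning(g <- extract_snippets(blk, pulses), "dropped")
  expect_length(g[["f1_s1"]]$snippets, 1)
})

test_that("extraction is lossless against the source block", {
  ses <- small_session(seed = 3)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  g <- extract_snippets(ses$block, p)
  for (gg in g[1:2]) {
    for (i in seq_along(gg$snippets)) {
      a <- gg$onset_sample[i] - gg$pre_samples
      b <- gg$offset_sample[i] + gg$post_samples
      expect_identical(gg$snippets[[i]],
                       ses$block$samples[gg$channels, (a + 1):b, drop = FALSE])
    }
  }
})

test_that("preprocessing supersamples, removes DC and preserves band content", {
  rate <- 30000
  x <- matrix(rnorm(2100), 1)
  y <- preprocess(x, hp_cutoff_hz = 1, supersample_factor = 4, rate = rate)
  expect_equal(ncol(y), 8400)
  expect_error(preprocess(x, supersample_factor = 0), "factor")

  # constant offset is killed by the high-pass
  cst <- matrix(500, 1, 2100)
  yc <- preprocess(cst, hp_cutoff_hz = 1, supersample_factor = 1, rate = rate)
  expect_lt(abs(mean(yc)), 5)             # within 1% of the 500 uV offset

  # 1 kHz sine amplitude preserved within 2% (compare to the analytic sine
  # evaluated on the supersampled grid)
  t <- seq_len(2100) - 1
  s <- matrix(3 * sin(2 * pi * 1000 * t / rate), 1)
  ys <- preprocess(s, hp_cutoff_hz = NULL, supersample_factor = 4, rate = rate)
  t4 <- seq(0, 2100 - 1 / 4, by = 1 / 4)
  ref <- 3 * sin(2 * pi * 1000 * t4 / rate)
  mid <- 200:8200                         # away from the circular-FFT edges
  expect_lt(max(abs(ys[mid] - ref[mid])), 0.02 * 3)
})

test_that("supersampling then decimating reproduces the base-rate signal", {
  ses <- small_session(seed = 5)
  p <- detect_pulses(ses$light, min_separation = 0.01)
  g <- extract_snippets(ses$block, p)
  gp <- preprocess(g[[1]], hp_cutoff_hz = NULL, supersample_factor = 4)
  gd <- decimate_group(gp)
  for (i in 1:3) {
    ref <- g[[1]]$snippets[[i]]
    ref <- ref - rowMeans(ref)              # preprocess removes DC
    err <- max(abs(gd$snippets[[i]] - ref))
    expect_lt(err, 0.01 * stats::sd(ref))
  }
})

test_that("recording block invariants are enforced", {
  expect_error(recording_block(matrix(1, 2, 10), rate = -1,
                               channel_positions = c(0, 50), shank_id = c(1, 1)),
               "rate")
  expect_error(recording_block(matrix(1, 2, 10),
                               channel_positions = c(50, 50), shank_id = c(1, 1)),
               "monotone")
})
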