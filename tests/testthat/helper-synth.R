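# small sessions shared across tests; sized so one group comfortably holds
# k_neighbors same-intensity trials without the cost of the full scenario
small_session <- function(seed = 7, ...) {
  synth_scenario("default", seed = seed, n_pulses = 60, channels = 8,
                 n_units = 4, fibers = 2, intensity_levels = c(20, 60),
                 gap_ms = 200, ...)
}

# a snippet group built directly from matrices (bypasses extraction), for
# unit tests of the template/residual operations
toy_group <- function(snippets, intensities = seq_along(snippets),
                      rate = 30000, factor = 1L, pre_samples = 900,
                      pulse_samples = 300) {
  n <- length(snippets)
  structure(list(
    fiber_id = 1L, shank_id = 1L,
    channels = seq_len(nrow(snippets[[1]])),
    channel_positions = 50 * seq_len(nrow(snippets[[1]])),
    rate = rate, factor = as.integer(factor),
    pre_samples = pre_samples, post_samples = pre_samples,
    onset_sample = rep(pre_samples, n),
    offset_sample = rep(pre_samples + pulse_samples, n),
    intensity_summary = intensities,
    snippets = snippets
  ), class = "snippet_group")
}
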