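#' Extract peri-pulse snippets grouped by fiber and shank
#'
#' Cuts a window from `pre_ms` before each pulse onset to `post_ms` after its
#' offset, separately for each probe shank, and groups the resulting snippets
#' by the `(fiber, shank)` pair (e.g. four fibers on a two-shank probe give
#' eight groups). Artifact templates are later built within a group, since the
#' photovoltaic response depends on both the light source and the shank.
#'
#' @param block A [recording_block()].
#' @param pulses Pulse tibble as returned by [detect_pulses()] (0-based,
#'   half-open sample indices on `block`'s timebase).
#' @param pre_ms,post_ms Margins before onset / after offset, milliseconds.
#'
#' @return A named list of class `snippet_groups`; each element is a
#'   `snippet_group` holding the group's channels and one channels x time
#'   matrix per pulse. Pulses whose window falls outside the recording are
#'   dropped with a warning.
#' @export
extract_snippets <- function(block, pulses, pre_ms = 30, post_ms = 30) {
  stopifnot(inherits(block, "recording_block"))
  req <- c("fiber_id", "onset_sample", "offset_sample", "intensity_summary")
  if (!all(req %in% names(pulses))) {
    abort("`pulses` must have columns fiber_id, onset_sample, offset_sample, intensity_summary.")
  }
  pre <- round(pre_ms / 1000 * block$rate)
  post <- round(post_ms / 1000 * block$rate)
  n_total <- ncol(block$samples)

  if (nrow(pulses) > 0) {
    ok <- pulses$onset_sample - pre >= 0 & pulses$offset_sample + post <= n_total
    if (any(!ok)) {
      warn(sprintf("%d pulse(s) dropped: snippet window outside the recording.",
                   sum(!ok)))
      pulses <- pulses[ok, ]
    }
  }

  groups <- list()
  for (f in sort(unique(pulses$fiber_id))) {
    pf <- dplyr::filter(pulses, fiber_id == f)
    for (s in sort(unique(block$shank_id))) {
      ch <- which(block$shank_id == s)
      snips <- purrr::map(seq_len(nrow(pf)), function(i) {
        a <- pf$onset_sample[i] - pre     # 0-based inclusive start
        b <- pf$offset_sample[i] + post   # 0-based exclusive end
        block$samples[ch, (a + 1):b, drop = FALSE]
      })
      key <- sprintf("f%d_s%d", f, s)
      groups[[key]] <- structure(
        list(
          fiber_id = f, shank_id = s,
          channels = ch,
          channel_positions = block$channel_positions[ch],
          rate = block$rate, factor = 1L,
          pre_samples = pre, post_samples = post,
          onset_sample = pf$onset_sample, offset_sample = pf$offset_sample,
          intensity_summary = pf$intensity_summary,
          snippets = snips
        ),
        class = "snippet_group"
      )
    }
  }
  structure(groups, class = "snippet_groups")
}

#' @export
print.snippet_group <- function(x, ...) {
  cat(sprintf("<snippet_group> fiber %d, shank %d: %d snippets, %d channels @ %g Hz (x%d)\n",
              x$fiber_id, x$shank_id, length(x$snippets), length(x$channels),
              x$rate, x$factor))
  invisible(x)
}

#' @export
print.snippet_groups <- function(x, ...) {
  cat(sprintf("<snippet_groups> %d group(s)\n", length(x)))
  for (g in x) print(g)
  invisible(x)
}

#' Band-limited (Fourier) resampling by an integer factor
#'
#' Zero-pads the discrete spectrum so the band content below the original
#' Nyquist is preserved exactly; samples at multiples of `factor` reproduce the
#' input.
#'
#' @param x Numeric vector.
#' @param factor Integer upsampling factor (>= 1).
#' @return Numeric vector of length `length(x) * factor`.
#' @export
resample_fourier <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1) abort("`factor` must be an integer >= 1.")
  if (factor == 1) return(x)
  n <- length(x)
  N <- n * factor
  X <- fft(x)
  Y <- complex(real = numeric(N), imaginary = numeric(N))
  if (n %% 2 == 0) {
    half <- n / 2
    Y[1:half] <- X[1:half]
    # split the (real) Nyquist bin between +/- Nyquist of the padded spectrum
    Y[half + 1] <- X[half + 1] / 2
    Y[N - half + 1] <- X[half + 1] / 2
    if (half >= 2) Y[(N - half + 2):N] <- X[(half + 2):n]
  } else {
    half <- (n - 1) / 2
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(N - half + 1):N] <- X[(half + 2):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Cubic-spline resampling by an integer factor
#' @inheritParams resample_fourier
#' @return Numeric vector of length `length(x) * factor`.
#' @export
resample_spline <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1) abort("`factor` must be an integer >= 1.")
  if (factor == 1) return(x)
  n <- length(x)
  stats::spline(seq_len(n), x, xout = seq(1, n + 1 - 1 / factor, by = 1 / factor),
                method = "natural")$y
}

#' High-pass filter and supersample peri-pulse data
#'
#' Applies a zero-phase (forward-backward) first-order Butterworth high-pass
#' and then supersamples by an integer factor to refine the temporal alignment
#' of artifact transients. The default resampler is band-limited (Fourier);
#' spline resampling is available via `method`.
#'
#' @param x A numeric matrix (channels x time), a `snippet_group`, or a
#'   `snippet_groups` list.
#' @param hp_cutoff_hz High-pass cutoff in Hz (default 1); `NULL` or 0 skips
#'   filtering.
#' @param supersample_factor Integer factor >= 1 (default 4).
#' @param rate Sampling rate of `x` (matrix method only).
#' @param method Resampling method, `"fourier"` or `"spline"`.
#' @param ... Passed between methods.
#'
#' @return The input with every trace filtered and `factor` times longer; for
#'   groups, the `factor` field is multiplied accordingly.
#' @export
preprocess <- function(x, ...) UseMethod("preprocess")

#' @rdname preprocess
#' @export
preprocess.matrix <- function(x, hp_cutoff_hz = 1, supersample_factor = 4,
                              rate = 30000, method = c("fourier", "spline"), ...) {
  method <- match.arg(method)
  supersample_factor <- as.integer(supersample_factor)
  if (supersample_factor < 1) abort("`supersample_factor` must be >= 1.")
  resampler <- switch(method, fourier = resample_fourier, spline = resample_spline)
  if (!is.null(hp_cutoff_hz) && hp_cutoff_hz > 0) {
    bf <- signal::butter(1, hp_cutoff_hz / (rate / 2), type = "high")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  }
  # a low-cutoff filter cannot settle within a short snippet, so the DC
  # component is removed explicitly per channel
  x <- x - rowMeans(x)
  if (supersample_factor > 1) {
    x <- t(apply(x, 1, resampler, factor = supersample_factor))
  }
  x
}

#' @rdname preprocess
#' @export
preprocess.snippet_group <- function(x, hp_cutoff_hz = 1, supersample_factor = 4,
                                     method = c("fourier", "spline"), ...) {
  method <- match.arg(method)
  x$snippets <- purrr::map(
    x$snippets, preprocess.matrix,
    hp_cutoff_hz = hp_cutoff_hz, supersample_factor = supersample_factor,
    rate = x$rate, method = method
  )
  x$factor <- x$factor * as.integer(supersample_factor)
  x
}

#' @rdname preprocess
#' @export
preprocess.snippet_groups <- function(x, ...) {
  out <- purrr::map(unclass(x), preprocess.snippet_group, ...)
  structure(out, class = "snippet_groups")
}

#' Decimate a supersampled snippet group back to base rate
#'
#' Keeps every `group$factor`-th sample, returning traces on the original
#' recording timebase (the spike-matching stage operates at base rate).
#'
#' @param group A `snippet_group`.
#' @return The group with `factor = 1` and base-rate traces.
#' @export
decimate_group <- function(group) {
  stopifnot(inherits(group, "snippet_group"))
  f <- group$factor
  if (f == 1) return(group)
  group$snippets <- purrr::map(group$snippets, function(m) {
    m[, seq(1, ncol(m), by = f), drop = FALSE]
  })
  group$factor <- 1L
  group
}
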