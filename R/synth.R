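#' Configuration for the synthetic session generator
#'
#' Defines a fully ground-truthed recording session with the statistical
#' structure the cleaning pipeline assumes: Gaussian background noise,
#' biphasic extracellular spikes of 100-200 uV spread over neighbouring
#' channels, optogenetic rate suppression with millisecond latency, and
#' photovoltaic artifacts whose amplitude grows linearly with light intensity
#' up to ~1000 uV and saturates at ~6000 uV, with sharp onset/offset
#' transients (strongest derivative ~260 us after onset, lasting ~300 us).
#'
#' @param channels Number of channels (split evenly over `shanks`).
#' @param rate Sampling rate, samples/s.
#' @param n_pulses Number of light pulses (order of 500).
#' @param pulse_ms Commanded pulse duration, ms (10 ms light pulses).
#' @param slope_ms Linear rise/fall of the light step, ms (0.1).
#' @param gap_ms Inter-pulse gap, ms.
#' @param fibers,shanks Number of stimulation fibers / probe shanks.
#' @param noise_sd_uV Background noise SD, uV.
#' @param n_units Number of synthetic units.
#' @param trough_uV Range of spike trough amplitudes, uV.
#' @param spread_decay Per-channel geometric decay of the spike across the
#'   probe (spread over 3 channels).
#' @param unit_rate_hz Range of baseline firing rates, Hz.
#' @param suppression Rate multiplier during optogenetic inhibition.
#' @param inhibition_latency_ms Delay from light onset to suppression.
#' @param post_suppression_ms Suppression outlasting the pulse, ms.
#' @param pvr_slope_uV Initial artifact amplitude slope, uV per photodiode
#'   intensity unit.
#' @param linear_limit_uV,saturation_uV Linear range limit (~1000) and
#'   saturation asymptote (~6000) of the artifact amplitude.
#' @param transient_peak_us Time of the strongest artifact derivative after
#'   onset, us (260).
#' @param transient_fwhm_us Width (full width at half maximum) of the
#'   derivative transient, us (300).
#' @param plateau_tau_ms Slow decay constant of the artifact plateau, ms.
#' @param polarity Artifact polarity (+1: positive-going, the default).
#' @param intensity_levels Photodiode intensity grid pulses are drawn from
#'   (five light-power conditions by default).
#' @param seed RNG seed; identical seeds give identical sessions.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(channels = 16, rate = 30000, n_pulses = 500,
                         pulse_ms = 10, slope_ms = 0.1, gap_ms = 80,
                         fibers = 4, shanks = 2, noise_sd_uV = 10,
                         n_units = 8, trough_uV = c(100, 200),
                         spread_decay = 0.5, unit_rate_hz = c(4, 12),
                         suppression = 0.2, inhibition_latency_ms = 1,
                         post_suppression_ms = 5, pvr_slope_uV = 50,
                         linear_limit_uV = 1000, saturation_uV = 6000,
                         transient_peak_us = 260, transient_fwhm_us = 300,
                         plateau_tau_ms = 20, polarity = 1,
                         intensity_levels = c(5, 10, 20, 60, 120),
                         seed = 42L) {
  cfg <- as.list(environment())
  cfg$channels <- as.integer(channels)
  cfg$n_pulses <- as.integer(n_pulses)
  cfg$fibers <- as.integer(fibers)
  cfg$shanks <- as.integer(shanks)
  cfg$n_units <- as.integer(n_units)
  cfg$seed <- as.integer(seed)
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$channels >= cfg$shanks, "channels must be >= shanks")
  chk(cfg$rate > 0, "rate must be > 0")
  chk(cfg$n_pulses >= 0, "n_pulses must be >= 0")
  chk(cfg$pulse_ms > 0, "pulse_ms must be > 0")
  chk(cfg$noise_sd_uV >= 0, "noise_sd_uV must be >= 0")
  chk(cfg$suppression >= 0 && cfg$suppression <= 1, "suppression must be in [0, 1]")
  chk(cfg$linear_limit_uV < cfg$saturation_uV, "linear_limit_uV must be < saturation_uV")
  chk(cfg$pvr_slope_uV >= 0, "pvr_slope_uV must be >= 0")
  chk(all(cfg$intensity_levels >= 0), "intensity_levels must be >= 0")
  if (length(problems)) {
    abort(paste0("invalid synth_config: ", paste(problems, collapse = "; ")))
  }
  structure(cfg, class = "synth_config")
}

#' Artifact amplitude as a function of light intensity
#'
#' Exponential-approach saturation law
#' `amplitude = saturation * (1 - exp(-slope * intensity / saturation))`:
#' linear with slope `pvr_slope_uV` at low intensity and asymptoting at the
#' saturation amplitude (6000 uV) at high intensity, matching the observed
#' linear-then-saturating intensity relation.
#'
#' @param intensity Non-negative photodiode intensity value(s).
#' @param cfg A [synth_config()].
#' @return Amplitude(s) in uV.
#' @export
pvr_amplitude <- function(intensity, cfg = synth_config()) {
  if (any(intensity < 0)) abort("intensity must be >= 0.")
  cfg$saturation_uV * (1 - exp(-cfg$pvr_slope_uV * intensity / cfg$saturation_uV))
}

#' Unit-amplitude photovoltaic artifact time course for one pulse
#'
#' Sharp onset transient whose absolute temporal derivative peaks
#' `transient_peak_us` after light onset and stays above half that peak for
#' about `transient_fwhm_us`, followed by a slowly decaying plateau and a
#' mirrored offset transient. The peak amplitude is normalized to 1.
#'
#' @param pulse_duration_s Light pulse duration, seconds.
#' @param cfg A [synth_config()].
#' @param rate Sampling rate; defaults to `cfg$rate`.
#' @return Numeric vector starting at light onset (sample 0) and extending
#'   past the offset transient; zero-based support, peak 1.
#' @export
pvr_waveform <- function(pulse_duration_s, cfg = synth_config(), rate = NULL) {
  rate <- rate %||% cfg$rate
  dur_us <- pulse_duration_s * 1e6
  sigma <- cfg$transient_fwhm_us / (2 * sqrt(2 * log(2)))
  extent_us <- cfg$transient_peak_us + cfg$transient_fwhm_us
  if (dur_us <= 2 * extent_us) {
    abort("pulse too short for the onset/offset artifact transients.")
  }
  dt_us <- 1e6 / rate
  tail_us <- cfg$transient_peak_us + 4 * sigma
  t_us <- seq(0, dur_us + tail_us, by = dt_us)
  p0 <- stats::pnorm(0, cfg$transient_peak_us, sigma)
  rise <- (stats::pnorm(t_us, cfg$transient_peak_us, sigma) - p0) / (1 - p0)
  fall <- 1 - stats::pnorm(t_us, dur_us + cfg$transient_peak_us, sigma)
  plateau <- exp(-pmax(0, t_us - extent_us) / (cfg$plateau_tau_ms * 1000))
  w <- rise * plateau * fall
  cfg$polarity * w / max(abs(w))
}

#' Generate a fully ground-truthed synthetic session
#'
#' Builds a recording block additively as noise + spikes + artifact (the
#' decomposition is returned exactly), together with the per-fiber light log
#' and ground truth: true spike times per unit, per-pulse intensities, and
#' the artifact-only trace. Identical seeds give identical sessions.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_session`: `block` ([recording_block()]),
#'   `light` ([light_log()]), `truth` (list with `spikes` tibble
#'   (`unit_id`, `time_sample`), `pulses` tibble (`fiber_id`,
#'   `onset_sample`, `offset_sample`, `intensity`), `units` (waveforms),
#'   `artifact`, `spike_trace`, `noise` matrices), and `cfg`.
#' @export
generate_session <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  rate <- cfg$rate
  ms <- function(x) round(x / 1000 * rate)
  nch <- cfg$channels
  per_shank <- nch %/% cfg$shanks
  shank_id <- rep(seq_len(cfg$shanks), each = per_shank)[1:nch]
  positions <- unlist(lapply(seq_len(cfg$shanks), function(s) {
    50 * seq_len(sum(shank_id == s))
  }))

  margin <- ms(100)
  period <- ms(cfg$pulse_ms + cfg$gap_ms)
  n_samp <- 2 * margin + cfg$n_pulses * period
  slope_smp <- max(1L, ms(cfg$slope_ms))
  pulse_smp <- ms(cfg$pulse_ms)

  with_private_seed(cfg$seed, {
    # --- pulse schedule -----------------------------------------------------
    fibers <- rep_len(seq_len(cfg$fibers), cfg$n_pulses)
    intens <- sample(cfg$intensity_levels, cfg$n_pulses, replace = TRUE)
    onset_cmd <- margin + (seq_len(cfg$n_pulses) - 1L) * period   # 0-based rise start
    pulses <- tibble::tibble(
      fiber_id = fibers,
      onset_sample = onset_cmd,            # start of the light rise
      offset_sample = onset_cmd + pulse_smp,
      intensity = intens
    )

    # --- light log ----------------------------------------------------------
    light_mat <- matrix(0, cfg$fibers, n_samp)
    ramp_up <- seq_len(slope_smp) / slope_smp
    for (i in seq_len(cfg$n_pulses)) {
      a <- pulses$onset_sample[i]
      shape <- c(ramp_up, rep(1, pulse_smp - slope_smp), rev(ramp_up))
      idx <- (a + 1):(a + length(shape))
      light_mat[pulses$fiber_id[i], idx] <-
        pmax(light_mat[pulses$fiber_id[i], idx], intens[i] * shape)
    }

    # --- artifact -----------------------------------------------------------
    artifact <- matrix(0, nch, n_samp)
    if (cfg$pvr_slope_uV > 0) {
      wave <- pvr_waveform(cfg$pulse_ms / 1000, cfg, rate)
      lw <- length(wave)
      # depth-dependent artifact gain per fiber: each fiber illuminates a
      # preferred depth most strongly
      fiber_depth <- seq(min(positions), max(positions), length.out = cfg$fibers)
      gain <- vapply(seq_len(cfg$fibers), function(f) {
        0.3 + 0.7 * exp(-abs(positions - fiber_depth[f]) / 500)
      }, numeric(nch))
      for (i in seq_len(cfg$n_pulses)) {
        amp <- pvr_amplitude(intens[i], cfg)
        idx <- (pulses$onset_sample[i] + 1):(pulses$onset_sample[i] + lw)
        artifact[, idx] <- artifact[, idx] +
          outer(gain[, pulses$fiber_id[i]] * amp, wave)
      }
    }

    # --- units and spikes ---------------------------------------------------
    wpre <- 20L; wpost <- 40L; wlen <- wpre + wpost + 1L
    t_rel <- seq(-wpre, wpost)
    unit_list <- list()
    spike_trace <- matrix(0, nch, n_samp)
    spike_rows <- list()
    supp_windows <- cbind(
      pulses$onset_sample + ms(cfg$inhibition_latency_ms),
      pulses$offset_sample + ms(cfg$post_suppression_ms)
    )
    for (u in seq_len(cfg$n_units)) {
      trough <- runif(1, cfg$trough_uV[1], cfg$trough_uV[2])
      prim <- sample(nch, 1)
      # per-unit waveform shape: trough width, afterpotential lag/size and
      # channel spread all vary across units, as across real neurons
      sig1 <- runif(1, 1.8, 3.2)
      lag <- runif(1, 6, 10)
      pos_frac <- runif(1, 0.2, 0.3)
      decay <- cfg$spread_decay * runif(1, 0.8, 1.2)
      shape <- -exp(-(t_rel + 2)^2 / (2 * sig1^2)) +
        pos_frac * exp(-(t_rel - lag)^2 / (2 * 6^2))
      shape <- shape / max(abs(shape)) * trough
      wf <- matrix(0, nch, wlen)
      for (dch in -1:1) {
        c2 <- prim + dch
        if (c2 >= 1 && c2 <= nch && shank_id[c2] == shank_id[prim]) {
          wf[c2, ] <- shape * decay^abs(dch)
        }
      }
      base_hz <- runif(1, cfg$unit_rate_hz[1], cfg$unit_rate_hz[2])
      n_exp <- stats::rpois(1, base_hz * n_samp / rate)
      st <- sort(sample.int(n_samp - wlen - 1L, min(n_exp, n_samp - wlen - 1L)))
      if (length(st) > 1) st <- st[c(TRUE, diff(st) > ms(2))]   # 2 ms refractory
      # optogenetic suppression: thin spikes inside suppression windows
      if (cfg$suppression < 1 && nrow(supp_windows) > 0) {
        wi <- findInterval(st, supp_windows[, 1])
        inside <- wi >= 1 & st < supp_windows[pmax(wi, 1), 2]
        drop <- inside & runif(length(st)) > cfg$suppression
        st <- st[!drop]
      }
      st <- st[st - wpre >= 0 & st + wpost < n_samp]
      for (t in st) {
        idx <- (t - wpre + 1):(t + wpost + 1)
        spike_trace[, idx] <- spike_trace[, idx] + wf
      }
      unit_list[[u]] <- list(unit_id = u, waveform = wf, primary_channel = prim,
                             trough_uV = trough, base_rate_hz = base_hz)
      spike_rows[[u]] <- tibble::tibble(unit_id = u, time_sample = st)
    }

    noise <- matrix(rnorm(nch * n_samp, sd = cfg$noise_sd_uV), nch, n_samp)
  })

  block <- recording_block(noise + spike_trace + artifact, rate = rate,
                           channel_positions = positions, shank_id = shank_id)
  structure(list(
    block = block,
    light = light_log(light_mat, rate = rate, fiber_ids = seq_len(cfg$fibers)),
    truth = list(
      spikes = if (length(spike_rows)) dplyr::bind_rows(spike_rows)
               else tibble::tibble(unit_id = integer(), time_sample = integer()),
      pulses = pulses,
      units = unit_list,
      artifact = artifact, spike_trace = spike_trace, noise = noise
    ),
    cfg = cfg
  ), class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %d ch x %.1f s, %d pulses, %d units, seed %d\n",
              x$cfg$channels, ncol(x$block$samples) / x$cfg$rate,
              x$cfg$n_pulses, x$cfg$n_units, x$cfg$seed))
  invisible(x)
}

#' Ground-truth mask of artifact-dominated samples
#'
#' Samples where the true artifact magnitude exceeds a threshold (default:
#' the background-noise SD), per channel, as 0-based half-open intervals in
#' block coordinates.
#'
#' @param session A `synth_session`.
#' @param threshold_uV Threshold on `|artifact|` (default `noise_sd_uV`).
#' @return Tibble `channel`, `start_sample`, `end_sample`.
#' @export
artifact_dominated_mask <- function(session, threshold_uV = NULL) {
  threshold_uV <- threshold_uV %||% session$cfg$noise_sd_uV
  A <- abs(session$truth$artifact) > threshold_uV
  purrr::map_dfr(seq_len(nrow(A)), function(c) {
    r <- rle(A[c, ])
    e <- cumsum(r$lengths); s <- e - r$lengths
    tibble::tibble(channel = c, start_sample = s[r$values], end_sample = e[r$values])
  })
}

#' Preset synthetic scenarios
#'
#' One-command scenarios used throughout the test-suite: `"default"` (the
#' standard conditions), `"artifact-free"` (zero artifact slope) and
#' `"heavy-artifact"` (doubled slope, top-heavy intensities).
#'
#' @param name Scenario name.
#' @param seed RNG seed.
#' @param ... Overrides passed to [synth_config()] (e.g. smaller `n_pulses`
#'   for quick runs).
#' @return A `synth_session`.
#' @export
synth_scenario <- function(name = c("default", "artifact-free", "heavy-artifact"),
                           seed = 42L, ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    "default" = list(),
    "artifact-free" = list(pvr_slope_uV = 0),
    "heavy-artifact" = list(pvr_slope_uV = 100,
                            intensity_levels = c(20, 60, 120, 240, 480))
  )
  cfg <- do.call(synth_config, utils::modifyList(c(base, list(seed = seed)), over))
  generate_session(cfg)
}
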