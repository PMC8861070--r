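---
title: "Managing photovoltaic light artifacts in optogenetic extracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing photovoltaic light artifacts in optogenetic extracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When light pulses for optogenetic stimulation are delivered next to the
recording sites of a silicon probe, the light itself induces a voltage on the
electrodes (a photovoltaic, Becquerel-type response, "PVR"). Because the
stimulus is aligned with the recording, the artifact is time-locked to light
onset and offset, can reach thousands of microvolts (dwarfing 100-200 uV
action potentials), grows linearly with light intensity up to roughly
1000 uV and saturates around 6000 uV. Simple blanking discards exactly the
epochs one cares about — the neuronal response to the light.

`pvrclean` implements a management strategy with three tiers:

1. **Subtract** what can be predicted: a per-pulse artifact template built
   from similar pulses.
2. **Black out** what cannot: samples where a residual artifact survives are
   marked invalid, in run-length intervals, and expanded so that no spike
   window can straddle them.
3. **Recover** spikes inside the cleaned stimulation windows by matching
   against unit templates sorted from the artifact-free inter-pulse data,
   flagging any event whose window touches a blackout as invalid, and
   averaging peri-stimulus histograms per time bin over only the trials that
   are clean there.

The package also covers the surrounding quantifications for side-emitting
fiber optics — Lambertian emission fits, cylindrical power densities,
connector-grid addressability, PVR-matched intensity ratios between fiber
configurations — and the statistics used to characterize optogenetic
inhibition (bootstrap latency estimation and a pre-inhibition split
analysis).

## The procedure in detail

**Pulse events.** Light is logged per fiber by a photodiode integrated in the
patch cord. Onset and offset of each pulse are the first and last crossings
of half of *that pulse's own* plateau peak, so trials of different commanded
intensity are treated consistently. Indices are 0-based and intervals
half-open throughout. Data snippets are cut from 30 ms before onset to 30 ms
after offset (a 10 ms pulse gives a 70 ms snippet) and grouped by
(fiber, shank) — four fibers on a two-shank probe give eight groups, each
cleaned independently, because the artifact depends on both the light source
and the recording shank.

**Preprocessing.** Snippets are high-pass filtered (first-order Butterworth,
1 Hz, forward-backward for zero phase — the acquisition filter reused; the
cutoff is a config field) and supersampled by a factor of 4 with band-limited
(Fourier) resampling; spline resampling is available as an option.
Supersampling refines the temporal alignment of the sharp artifact
transients. Spike matching afterwards operates at base rate, on the
decimated cleaned traces, so that spike-window bookkeeping stays in the
units of the -20/+40 sample spike window.

**Per-pulse templates.** For each pulse, the template is the per-channel
mean of the `k = 20` snippets in its group with the smallest mean squared
error to the pulse of interest (onset-aligned, all channels). The candidate
set includes the pulse itself — only then does a spike that occurs in
exactly one of the averaged snippets enter the template at weight `1/k` and
get attenuated by the documented ~5% at `k = 20`. Because pulse durations
vary, onset-aligned and offset-aligned templates are computed separately and
joined across an overlap of 100 base-rate samples (3.3 ms at 30 kHz,
centred on the pulse midpoint) with linear weights summing to one at every
sample, so no discontinuity is introduced.

**Residual detection.** Residual artifacts concentrate where the artifact's
temporal derivative is strongest (~260 us after onset, lasting ~300 us).
The cleaned traces are differentiated in time and rectified; trials are
ordered by pulse intensity and a centred window of 7 intensity-adjacent
trials is averaged per time point *after dropping the single largest value*,
which protects genuine spikes (present in one trial) from triggering the
detector while artifacts (shared by intensity-neighbours) accumulate. The
window shrinks at the extremes of the intensity ordering, never below 3
trials. A sample is flagged when the statistic exceeds its own
pre-stimulation mean by 4 pre-stimulation SDs (the statistic is a rectified
mean with a positive baseline, so the criterion must be referenced to that
baseline; the SD is pooled per channel across trials over the 30 ms
pre-onset span). Flagged intervals are then expanded 40 samples back and 20
forward, clipped and merged — labelling every period in which no -20/+40
spike window could be fully clean.

**Sorting and recovery.** Units are sorted from the concatenated inter-pulse
segments only (the pipeline treats sorting as pluggable; external sorter
output enters through `as_unit_templates()`). The built-in sorter detects
-30 uV threshold crossings, clusters waveforms with a budget of twice the
number of channels, and curates units with unphysiological properties:
troughs beyond 400 uV, templates shallower than the noise scrape level,
clusters with too few members, and templates whose positive deflection
exceeds 20 uV on three or more pairwise non-adjacent channels at one sample
(a light artifact spans the probe; a spike's footprint is contiguous).
Inside cleaned windows, a greedy loop normalizes each channel to unit SD,
picks the most negative unmasked sample, compares the three probe-adjacent
channels centred on it over the -20/+40 window against each unit's
correspondingly normalized waveform, and accepts the best unit when the
mean squared error (over 3 x 61 samples, in SD units) is below one. The
loop stops when no unconsumed event exceeds 4 SDs. Events whose window
intersects the expanded blackout are emitted with `valid = FALSE`.

**Weighted PSTH.** Per time bin, the firing rate is averaged over only the
trials whose bin is fully unmasked, and the percentage of masked trials is
reported alongside; a bin masked in all trials is undefined rather than
silently zero.

## The synthetic-session generator

Every stage is testable hermetically against `generate_session()`, which
builds a recording block *additively* — noise + spikes + artifact, with the
decomposition returned exactly — plus the per-fiber photodiode log and full
ground truth. The generator emulates the study conditions: 30 kHz sampling,
on the order of 500 pulses of 10 ms with a 0.1 ms linear light slope, four
fibers and two shanks, Gaussian background noise (10 uV SD), biphasic
spikes of 100-200 uV spread over three channels with per-unit shape
variation (trough width, afterpotential lag and size, channel-spread decay —
real neurons differ in shape, and a generator in which co-located units are
exact scalings of each other would make template merging degenerate),
optogenetic rate suppression with 1 ms latency, and artifacts with a sharp
onset transient (derivative peak 260 us after onset, 300 us full width at
half maximum), a slowly decaying plateau and a mirrored offset transient.
The amplitude-versus-intensity law is an exponential approach to the
6000 uV asymptote matching the stated linear slope at low intensity; a
piecewise alternative was considered and rejected as it introduces a kink
with no physical motivation. Pulse intensities are drawn from a five-level
grid echoing the five light-power conditions of the dose-response
experiment. Artifact polarity is positive-going by default and
configurable.

What the generator does *not* emulate: electrode drift, multi-unit
background hash, non-stationary firing rates, artifact shape variability
across trials of equal intensity, and overlapping-spike resolution. Passing
tests on synthetic data therefore demonstrate the mechanics of the
procedure, not its performance on any particular real recording.

## Numerical and design choices

* Half-open 0-based sample intervals everywhere; masks are run-length
  interval tables (snippet, channel, start, end), not NaN sentinels, which
  makes coverage, merging and serialization exact.
* The 40/20-sample blackout expansion is applied at base rate, matching the
  spike-window units; residual detection runs in the supersampled domain and
  flagged indices are floored to base rate first.
* The matcher searches trough alignments up to +/-2 samples (noise jitters
  the apparent trough), requires the candidate unit to actually have an
  event-scale trough on the compared channels, and requires the template
  trough to be within 4 SDs of the picked amplitude — without these, windows
  of bare noise can "match" the flat part of a distant unit's template at
  the noise floor.
* Degenerate inputs error early with named fields (configuration
  validation), an all-zero light trace detects zero pulses rather than
  erroring, and a pulse whose snippet would leave the recording is dropped
  with a warning.
* Problem sizes in the test-suite: most unit tests run on sessions of 60
  pulses and 8 channels; the end-to-end checks run the full standard
  scenario (500 pulses, 16 channels, 8 units) once and share it across
  assertions. These sizes were chosen to exercise each mechanism at the
  scale it needs — notably, nearest-neighbour templates need enough
  same-intensity trials per group to fill `k = 20`.

## Known limitations

* The acceptance rule for recovered spikes (mean squared error below one, in
  SD units) sits exactly at the noise floor of a perfect match whenever the
  trial's overall SD is close to the background-noise SD, as it is in clean
  synthetic data; borderline events are then rejected at an appreciable
  rate. In real recordings the trial SD is inflated by residual artifact
  and unsorted background activity, which makes the same criterion more
  permissive. The threshold is a config field (`match_config(max_error =)`),
  with the documented value as default.
* Temporally overlapping spikes on neighbouring channels are not resolved;
  the greedy matcher consumes the joint trough and at most one of the two
  events survives.
* The residual detector is derivative-based and blind to slowly varying
  residuals (a DC-shifted plateau from an intensity-mismatched template
  passes undetected); such trials surface instead as inflated trial SD.
* Latency estimation reports the first bin at-or-below the level on the
  pooled bootstrap histogram; with wide bins the crossing rule, not the
  data, limits resolution.
* Rate-tercile boundaries in the pre-inhibition split are data-driven
  terciles by default; fixed boundaries can be supplied.
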