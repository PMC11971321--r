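---
title: "Analyzing interval learning, replay and connectivity in whole-cell recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing interval learning, replay and connectivity in whole-cell recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replaytrace)
```

## The experimental setting

`replaytrace` analyzes whole-cell current-clamp recordings from ex vivo
cortical circuits trained with a dual-optogenetic delay-conditioning-style
protocol. Two sparse pyramidal-neuron subpopulations express a red-shifted
(ChrimsonR) and a blue (ChR2) opsin. Training pairs a 440 ms red pulse train
(the conditioned stimulus, CS) with an 80 ms blue train (the unconditioned
stimulus, US) at one of two onset intervals — 10 ms ("Early") or 370 ms
("Late") — every 20 s for 24 h. After training, recordings at 10 kHz probe:

* **evoked dynamics** — the network response to red light alone in a 1 s
  window after stimulus onset;
* **spontaneous replay** — Up-state-like bouts of network activity whose
  temporal profile mirrors the trained dynamics;
* **ensemble order** — cross-correlation lags between simultaneously
  recorded Chrim+ and ChR2+ neurons during spontaneous events;
* **timed prediction errors** — neurons responding more to red alone than to
  red+blue, i.e. an internally generated late response suppressed by the
  delivered blue light;
* **connectivity** — monosynaptic EPSP-based connection calls between
  neighboring neurons, probed in both directions.

Every stage consumes an `ephys_dataset` container and returns tibbles, so
results chain directly into dplyr/ggplot2 workflows.

## The analysis procedures and their parameters

All constants live in `analysis_params()`; the defaults are the values the
procedures are defined with, in the units given there.

**Event detection.** Spontaneous network events are voltage threshold
crossings: samples more than 5 mV above the resting potential. Because the
membrane potential repeatedly dips below threshold during an event, runs of
suprathreshold samples separated by dips shorter than 25 ms are merged, and
merged runs of at least 100 ms (dips included) become events. Each event
owns a 100 ms pre-onset baseline and a 1 s analysis window; events whose
baseline would precede the sweep start or overlap the previous event are
dropped. The resting potential of a spontaneous record is the mode of a
0.5 mV-bin histogram of the whole trace (events are rare, so the mode sits
at rest); for evoked sweeps it is the median of the 1 s pre-stimulus
baseline. Detection operates on median-filtered voltage — the original
procedure does not state whether spikes were removed before thresholding;
filtering first is the conservative choice and is recorded here.

**Preprocessing.** "Spike filtering" is a 5 ms sliding median for the
evoked path (the source never defines its filter; a 5 ms median removes
1–3 ms action potentials and leaves 100 ms-scale envelopes intact),
block-mean down-sampling by 10 for spontaneous windows, and a median filter
followed by block-mean down-sampling by 50 for the paired path. Smoothing is
a centered 10 ms moving average (a centered window introduces no phase shift
in peak-time estimates); the median filter runs before the moving average.
Down-sampling uses block means, not decimation, so it is also an
anti-aliasing spike filter.

**Temporal features.** Per analysis-window trace: the *peak time* (global
maximum, earliest tie), *slope event times* (onsets of runs where the 10 ms
finite-difference slope exceeds three within-trace slope SDs — a
zero-variance trace has no events rather than all events; per-sweep SD keeps
the threshold adaptive to each trace's noise, with pooling across sweeps
left as an option), and the *center of gravity* (the time at which the
cumulative trapezoidal integral of the rectified, baseline-subtracted trace
reaches half its total; rectification is the default because a signed
"area" can cancel, and the signed variant is available via
`center_of_gravity(rectify = FALSE)`). Per neuron, peak times aggregate by
median, slope events by the median of the pooled event list, centers of
gravity by mean; group level uses means of these per-neuron values.
Peak-time CDFs pool the first five traces per neuron.

**Replay correlation.** For the evoked-versus-spontaneous comparison only,
evoked windows are aligned at their first 5 mV crossing (the same criterion
that anchors spontaneous event onsets, so both contexts are locked to the
same phase of the network event) and down-sampled to the spontaneous rate.
Pearson correlations between mean evoked and mean spontaneous traces fill
the intra-condition matrices (self-pairs excluded) and inter-condition
matrices; unequal lengths are truncated to the common prefix. The intra vs
inter comparison uses the two-sided rank-sum test.

**Paired dynamics.** Events detected on either neuron of a pair are
unioned (overlaps merged, earliest onset and latest offset kept); each
1100 ms segment includes 100 ms of baseline. Pairwise similarity is the
mean squared Pearson correlation per segment. Cross-correlation uses
segments trimmed to 50 ms inside the detected onset/offset, lags up to
±500 ms (the source states no range; ±500 ms comfortably covers the 370 ms
trained interval), per-segment normalized correlation averaged across
segments, and a peak-lag tie broken toward zero. Only lags covered by every
segment enter the peak search — short segments would otherwise contribute
spuriously high correlations from tiny overlaps. Positive lag means the
ChR2-labeled neuron follows the Chrim-labeled one.

**Prediction error.** Per neuron, the signed CS − CSUS difference of mean
evoked windows is integrated over the 1 s window (trapezoid, mV·ms). A
neuron is flagged when its statistic strictly exceeds the group mean plus
three SEM ("exceeded" is read strictly; an epsilon keeps exact boundary
ties deterministic under floating point). The signed (unrectified)
difference is deliberate: neurons responding more to red+blue pull the
threshold down, matching the one-sided rule. The population over which mean
and SEM are computed is the group passed in — by default all classifiable
Late opsin-negative neurons — because the source is ambiguous about wider
pooling.

**Connectivity.** Presynaptic action potentials are 0 mV upward crossings;
only the first AP of each trial is scored. The EPSP amplitude is the peak
voltage in a 1.5–15 ms post-AP search window minus the mean of a
−50 to −2 ms baseline window (neither window is stated in the source; these
defaults bracket monosynaptic latencies at 32–33 °C and are configurable).
A connection exists when the mean amplitude is at least three times the
across-trial SD of the baseline means — that SD is the noise floor of the
averaged EPSP; the within-trial sample SD is the configurable alternative.
Calls from fewer than five trials are flagged low-confidence.

**Group statistics.** Mann–Whitney U (midranks for ties; exact p-values
when both samples are below n = 20 with no ties, otherwise the normal
approximation with continuity correction, with the method recorded) and the
two-sample Kolmogorov–Smirnov statistic, delegated to the standard
`stats` implementations.

## What the synthetic generator emulates

`simulate_dataset(generator_config())` builds a world with the statistical
structure the analysis assumes. Voltage is a −65 mV resting potential plus
exponentially correlated noise (SD 0.4 mV, correlation time 20 ms — white
noise would understate false-event rates), stylized triangular spikes on
depolarized segments, and deterministic network envelopes built from
difference-of-exponential components (rise 30 ms, decay 150 ms, peak
12 mV). Early-trained activity peaks 120 ms after onset, Late-trained
480 ms — the 370 ms trained interval plus the ~110 ms latency of the early
response — and Untrained activity peaks at an intermediate 250 ms.
Spontaneous bouts replay the condition envelope at 0.1 Hz (Poisson with a
2 s refractory gap) for 5 simulated minutes per neuron; bout amplitude and
rate are placeholders (the source reports no distributions for them) and
stay configurable.

Two structural choices deserve their reasoning spelled out:

* **The Late bridge bumps.** A Late bout must (a) be detected as *one*
  event anchored at its start — so the trace has to stay above the 5 mV
  threshold from bout onset to the late rise, up to dips shorter than
  25 ms — and (b) keep its center of gravity near the late peak so that the
  Late − Early gap recovers the injected 360 ms separation within the
  ±20% recovery band. A solid plateau satisfies (a) but adds so much area
  that it fails (b); closed-form integrals of the envelope show any bridge
  of more than ~1300 mV·ms drags the gap below the band. The generator
  therefore bridges the interval with brief 7.5 mV bumps (rise 2 ms, decay
  6 ms, every 25 ms): each crosses threshold for ~8 ms with ~20 ms
  sub-threshold gaps, so the merge rule chains them into one event, while
  their total area (~900 mV·ms) displaces the center of gravity by only
  ~55 ms. They double as the "polysynaptic events" the slope detector
  counts between onset and the late peak.
* **Separate probe noise.** Connectivity probe sweeps carry 0.15 mV noise
  rather than the 0.4 mV of the network records: probe baselines are taken
  in quiescent periods, and an Up-state-scale noise floor would make the
  3×SD rule reject realistic 0.4–0.8 mV EPSPs wholesale.

Prediction-error neurons are `round(pe_fraction × n)` of the Late
opsin-negative group, assigned to the lowest indices for reproducibility;
their red+blue sweeps have the late component multiplicatively suppressed
by 80%. Pairs share a bout schedule with the ChR2 trace delayed 30 ms in
the Late condition and 0 ms in Untrained. Forward probe EPSPs are 0.8 mV
and reverse 0.4 mV at equal 0.5 connection probability, mirroring the
reported pattern of asymmetric strength with similar probability.

What the generator does **not** emulate: conductance-based spiking, network
state transitions with variable bout shapes, slow drift of the resting
potential, electrode artifacts, or any plasticity mechanism. A green test
on this world therefore establishes that the pipeline recovers parameters
from data with the assumed structure — not that the biological claims hold,
and not that the pipeline is robust to pathologies the generator omits.

## Numerical choices and degenerate inputs

Time is milliseconds throughout, windows are half-open `[start, end)`, and
sample *i* of a sweep sits at `t0 + (i−1)·1000/rate` ms. Equal seeds give
byte-identical datasets; the analysis itself consumes no randomness.
Degenerate inputs resolve conservatively: a constant trace has peak time 0
(earliest tie) and no slope events; an all-zero rectified trace has no
center of gravity (`NA`); a sub-threshold evoked trace is excluded from
replay alignment only; zero-variance paired segments are dropped with the
count reported; neurons missing a context are omitted from that context's
tables. The stored 440 ms red-train duration disagrees by 5 ms with its own
pulse arithmetic (11 intervals at 25 Hz + one 5 ms pulse = 445 ms); the
container keeps the stated value and `validate_dataset()` warns rather than
fails.

## Known limitations

* The 3×SEM prediction-error rule is anticonservative under a pure null:
  with group size n the threshold sits only `3/√n` SDs above the mean, so
  ~28% of a Gaussian null group exceeds it at n = 28. On real (and
  simulated) data the rule works because genuine prediction-error
  responders inflate the SEM and push the threshold into the gap between
  the two modes. The package implements the rule as defined and documents
  this property instead of papering over it.
* Cross-correlation lags are resolved on the 5 ms grid of the
  down-sampled (factor 50) paired traces; sub-sample interpolation is out
  of scope.
* The container reads CSV + JSON sidecar directories only; vendor formats
  (ABF, Igor, NWB) must be converted upstream, and no HDF5 dialect is
  provided in this build.

## A worked run

```{r, eval = FALSE}
library(replaytrace)
library(dplyr)

d <- simulate_dataset(generator_config(seed = 1))
res <- run_pipeline(d)

res$feature_stats |>
  filter(context == "evoked") |>
  select(feature, mean_early, mean_late, U, p_u)

glance(res$replay)     # intra vs inter condition correlations
tidy(res$paired)       # per-pair r-squared and peak lag
glance(res$pe)         # prediction-error fraction

plot_mean_traces(d, "evoked")
autoplot(res$pe)
```

The README shows the numbers this run prints.
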