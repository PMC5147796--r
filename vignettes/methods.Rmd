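---
title: "Methods: avalanche statistics, correlation analysis and the dF/F pipeline"
author: "critstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: avalanche statistics, correlation analysis and the dF/F pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critstate)
```

This vignette documents the models and procedures implemented by
**critstate**, the parameters that matter, the numerical choices made where
a definition was genuinely open, and what the synthetic-data module does and
does not establish about real recordings.

## Event detection from continuous signals

LFP channels are band-pass filtered (default 1–50 Hz for avalanche work,
300–4000 Hz for multi-unit activity) with a 2nd-order Butterworth filter run
forward and backward (`signal::filtfilt`), i.e. an effective 4th-order
zero-phase response. Zero phase is a hard requirement: event timestamps are
taken from filtered extrema, and a causal filter would bias every downstream
latency and triggered average. The test suite checks that a symmetric test
pulse keeps its peak sample within one sample after filtering.

Negative/positive LFP deflections (nLFP/pLFP) are detected per channel
against `z × SD`. The SD can be estimated from a short baseline window
(2–3 s; appropriate for slice recordings with quiescent epochs) or from the
entire signal (awake recordings, where no quiescent baseline exists). Each
contiguous supra-threshold excursion yields **one** event at its signed
extremum. This is a deliberate merge rule: when an excursion contains two
local minima separated by a sub-threshold but still-negative trough, we
count one event at the deeper minimum, because the amplitude of the
excursion extremum is what the threshold definition refers to. Typical
thresholds are z = −2.5 (awake nLFP), −4.5 (slice nLFP), +2.5 to +3 (pLFP).

MUA spikes are negative threshold crossings (`k × SD`, k = −5, or
`k × RMS`, k = −6; identical for zero-mean signals) with a 1-ms dead-time
merge window. The dead time stands in for the hardware refractory handling
and offline sorting used in acquisition systems, which are out of scope
here; 1 ms is the shortest interval at which two threshold crossings can
plausibly be distinct units' spikes at these bandwidths.

Event-triggered averages exclude triggers whose window crosses a recording
edge, and carry a ±3 SD band computed from averages over uniformly
re-drawn trigger times (default 100 repetitions) — the null for
event-locked structure. Event-locked spectra use Hann-windowed
periodograms over ±500 ms snippets, averaged over events and channels and
normalised to unit area, so spectra from recordings with different overall
power are comparable in shape.

## Avalanche clustering and finite-support inference

Event rasters are binned at Δt (default 4 ms; the plausible range is
2–4 ms, of the order of the inter-electrode propagation time). Bins are
half-open `[kΔt, (k+1)Δt)`; an event exactly on an edge belongs to the
later bin, and an event exactly at the recording end is clamped into the
last bin. Clusters are maximal runs of consecutive non-empty bins — a
cluster ends only at a bin with **no** event on **any** channel ("separated
by at least one bin width", read literally). The discrete size *s* is the
event count in the cluster; the continuous size is the summed absolute
amplitude in µV.

Sizes are modelled on the finite support `1..N`, where *N* is the electrode
count: the avalanche power law is expected to hold up to the system size
and the cut-off there is what makes the exponent estimate robust. Discrete
sizes *can* exceed *N* (several events on one electrode within one
cluster); such sizes are retained in the `SizeDistribution` object for
plotting and cross-condition KS comparisons but are excluded from the
likelihood, which is only defined on `1..N`. `supportSizes()` performs that
truncation and reports how many sizes were above the cut-off.

The power-law model is `p_α(s) = s^α / Σ_{x=1..N} x^α`; the exponential
null is `p_λ(s) = e^{−λs} / Σ_{x=1..N} e^{−λx}`. Both are fitted by
bounded scalar maximisation of the analytic log-likelihood (`stats::optimize`,
tolerance 1e-8, search ranges α ∈ [−6, 0], λ ∈ [0, 10]); both likelihoods
are smooth and unimodal, so this matches a brute-force grid with step 1e-4
to within 2e-4 (asserted over 100 random datasets in the test suite).
Degenerate data (e.g. all sizes equal to 1) push the optimum onto a search
bound; the fit is then flagged `degenerate` and the bound value is
reported. Because `optimize` never returns an exact endpoint, boundary
optima are checked explicitly — this matters for the exponential fit,
where λ̂ = 0 (uniform) is a perfectly regular answer.

The LLR comparison reports `l(α̂|s) − l(λ̂|s)`. For significance we use the
Vuong-type normalisation, `LLR / (√n · sd(d_i))` with `d_i` the per-sample
log-likelihood differences, referred to a two-sided standard normal; the
default level is 0.05 and the raw p-value is always reported. Zero variance
of the `d_i` (both models fitting identically) yields "undecided" rather
than a sign flip on numerical noise. Continuous (µV) distributions are
compared only through the KS distance — there is no continuous MLE here,
mirroring how such distributions are used in practice.

## Correlation analysis

`ccFunction` implements the Pearson lagged correlation over the overlapping
range at each lag. Shuffle correction subtracts the mean CC of surrogate
pairs over 10 repetitions; the surrogate is an independent uniform
**circular shift** of each series. The choice of surrogate was open:
circular shifts preserve each channel's rate and autostructure exactly
while destroying the temporal relation between channels, which is the null
we want for rate-induced chance correlation. The shift offsets are
seed-controlled. Matrix summaries use τ = 0; pairs with fewer than 10
events per series are excluded from matrix averages (their CC estimate is
dominated by a handful of bins), as are zero-variance series. Default CC
bins: 4 ms for LFP-event rasters, 20 ms for MUA. ΔF/F trace correlations
are computed raw — no shuffle correction — since the slow indicator
dynamics are the signal there, not a nuisance rate.

Peak half-widths are full width at half of the zero-lag peak above
baseline, divided by two, with the baseline taken as the mean CC at
|τ| ≥ 0.8 × max-lag and linear interpolation between lag samples. A CC
function whose maximum is not at zero lag, or whose peak does not exceed
the baseline, has no defined half-width and is flagged rather than forced.

## Calcium pipeline

`ΔF/F = 100 (F_ROI − F_0)/F_0`, with the dark-background signal subtracted
from the raw ROI trace before normalisation. The running baseline F₀ is the
mean of the 50 % smallest values in a centred 30-s window (truncated at the
edges): transients are sparse and strictly positive, so the lower half of
the window's values tracks the noise floor and not the activity. For an
n-frame window the lower half is the ⌈n/2⌉ smallest values.

Transient detection summates successive positive frame-to-frame increases
of ΔF/F; the sum resets on **any** non-positive increment (the strictest
reading of "successive increases"; the rule is config-exposed). A peak is
emitted when the summated signal crosses the threshold during a rising
epoch — one peak per epoch, timed at the epoch maximum, with amplitude
equal to ΔF/F at that maximum (amplitudes are reported in ΔF/F units, not
as the summated value). The default threshold is 5 × a robust noise SD
estimated from the increments themselves (`mad(diff)/√2`, insensitive to
the sparse transients); at that setting the spurious-peak fraction on
event-free noise traces stays below 0.5 % of frames, the calibration target
for the detector. The denominator for "spurious fraction" is detection
opportunities = frames scanned, measured on traces that are event-free by
construction.

Spike-count → amplitude regression averages transient amplitudes per
spike-count level within each neuron, normalises each neuron by its 2-spike
mean (the anchor level; neurons without 2-spike events are excluded and
flagged), and pools the normalised means into one ordinary least-squares
regression on spike count. Episode rates come from running the same
transient detector on the summed (bulk) fluorescence signal.

Functional-connectivity stability splits the recording into consecutive
~120-s segments, computes the vector of pairwise CCs per segment, and
reports R² (squared Pearson correlation, identical to the OLS coefficient
of determination for a simple regression) between consecutive segment
vectors. Raw CCs are used, not Fisher-transformed ones — at the CC
magnitudes involved the transform is near-linear and the raw scale is what
the stability maps display. Zero-variance pairs are dropped from both
vectors of a comparison.

## Movement extraction

The movement signal is 1 minus the Pearson correlation of consecutive ROI
pixel vectors: 0 for a static scene, approaching 2 for contrast inversion.
Constant frames (undefined correlation) map to 0 with a flag. Events are
supra-threshold excursions at `mean + z × SD` (z = 2–3), one event per
excursion with onset at the first supra-threshold frame — the onset
definition was open and "first crossing" is the least processed choice.
Resting-period restriction is accepted as an external boolean mask applied
to both the SD estimate and detection; the package does not classify
behaviour.

## The synthetic-data module

The generators define the study conditions for every test:

* **Branching process** — `nUnits` electrodes; per bin, each unit activates
  spontaneously with probability `driveRate` (default 1e-3), and each
  active unit activates Poisson(`sigmaBranch`) uniformly chosen units
  (without replacement, truncated at `nUnits`) in the next bin. At the
  critical point `sigmaBranch = 1` cascade sizes follow the −1.5 power law
  up to the system-size cut-off. Unit activation is binary per bin, so
  simultaneous cascades can merge — as they do on a real array. Amplitudes
  are lognormal (meanlog log 30 µV, sdlog 0.35: physiological deflection
  scale, kept well above the −4.5 SD detection floor so end-to-end
  detection tests measure the detector, not amplitude censoring).
* **Calcium population** — population episodes arrive as a Poisson process
  (default 0.15 s⁻¹, the baseline striatal episode rate); each episode
  activates one of 4 overlapping assemblies; members spike with p = 0.8,
  non-members with p = 0.15, producing a heterogeneous pairwise-CC
  structure. Spike counts convert linearly to ΔF/F (5 % per spike) and
  decay with a single 500-ms exponential (OGB-like kinetics); slow
  sinusoidal drift (0.8 %, 60–150 s periods) and white noise (1 %) are
  added from a condition-specific RNG stream — separate recordings never
  share measurement noise, and a shared stream would leak an identical
  pairwise component into cross-condition comparisons. The `ptx_like`
  preset raises participation (0.95/0.6) and spike counts, lifting both
  amplitudes and CCs; `iem_like` permutes neuron identities of an
  otherwise baseline-like spike matrix, preserving the mean pairwise CC
  exactly (the CC multiset is relabelled, not changed) while decorrelating
  the per-pair structure.
* **LFP/movement synthesizers** — embed stereotyped deflections / burst
  excursions at known times into Gaussian noise, retaining ground truth in
  attributes.

One global seed is split into per-component streams (`withSeed` +
`subSeed`), so each generator is bit-reproducible in isolation.

What passing tests on these data do **not** show: the generators have no
1/f background, no electrode crosstalk or movement artifacts, no indicator
saturation or bleaching, no spatially structured propagation (wiring is
uniform), and drift is smooth rather than step-like. Results on real
recordings depend on those nuisances; the synthetic suite establishes
correctness of the statistics, not robustness to acquisition artifacts.

## Problem sizes and runtime choices

The package's own validation uses desk-scale simulations: 10⁵ draws for
exponent recovery (recovered to ±0.02), 5×10⁵ branching bins yielding
≥10⁴ clusters for the end-to-end pipeline (exponent within ±0.2 of −1.5,
LLR decisively in favour of the power law), 8 × 320-s noise traces for the
spurious-peak fraction, 10³ independent Poisson pairs for the
shuffle-correction null, and 20 paired seeds for the condition-contrast
comparisons. These sizes keep the full suite in the tens of seconds while
leaving Monte-Carlo error well inside each tolerance.

## Known limitations

* The branching simulator's collision truncation (binary activation per
  unit-bin) slightly flattens the size distribution near the cut-off, so
  pipeline-level exponent estimates sit a little above −1.5; that bias is
  part of the model, not of the fitter (which recovers sampler draws to
  ±0.02).
* The exponential MLE search is capped at λ = 10; distributions
  concentrated entirely on s = 1 are reported at the bound and flagged.
* `ccHalfWidth` assumes a zero-lag-centred peak; asymmetric or shifted
  peaks are flagged undefined rather than measured.
* The ΔF/F pipeline assumes given ROIs; segmentation, registration and
  neuropil correction are out of scope.
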