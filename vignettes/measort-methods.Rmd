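---
title: "Spike detection, sorting and evoked-response identification with measort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike detection, sorting and evoked-response identification with measort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(measort)
```

## The problem

Retinal prostheses evoke activity in retinal ganglion cells (RGCs) by
electrical stimulation, and calibrating a stimulator requires knowing, for
each pulse amplitude, which cells respond, how strongly, and how far from
the stimulating electrode the effect reaches.  The raw material is a
multi-electrode array (MEA) recording: ~120 extracellular electrodes at
100 µm pitch sampled at 10 kHz, with a charge-balanced biphasic voltage
pulse (cathodic amplitude A for width T, then A/2 for 2T) delivered from
one electrode, 20 repeats per amplitude, amplitudes stepped from 0.15 to
1.65 V in 0.15 V increments.

`measort` implements the full analysis chain for such recordings:

1. **Artifact blanking** — stimulation artifacts dwarf spikes and appear
   synchronously on every channel; affected samples are reset to zero.
2. **Spike detection** — a stationary wavelet transform (SWT) sharpens
   spikes against noise, the Teager energy operator (TEO) converts
   transients into an instantaneous-energy trace, Hamming smoothing
   suppresses single-sample noise, sub-bands are combined, and peaks above
   a threshold are spikes.  The threshold is chosen by sweeping a grid and
   minimizing the disagreement with a reference count.
3. **Spike sorting** — wavelet-packet features of each 2 ms waveform are
   clustered with K-means; the cluster count is chosen by maximizing the
   mean silhouette coefficient.
4. **Response identification** — a unit is responsive when its firing rate
   in the 300 ms after the pulse exceeds three times its rate in the
   100 ms before, in at least 10 of 20 trials.
5. **Characterization** — responsiveness percentage per electrode "layer"
   (distance ring) and a Boltzmann sigmoid fit of mean evoked spikes per
   pulse versus amplitude, from which a threshold voltage (0.5 spikes per
   pulse) and a saturation voltage are read.

Because raw recordings of this kind are rarely shareable, the package also
contains a ground-truthed synthetic recording generator
(`simulate_recording()`) that emulates the experiment's structure, so
every stage is testable end to end.

## Detection model

The SWT (`swt_decompose()`) is the undecimated à trous transform: at level
j the level-(j−1) approximation is circularly convolved with the level-1
low- and high-pass taps upsampled by 2^(j−1) (zeros inserted between
taps).  Both coefficient series keep the input length, so spike timing is
preserved, and the transform commutes exactly with circular shifts.  The
default wavelet is Haar; `db2` and `db4` are available.  Circular boundary
handling was chosen because it keeps the transform exactly
translation-invariant and length-preserving; on traces hundreds of
thousands of samples long the wrap-around affects a negligible border.

The TEO (`teo()`) is `psi(n) = x(n)^2 − x(n−1) x(n+1)`; it responds to the
product of amplitude and frequency, so brief large transients (spikes)
stand out from slower or smaller fluctuations.  Endpoints are set to 0.
Each sub-band's energy is smoothed with a unit-area Hamming window
(default 11 samples = 1.1 ms at 10 kHz, zero phase) and the sub-bands are
summed pointwise (a `max` rule is available).  Negative TEO values are
clipped to zero before peak picking, consistent with reading the trace as
an energy.

The default sub-bands are the level-1 and level-2 **approximation**
coefficients.  At a 10 kHz sampling rate these retain the 0–2.5 kHz band
where extracellular spike energy lives; the detail coefficients are
available behind `detection_config(subband = "detail")` for recordings
where low-frequency contamination dominates.

Peak picking (`detect_peaks()`) accepts local maxima above the threshold
greedily in descending energy order subject to a 1 ms refractory
separation.  Detected peaks are then re-aligned to the sample of maximum
absolute voltage within ±0.5 ms, and fixed-length waveforms (8 samples
before the peak, 12 after) are cut for sorting.

**Threshold optimization** (`optimize_threshold()`) mirrors the practice
of calibrating against manual marking: for each threshold on a grid, the
mean absolute difference between the detector's count and a per-trial
reference count is computed; the optimum minimizes this difference, with
ties broken toward the larger threshold (fewer false positives).  The
built-in reference is the manual rule "amplitude exceeds twice the
baseline bandwidth", with the baseline bandwidth taken as 6 robust noise
SDs (`robust_noise_sigma()`, the MAD estimator) — roughly the peak-to-peak
extent of the ±3σ noise band.  External reference counts (e.g. a
hand-marked trial or simulation ground truth) can be supplied instead.
The companion SNR (`compute_snr()`) is the squared ratio of the median
spike peak-to-peak amplitude to the peak-to-peak amplitude of the longest
spike-free stretch.

The pipeline builds its per-channel grid as 20 log-spaced energies from
the 95th percentile of the positive energy trace up to its maximum; this
covers the whole over- to under-detection range with enough resolution at
the noise/spike crossover.

## Sorting model

Each waveform is decomposed to depth 3 with a **stationary wavelet
packet** transform: both approximation and detail branches are split at
every level, giving 8 terminal sub-bands.  The undecimated variant is
used because waveforms are only 20 samples long — decimated depth-3 nodes
would hold 2–3 coefficients each — and because it inherits the SWT's shift
invariance, so a one-sample alignment error does not scramble features.
Per sub-band, two summaries are kept per spike: the standard deviation and
the first quartile (linear-interpolation quantile) of the coefficients,
giving 16 raw features, which are standardized column-wise (constant
columns dropped).

K-means (`kmeans_fit()`) is Lloyd's algorithm with squared-Euclidean
assignment and mean-centroid updates, run to an assignment fixed point,
best of 10 random restarts by inertia; an emptied cluster is re-seeded to
the point farthest from its centroid.  Cluster quality is the mean
silhouette coefficient (`mean_silhouette()`): per sample,
`s = (b − a) / max(a, b)` with `a` the mean intra-cluster and `b` the
smallest mean inter-cluster distance, and `s = 0` when `a = b`.

`select_k()` fits k = 2..5 and keeps the k with the largest mean
silhouette.  The silhouette is undefined for k = 1, so a single unit is
returned when the data give no support for splitting: fewer than 10
spikes, or a best mean silhouette below `sc_floor = 0.20`.  The floor was
chosen from the behaviour of the 16-dimensional standardized features: an
unstructured single cluster scores ≈ 0.1 under any forced split, while
two genuinely distinct templates score ≥ 0.3.  Both guards are
configurable.

## Response criterion

With the fixed windows (100 ms pre, 300 ms post), the rate reading of the
3× criterion reduces to the integer comparison `n_post > 9 n_pre`, which
is how it is evaluated — no floating-point boundary cases.  The wording
of such criteria is ambiguous between rates and counts, so a count mode
(`n_post > 3 n_pre`) is provided; the rate mode is the default.  All
inequalities are strict, and a unit is responsive with ≥ 10 passing trials
out of 20 (for other trial counts, at least half, rounded up).  When
several amplitudes are present the pipeline classifies per amplitude and
calls a unit responsive overall if it is responsive at any amplitude.

Blanked samples simply contribute no spikes.  With a 25 ms cathodic width
the deterministic blanking window `[0, 3T + 2 ms]` removes the first
~77 ms of the post-stimulus window; early evoked spikes falling there are
invisible to the criterion, which is a property of the experiment (the
artifact genuinely hides them), not of the implementation.

## Spatial and voltage characterization

Electrode **layers** are Chebyshev rings on the grid:
`k = max(|Δrow|, |Δcol|)`.  Ring 1 is exactly the 8 electrodes adjacent
to the stimulation site, at Euclidean distances 100–141.4 µm for a 100 µm
pitch, matching the experimental definition of the first layer distance
`d`; ring k spans `[k·d, k·d·√2]`.

The voltage–response curve is the mean spike count in `(0, 0.3]` s per
(responsive unit × trial), by amplitude.  Only responsive units enter the
average, matching the convention that the population curve describes the
cells that respond at all.  The fit family is the Boltzmann sigmoid
`y(V) = L + (U − L)/(1 + exp(−(V − V₀)/s))`, chosen because the empirical
curve is monotone and saturating; it is fitted by Levenberg–Marquardt
(`minpack.lm`), initialized from the data (`L = min`, `U = max`,
`V₀ = mid-range`, `s = range/10`).  The **threshold voltage** solves
`y(V) = 0.5` (an error if 0.5 lies outside the fitted plateaus, e.g. for a
flat curve), and the **saturation voltage** is the smallest tested
amplitude whose fitted value reaches 95% of the upper plateau.

## The synthetic generator, and what it does not emulate

`synth_config()` fixes the study conditions:

| parameter | default | rationale |
|---|---|---|
| grid, pitch, rate | 7×7, 100 µm, 10 kHz | pitch and rate of the reference MEA; grid reduced to desk scale |
| amplitudes, trials | 0.15–1.65 V step 0.15, 20 | the experimental schedule |
| cathodic width T | 25 ms | the experimental pulse |
| inter-trial gap | 1 s | compressed from the experimental 10 s to keep recordings small; rates are per second so spontaneous statistics are unchanged |
| units per channel | 2 | typical single-electrode yield |
| template troughs | 100, 70 µV | healthy extracellular spikes, 20σ/14σ over the noise |
| noise σ | 5 µV | typical MEA noise floor |
| background rate | 2 Hz per unit | spontaneous RGC firing |
| evoked model | μ(A) = 3/(1+exp(−(A−0.8)/0.15)) | monotone-saturating count, ~2.5 spikes/pulse near 1 V |
| latency | uniform 5–200 ms | spans direct and network-mediated responses |
| responsiveness | 0.5 · 0.5^(layer−1) | ~50% at the first ring, decaying with distance |
| artifact | 1000 µV/V, rectangular biphasic | saturating, synchronous, charge-balanced |

Templates are biphasic differences of exponentials (~1.5 ms, fast trough
then small overshoot) with per-unit time constants, added by linear
superposition; a 2 ms per-unit refractory gap is enforced.  Everything is
drawn from R's default generator under the mandatory seed, so a
configuration reproduces bit for bit.

The generator emulates the *structure* of the experiment, not retinal
biophysics: no bursting or adaptation, no electrode impedance variation,
no drift, no correlated noise, no spike-amplitude attenuation with
distance, and each unit is seen by one electrode only.  Passing the
end-to-end checks therefore demonstrates that the algorithm recovers what
it claims *under its own assumptions* — clean templates, Poisson
backgrounds, stationary noise — not that it is robust to every failure
mode of real tissue.

## Numerical choices and degenerate inputs

* Sample indices are 0-based everywhere (sample k ↔ time k/rate);
  stimulus onset defines t = 0; raster windows are `[−pre, 0) ∪ (0, post]`.
* The adaptive artifact rule needs at least two channels over threshold:
  a lone excursion is a spike, not an artifact.
* Detection on an all-zero or peak-free trace returns an empty result;
  the SNR is reported as `NA` when no spike or no 10 ms spike-free
  stretch exists.
* K-means ties in assignment go to the lowest cluster index; silhouette
  `a = b` (including all-identical points) gives `s = 0`; duplicated
  points that starve a cluster are donated a point from the largest one.
* Threshold-grid ties pick the larger threshold.
* The sigmoid fit refuses flat curves and reports the residual sum of
  squares; the saturation voltage is `NA` when the plateau is not reached
  within the tested amplitudes.

## Problem sizes used in validation

The test-suite and the acceptance script exercise: 50-instance oracle
sweeps for the SWT and the silhouette; a 30 s single-channel recording
with 8σ templates for detection recovery; a 60 s two-unit channel for
sorting; five seeds of the 7×7 grid at a single strong amplitude
(1.05 V, 20 trials) for the end-to-end layer/responsiveness checks; and
20 trials × 30 units of Poisson counts on the full 11-step amplitude grid
for voltage-threshold recovery.  These sizes were chosen so the entire
validation runs on a laptop in minutes while keeping every statistical
check comfortably powered (e.g. ~500 expected background spikes in the
Poisson concentration check, ~600 observations per amplitude in the curve
fit).

## Known limitations

* The wavelet-packet feature set (sd + first quartile per node) is one
  defensible reading of summarizing packet coefficients for clustering;
  raw-coefficient features are not currently exposed.
* Units are sorted per electrode; the same cell recorded on two
  electrodes is counted twice (no cross-channel merging).
* No latency analysis, no separation of direct versus network-mediated
  responses, no drift correction.
* The CLI's stage subcommands recompute the pipeline deterministically up
  to the requested stage rather than caching intermediates.
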