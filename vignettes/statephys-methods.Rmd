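---
title: "Methods: state-dependent electrophysiology and behavioral phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent electrophysiology and behavioral phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Mouse models in which *Mecp2* is deleted from specific GABAergic interneuron
classes (pan-interneuron, VIP, PV, SST) are compared against floxed controls
on three fronts: state-dependent cortical physiology recorded in head-fixed
wheel-running animals (LFP band power, spike-field coherence, single-unit
firing and its modulation at locomotion onset), a battery of four behavioral
assays, and longitudinal outcomes (survival to P500, Racine-scored
seizures). `statephys` implements that full chain as composable, tested
functions, and ships a synthetic session/cohort generator with planted
ground truth so that every stage can be validated quantitatively without any
animal data.

```{r setup}
library(statephys)
```

# Locomotion state segmentation

The behavioral backbone is a two-state labeling of each session into
locomotion (L) bouts and quiescence (Q), derived from the wheel's magnetic
angle sensor.

`angle_to_velocity()` unwraps the angle (the 2&pi;&rarr;0 crossing produces
no spike), converts to arc length on the 15-cm wheel, differentiates with
central differences and smooths with a 0.25-s boxcar. The smoothing window
sits well below the 2-s minimum run duration of interest, so it blurs onset
localization by at most a fraction of the tolerance used downstream.

`segment_states()` detects change points in the speed distribution by
binary segmentation on the *globally rank-transformed* speed, minimizing
within-segment sums of squares of the ranks with a BIC-style penalty
(`penalty_scale * sigma^2 * log(n)`, noise variance estimated from first
differences of the rank series) and a 0.5-s minimum segment. A rank cost was
chosen over a Gaussian mean-shift cost because wheel speed is bimodal and
heavy-tailed within bouts; the rank transform makes the cost sensitive to
any distributional shift without a parametric model. Segments are labeled L
when their mean speed reaches 1 cm/s — the same speed criterion the trial
selection rule uses, since no separate labeling threshold is part of the
recipe — and same-label neighbours are merged. Two invariants are asserted
after every call: L and Q tile the session exactly, and raising the speed
threshold can never increase total L time.

Epoch and trial rules follow the recording conventions:

* firing-rate analyses use quiescent intervals longer than 20 s;
* LFP analyses additionally require the animal to have been stationary for
  20 s (usable data start 20 s after quiescence onset) and exclude data
  within 10 s of the next bout. The stationarity phrasing admits a weaker
  reading — any quiescent interval longer than 20 s is usable in full — so
  both conventions are implemented behind
  `stationary_convention = c("trim", "duration")`, with `"trim"` the
  default as the literal reading;
* locomotion-onset trials are accepted when the preceding quiescence
  exceeds 20 s, mean speed to the locomotion offset exceeds 1 cm/s, and the
  run lasts longer than 2 s.

# Spectral analysis

`compute_psd()` uses an averaged modified periodogram: 2-s Hann windows,
50% overlap, per-window mean removal, restricted to windows wholly inside
the selected epochs. No estimator is prescribed by the recipe; Welch
averaging at 0.5-Hz resolution resolves the narrow 3–6 Hz band while
keeping variance low over the tens of windows a typical session provides.
Relative band power is the trapezoidal band integral over the integral
across the analysis range, with linearly interpolated values at the exact
band edges. The normalization range for "total power" is 0.5–100 Hz: wide
enough to cover both reported bands (3–6 Hz and gamma, 40–55 Hz), excluding
DC drift; it is a configurable choice, not a derived one, and relative band
powers depend on it.

`spike_field_coherence()` bins spikes at the LFP rate and computes Welch
magnitude-squared coherence with the same windowing. The estimator's
small-sample bias (expected value `1/K` for independent processes, with `K`
windows) is removed via `(C - 1/K)/(1 - 1/K)` clipped at zero, which makes
both analytic limits testable: deterministically peak-locked spikes give
coherence ~1 at the locking frequency, independent Poisson spikes give ~0.

# Single units

Sorting quality is summarized by two accepted-unit criteria: isolation
distance above 20 and inter-spike-interval contamination at most 0.1% at a
1.5-ms refractory period. Isolation distance is the squared Mahalanobis
distance (cluster mean and covariance) of the n-th nearest noise spike,
n = cluster size; it is affine-invariant, which the suite verifies under
random invertible feature-space maps. Accepted units are split into
regular-spiking (RS) and fast-spiking (FS) classes at a 0.4-ms
trough-to-peak width — the conventional cortical boundary, exposed in the
configuration because the recipe itself names no criterion.

Locomotion-onset modulation compares the firing rate in [−0.5, 0.5] s
around onset (FR~L~) with [−5, −2] s before it (FR~Q~) through the index
(FR~L~−FR~Q~)/(FR~L~+FR~Q~). Rates are pooled (total spikes over total
window time) across accepted trials rather than averaged per trial: for
sparse trains per-trial ratios are dominated by empty windows. A per-trial
mean is available behind `per_trial = TRUE`. Trials whose Q window would
leave the session are dropped, and a 0/0 index is reported as `NA` and
excluded from population averages rather than silently propagated.

# Behavior scoring

All four assays consume plain (t, x, y) trajectories in cm. The elevated
plus maze reports percent time in the open arms, with the center zone in
the denominator but neither arm, and tracking gaps over 1 s removed from
the denominator. Open-field distance is the path integral after a 5-sample
median despiking filter. Three-chamber sociability scores side-chamber
occupancy (Time~C~, Time~E~) and approaches — entries into a 5-cm disc
around each holding cage. Approaches are debounced with a 7-cm hysteresis
radius: after an entry, a new approach is only counted once the animal has
retreated beyond 7 cm, preventing boundary jitter from double-counting.
Marble burying matches connected components between before/after masks by
centroid proximity and calls a marble buried when its exposed area dropped
by at least 2/3 — the recipe compares exposed areas without fixing a
per-marble threshold, so the conventional "two-thirds covered" criterion is
used and exposed as a parameter. All preference quantities go through
`preference_index(a, b) = (a - b)/(a + b)`.

# Cohort statistics

The statistical unit is the animal: unit- and session-level metrics are
averaged within animal before any test. Group comparisons use the
tie-corrected Kruskal-Wallis H with a chi-square reference, followed by
Dunn's post-test of each group against the control (pooled-rank means,
tie-corrected variance). The post-hoc family is the set of
mutant-vs-control comparisons and is Bonferroni-adjusted, matching the
usual "Dunn's multiple comparisons" convention of commercial statistics
packages; the adjustment method is a parameter. Survival curves are
empirical fractions alive per day with censoring at P500 (censored animals
count as alive throughout and are excluded from mean death age); a seizure
qualifies at Racine level 4 or 5. Box summaries are five-number
(min, quartiles, max) with linear-interpolation quantiles, mirroring
box-and-whisker plots whose whiskers span the full distribution.

# The synthetic-data generator

The generator emulates every input the pipeline consumes, with planted
effects recorded in a `truth` sidecar that tests read and the pipeline
never does.

* **Wheel**: bouts follow trapezoidal speed profiles with 0.5-s rise/fall,
  scaled so the distance integral equals the nominal speed times duration;
  onsets are therefore sharply defined and arc-length arithmetic is exact.
  White velocity noise (default 0.3 cm/s) is added before integration to
  the angle. Wheel traces are sampled at 50 Hz — ample for a signal whose
  useful bandwidth is a few hertz.
* **LFP**: band components (defaults 3–6 Hz and 40–55 Hz) are brick-wall
  filtered Gaussian noise scaled to a target RMS amplitude, multiplied by a
  band gain inside locomotion bouts, on top of broadband noise. Fixtures
  are synthesized directly at 1 kHz: the analyses use no content above
  110 Hz, and synthesizing at the 40-kHz acquisition rate would add cost
  without information.
* **Spikes**: inhomogeneous Poisson with quiescent/locomotion rates. The
  locomotion rate engages 0.5 s before bout onset, emulating the
  anticipatory firing-rate rise seen at state transitions; this also makes
  the closed-form index (rate~L~−rate~Q~)/(rate~L~+rate~Q~) the exact
  expectation of the onset-window measurement. Phase locking thins spikes
  with a von-Mises-shaped acceptance on the instantaneous narrowband phase;
  the thinning lowers the mean rate as concentration grows, so coherence
  comparisons across concentrations are made at modest &kappa;.
* **Behavior**: trajectories are reflected random walks drifting toward a
  scheduled target zone; the visit schedule realizes the planted occupancy
  (sociability preference index, EPM open-arm fraction). The planted EPM
  fraction is defined among arm time, since center and transit time dilute
  raw percentages. Marble masks are disc rasters with planted burial
  decisions realized as chord-shaped occlusions on either side of the 2/3
  threshold.
* **Outcomes**: death and first-seizure ages are exponential draws at
  per-group daily hazards from weaning (P21), censored at P500, with
  sub-threshold Racine 1–3 events sprinkled in to exercise the level
  filter.

Cohort defaults (`default_cohort_spec()`) mirror the study design these
tools target: group sizes of order 5–12 animals, a ~2-fold gamma-power
reduction (amplitude × 0.7) and a ~3-fold modulation-index reduction in the
affected groups, 3-fold firing-rate increases, reversed sociability
preference, and hazards chosen so mean death ages fall near the reported
range (e.g. ~120 d for the pan-interneuron-like group). Between-animal
variability is lognormal (SD 0.15 on log gamma amplitude, 0.2 on log firing
rate) — enough that group tests are non-trivial while planted effects of
the default size remain detectable.

What the generator does **not** emulate: biophysical waveforms, 1/f
background structure, electrode drift, behavioral idiosyncrasies (grooming,
postural artifacts), or video noise. Passing tests therefore demonstrate
correctness of the measurement and inference chain on data whose generative
assumptions are known, not robustness to every artifact of real recordings.

# Numerical choices and degenerate inputs

* Interval membership is half-open `[start, end)` everywhere, so adjacent
  windows never double-count a spike.
* Undefined quantities (0/0 indices, isolation distance with fewer noise
  than cluster spikes, contamination of a 1-spike train) are `NA` (or
  `Inf` for unbounded isolation), never silent `NaN`; flagged coherence
  results carry a `"too_few_spikes"` marker instead of being dropped.
* `compute_psd()` fails loudly with an "insufficient quiescence" error when
  no complete window fits the epochs.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical spec + seed gives byte-identical output, which the
  pipeline's provenance record (config hash + seed) makes auditable.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data at desk scale:
600-s sessions with 8 bouts for segmentation recovery, 90–200 s of 1-kHz
LFP for the spectral limits, 30–40 replicate spike trains for
modulation-index convergence, 2000 null replicates (n = 10 per group) for
omnibus-test calibration, and 12–20 replicate cohorts of 32 animals
(400-s sessions, 2 units each) for end-to-end planted-group detection.
These sizes were chosen so each check's Monte-Carlo error is well below the
effect it certifies.

# Known limitations

* Binary segmentation with a rank cost localizes well-separated bout
  onsets to within ~0.1 s but can fragment long bouts with strong
  within-bout speed drift; the merge step absorbs most of this.
* Relative band power depends on the 0.5–100 Hz normalization range;
  comparisons across configurations must hold it fixed.
* Dunn's test uses the normal approximation; for very small groups
  (n &le; 3) exact permutation would be preferable.
* The survival summary is a plain empirical curve; with informative
  censoring before P500 a Kaplan-Meier estimator would be required.
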