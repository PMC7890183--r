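---
title: "Methods: sway posturography, phase-lag connectomes and spanning-tree integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sway posturography, phase-lag connectomes and spanning-tree integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

posturenet implements the full analysis chain of a balance-training
transfer experiment: behavioral outcomes from center-of-pressure (COP)
sway, functional brain connectomes from multichannel EEG via the
weighted phase-lag index (wPLI), minimum-spanning-tree (MST) network
integration metrics, and the paired multivariate statistics used to
compare a pre-training and a post-training session in each group. Since
studies of this design rarely deposit raw recordings, the package ships
a first-class synthetic-data module whose ground truth every downstream
stage is tested against. This vignette documents the models, the
tunable parameters with their defaults, the numerical choices, and what
the synthetic cohorts do and do not establish about real data.

## Behavioral outcomes from COP sway

Raw AP/ML sway is conditioned with a 4th-order low-pass Butterworth at
6 Hz. The filter is applied forward–backward (zero phase) although some
descriptions leave the direction unspecified: posturography convention
favors zero-phase conditioning because phase distortion of slow sway
would bias timing-sensitive measures. From the conditioned trial the
package computes seven metrics:

* **RMS sway** (`rms_sway`), the dispersion about the trial mean, per
  axis, in cm. The mean is removed because stance offset depends on
  foot placement, not postural control.
* **95% confidence ellipse area** (`confidence_ellipse_area`), the area
  of the bivariate-Gaussian ellipse covering 95% of the sway
  distribution: `pi * qchisq(0.95, 2) * sqrt(det(S))` with `S` the
  AP/ML sample covariance (`qchisq(0.95, 2) = 5.991`). A degenerate
  covariance yields area 0 with a warning rather than an error, so
  batch runs survive a stuck trace.
* **Mean frequency** (`mean_frequency`), the power-weighted centroid of
  the Welch spectrum with a 15 s Hann window and 25%-of-window overlap.
  Segments are zero-padded to a 0.02 Hz grid: a 15 s window alone gives
  ~0.067 Hz bins, and only zero-padding reconciles a 15 s window with a
  0.02 Hz spectral resolution. The integration band is (0, 6] Hz with
  the DC bin excluded, since the trace is low-pass filtered at 6 Hz and
  DC reflects stance offset.
* **Sample entropy** (`sample_entropy`), `-log(sum(A_i)/sum(B_i))` with
  template length `m = 2`, tolerance `r` equal to 20% of the SD of the
  decimated series, Chebyshev distance, self-matches excluded, and both
  counts taken over templates `i = 1..N-m`. The series is decimated to
  100 Hz through an anti-aliasing filter first; plain subsampling would
  alias high-frequency noise into the match counts. Because `r` tracks
  the SD, the metric is invariant to affine transforms of the signal.
  The hot O(N²) counting loop is implemented in C++; an independent
  brute-force R implementation serves as the oracle in the test suite.
  If no template pair matches at length `m + 1` the statistic is
  undefined and the package signals a distinct condition class rather
  than returning a number.
* **Task error** (`task_error`), the RMS mismatch between the
  stabilometer plate angle and the target over seconds 3–42 of a 45 s
  round. The mismatch is *not* demeaned: a constant angular offset is a
  genuine task error. Protocol descriptions often leave this point
  ambiguous; the package keeps the bias and flags the choice for
  sensitivity testing.
* **Standardized errors** (`standardized_errors`), per-round errors as
  percentages of round 1.

Per-subject outcomes are the means over the (by default three) trials
of a session.

## EEG preprocessing

The chain order is fixed: broadband filter → ocular regression →
epoching → artifact rejection → sub-band filtering.

1. **Broadband filter** (`broadband_filter`): 1–60 Hz zero-phase FIR.
   The filter is a linear-phase Blackman design applied with exact
   group-delay compensation through FFT convolution; a single pass of a
   symmetric FIR already has zero net phase. The default 0.6 Hz
   transition width makes DC attenuation exceed 60 dB while leaving
   passband gain flat within 2%. Boundaries use even (mirror)
   reflection padding — value-continuous and mean-preserving — because
   an odd reflection would inject a local-mean step whose broadband
   energy leaks through the passband.
2. **Ocular correction** (`derive_eog`, `regress_out_ocular`): bipolar
   VEOG (supraorbital − infraorbital) and HEOG (right − left canthus)
   channels are derived, then every scalp channel is regressed on both
   (ordinary least squares with intercept) and the fitted ocular
   component subtracted. Coefficients are returned so synthetic
   propagation gains can be checked; collinear or degenerate EOG
   regressors fall back to a pseudo-inverse fit with a warning.
3. **Epoching** (`epoch_recording`): contiguous non-overlapping 2 s
   epochs by pure sample-index arithmetic, after discarding the first
   2 s of the run; the remainder tail is dropped.
4. **Artifact rejection** (`reject_artifacts`): an epoch is dropped iff
   any scalp channel exceeds ±100 µV. Protocols often state only that
   automated rejection was applied; an absolute amplitude threshold is
   the standard automated criterion, and the threshold is configurable
   rather than hard-coded. Visual inspection is out of scope.
5. **Sub-band filtering** (`band_filter`): theta 4–8, alpha 8–13, beta
   13–20 Hz, 4th-order Butterworth forward–backward per epoch, with
   0.5 s reflection padding trimmed afterwards to bound edge transients
   on 2 s epochs. Activity below 4 Hz and above 20 Hz is not analyzed
   (ocular and muscle contamination). Reference handling (linked
   mastoids) is assumed already applied in the input.

## Phase-lag connectivity

Instantaneous phase comes from the analytic signal
(`instantaneous_phase`); the first and last 10% of samples of each
epoch are excluded from all expectations because the finite-length
Hilbert transform is biased near the edges. Two indices are available:

* **PLI** `= |E{sgn(Δφ)}|`: the asymmetry of the phase-difference
  distribution around zero, blind to exactly zero-lag coupling.
* **wPLI** (default): with `Z = a_x conj(a_y)` the analytic
  cross-signal, `wPLI = |E{Im Z}| / E{|Im Z|}`. Phase differences near
  ±90° carry the largest imaginary component, so the index maximizes
  sensitivity exactly where volume conduction (which is instantaneous
  and therefore real-valued in `Z`) contributes nothing.

Published renderings of the weighted index vary and are sometimes
typographically garbled; the package implements the established
imaginary-cross-spectrum estimator — the standard definition in the
electrophysiology literature — which realizes the ±90° weighting
directly. A phase-difference-weighted variant,
`|E{|Δφ| sgn(Δφ)}| / E{|Δφ|}`, is available behind
`variant = "phase-weighted"` for sensitivity analysis. When the
denominator vanishes (an exactly zero-lag pair) the index is defined as
0, consistent with "no phase synchronization". Expectations are taken
over time within one epoch; matrices are computed per epoch and tree
metrics averaged afterwards.

One estimator property matters for interpretation: within a 2 s epoch a
narrowband signal offers only ~10 effectively independent samples, so
the per-epoch wPLI of truly independent channels has a positive noise
floor around 0.3 — it cannot average to zero across epochs because the
index is non-negative. The suppression-to-zero property therefore holds
as the series grows (the package's tests verify it on 40–60 s
recordings), while at 2 s the floor is common to both sessions and
cancels in pre/post contrasts.

## Spanning-tree backbone and integration metrics

The connectome's backbone is the spanning tree of *strongest*
connections — the maximum-weight spanning tree, equivalently the
minimum spanning tree of `1 − wPLI` (`max_spanning_tree`). Kruskal's
algorithm runs on edges sorted by descending weight with deterministic
lexicographic `(i, j)` tie-breaking; floating-point ties are compared
exactly, with no epsilon. Zero-weight edges enter only if the
positive-weight graph cannot span all nodes (with a warning), and `NA`
entries from undefined-phase channels are treated as zero weight, also
with a warning.

Four topology-only metrics summarize integration, each normalized into
[0, 1]:

| metric | definition | normalization | integrated network |
|---|---|---|---|
| diameter | longest path, in edges | ÷ (N−1) | lower |
| leaf fraction | # degree-1 nodes | ÷ (N−1) | higher |
| avg. eccentricity | mean over nodes of the longest distance to any node | ÷ (N−1) | lower |
| BC_max | most node pairs routed through one node | ÷ (N−1)(N−2)/2 | higher |

No single normalization is universal across toolboxes; these constants
put a 30-channel montage's values on the scale conventional in the
MST-EEG literature (an edge-count diameter of ~10 of 29 maps to ≈0.34)
and are documented here rather than presented as recoverable facts.
Betweenness uses the component-size identity for trees (pairs through
`v` = pairwise products of the component sizes after deleting `v`); the
test suite checks all four metrics against BFS/path-enumeration oracles
on every labeled tree with up to 7 nodes. Aggregation averages metrics
over epochs within a trial, then over trials per subject, so trials
with unequal surviving epoch counts carry equal weight.

## Paired statistics

* **Paired t** (`paired_t`): classical two-sided t on the differences;
  a zero-variance difference vector is handled explicitly (t = 0, p = 1
  for no shift; infinite statistic with p = 0 for a constant shift).
* **Paired Hotelling's T²** (`paired_hotelling`): one-sample T² on the
  difference vectors, `T2 = n d̄' S⁻¹ d̄`, with
  `Wilks' Λ = (1 + T²/(n−1))⁻¹` and
  `F = T² (n−p) / (p (n−1))` on `(p, n−p)` degrees of freedom. The
  p = 1 case reproduces the squared paired t to numerical precision — a
  tested identity. Singular difference covariances are refused with a
  suggestion to reduce the variable set.
* **Simes** (`simes`): order the unadjusted p-values and reject the
  global null iff `p_(i) ≤ i·α/m` for some `i`; elementary hypotheses
  are rejected by the same inequality at their rank. Write-ups of this
  procedure sometimes state the inequality inverted; the package
  implements the standard rule, which is exactly level-α under
  independence and whose m = 3 post-hoc cutoffs are 0.0167, 0.0333 and
  0.05.

The group layer (`paired_family_test`, `run_behavioral`,
`run_connectome`) mirrors the conventional pre/post outcome-table
layout: one Hotelling
family per direction over the (RMS, MF, SampEn) triple plus a paired t
for the ellipse area on the behavioral side; one Hotelling family per
tree metric across the (theta, alpha, beta) triple on the connectome
side; Simes `m` equals the number of post-hoc comparisons within one
family.

## The synthetic-data module

Every generator is seeded and deterministic, and restores the caller's
RNG state.

**Coupled EEG** (`gen_coupled_eeg`). Sources are Gaussian noise
band-passed at the requested band edges (4th-order Butterworth,
forward–backward). A coupled channel is the analytic-signal phase
rotation of its driver — `Re{a(t) e^{-iφ}}` — which fixes the phase
difference at exactly `φ` at band center; phase jitter scaled by
`1 − coupling_strength` (narrowband noise rescaled to SD π) degrades
the lock continuously, and the recovered wPLI is monotone in the
coupling strength. Volume conduction is emulated by an instantaneous
(zero-lag by construction) mixing matrix, and white sensor noise is set
by an SNR in dB. Defaults mirror a typical scalp recording: 30 channels
of a standard 10–20 montage at 1 kHz.

**Ocular artifacts** (`gen_eog_artifacts`). Blinks are 200 ms
raised-cosine pulses and saccades 50 ms step-ramps — simple shapes
that match typical EOG morphology well enough to exercise regression
correction. Each scalp channel receives the blink train times a known
per-channel gain; four periocular channels are attached whose
derivation gains sum to one, so the bipolar traces reproduce the true
ocular sources up to sensor noise. The clean recording is retained, so
correction error is measurable exactly.

**COP trajectories** (`gen_cop`). Each axis is a broadband sway
process: an order-2 Butterworth band-pass core (low edge fixed at
0.1 Hz, since postural corrections bound very slow drift) whose upper
corner is solved numerically so the theoretical centroid of the
filtered spectrum over (0, 6] matches the requested value, plus a small
high-frequency "tremor" component (1–6 Hz, at most 3% of variance).
The `regularity` control blends in a deterministic oscillation at the
centroid frequency — which leaves the centroid unchanged while making
the trajectory more self-similar, so sample entropy falls as
regularity rises. Finally the two axes are whitened against their
realized sample covariance and re-colored by the symmetric square root
of the target covariance, so the sample covariance of every emitted
trial equals the specification exactly and ellipse-area recovery is
exact up to the chi-square model. An earlier, narrower design (a
band-pass centered *at* the centroid) was rejected because a 0.2–0.3 Hz
narrowband process is unresolvable inside a 15 s Welch window and the
resulting trace was too smooth for meaningful entropy: the broadband
model is both more realistic and the only one under which the module's
own recovery properties hold.

One estimator caveat found while validating: the Welch centroid
carries a positive small-sample (Jensen-type ratio) bias of roughly
+0.04 Hz on 120 s records that vanishes by 600 s; the centroid-recovery
test therefore uses 600 s records, and mean frequencies of 60 s cohort
trials should be read as comparable within a study, not as unbiased
absolute values.

**Null p-values** (`gen_null_pvalues`) are i.i.d. Uniform(0, 1)
matrices for calibrating the Simes procedure.

**Cohort scenario.** `study_config` collects every tunable with the
conventional defaults (16 subjects per group, three trials, 6 Hz sway
conditioning, 1–60 Hz broadband, ±100 µV rejection, 2 s epochs) and a
generative scenario: baseline sway (SD 0.65/0.45 cm AP/ML, centroid
0.27 Hz, regularity 0.5, lognormal 12% between-subject variation, 5%
trial jitter) with post-session effects — smaller, faster, more
irregular sway — planted in the control group only; and EEG coupling
that is spread over disjoint channel pairs before training but
concentrated onto a single hub channel after training in the control
group, the topology shift the integration metrics are designed to
detect. Configurations round-trip losslessly through YAML.

## What the synthetic cohorts do and do not show

The generators emulate the *measurable structure* the pipeline
estimates: narrowband phase lags, zero-lag mixing, known artifact
propagation, prescribed sway covariance, spectral centroid and
regularity. They do not emulate biophysically realistic head volumes,
dipolar source geometry, nonstationary vigilance dynamics,
heavy-tailed artifact families, or the coupling between posture and
cortical activity. Passing tests therefore establish that the
estimators recover known ground truth under the stated noise models —
they do not certify effect sizes or significance patterns on human
recordings, and group values from a human cohort cannot be recomputed
without its raw recordings; the pipeline instead produces tables of
identical structure from synthetic cohorts.

Session effects on spectrum and regularity are applied to both axes
jointly (the exact-covariance coloring mixes the axes), so
axis-specific spectral effects are outside the current scenario
vocabulary; amplitude effects are per-axis.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than by NaN
propagation: degenerate sway covariance → area 0 with a warning;
all-zero EEG channel → undefined phase, flagged, its pairs set missing;
wPLI denominator below machine tolerance → 0; no sample-entropy
template matches → a distinct "undefined" condition; all epochs
rejected → an error advising threshold review; fewer subjects than
variables or a singular difference covariance → refusal with an
explanation. Seeds derived from a master seed are drawn once per
cohort unit from a deterministic stream and stay below 2³¹.

The shipped analysis scripts run the behavioral arm at the full study
layout (2 × 16 subjects × 2 sessions × 3 × 60 s trials at 100 Hz) and
the connectome arm at a reduced scale chosen for a laptop-class run
(2 × 8 subjects, 12 channels at 250 Hz, 22 s runs, 2 trials): the
estimators are scale-free in these dimensions, and the reduced cohort
exercises every code path including rejection and post-hoc control.
The test suite's Monte-Carlo sizes (50-seed wPLI limits, 10⁵ Simes
replicates, 10⁴ Hotelling null replicates, exhaustive tree enumeration
to 7 nodes) follow the package's acceptance properties.

## Known limitations

* Per-epoch wPLI at 2 s carries the noise floor discussed above;
  between-session contrasts are the supported use.
* The ocular model covers blinks and horizontal saccades with linear
  instantaneous propagation; slow drifts and nonlinear EOG–EEG coupling
  are not modeled.
* MST normalization constants are a documented convention, not a
  recoverable fact about the source toolbox.
* EEG interchange is delimited text; EDF input is not implemented in
  this environment.
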