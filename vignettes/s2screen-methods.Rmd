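---
title: "Acoustic-electrocardiographic screening for pediatric ASD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic-electrocardiographic screening for pediatric ASD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem and the measurement model

A secundum atrial septal defect (ASD) shunts blood from the left to the right
atrium. The chronic right-ventricular volume overload delays pulmonary valve
closure, so the second heart sound's pulmonic component (P2) separates from
its aortic component (A2): auscultation classically finds a *wide, fixed*
splitting of S2 that barely varies with respiration. `s2screen` implements a
quantitative version of that bedside sign for a wearable patch that records a
phonocardiogram (PCG, 2,000 Hz) synchronized with a single-lead ECG (500 Hz),
and the diagnostic biostatistics needed to evaluate it.

Five per-beat indices are computed from the fiducials of each cardiac cycle:

* **S2 splitting (ms)** = P2 peak − A2 peak;
* **S1–S2 (ms)** = A2 peak − S1 peak (mechanical systole);
* **S1–S2/RR (%)** = S1–S2 divided by the beat's RR interval × 100;
* **EMAT (ms)** = first S1 peak − ECG Q-wave onset (electromechanical
  activation time);
* **EMAT/RR (%)** = EMAT/RR × 100.

A subject's value for each index is the arithmetic mean over 30 consecutive
artifact-free sinus beats gated to end-expiration — the mean of per-beat
ratios, not the ratio of means, which differ whenever RR varies.

## What the synthetic-data generator emulates

No recordings are distributed with the device study, so every downstream
stage is exercised against synthetic subjects with exact ground truth.

`generate_ecg()` builds a template sinus rhythm (P wave, a 30-ms raised-cosine
Q dip starting 40 ms before the R peak, Gaussian R/S/T deflections) with
multiplicative RR jitter. `generate_pcg()` places one S1 burst and two S2
clicks per beat by *inverting the index definitions*: the S1 envelope peak at
Q onset + EMAT, A2 at S1 + S1–S2, P2 at A2 + the instantaneous split. Heart
sounds are Gaussian-windowed (S1, sigma 10 ms at 55 Hz) or attack–decay
(A2/P2, 0.6 ms rise, 2.2 ms decay at 180 Hz) sinusoids; any morphology with
unambiguous envelope peaks would do, and this one is analytically placeable.
The A2/P2 decay constant is deliberately short so that splits down to 5 ms
remain resolvable by the estimator — with realistic 10–20 ms burst durations
the two components fuse below about 15 ms, which is a physical limit of
envelope-based splitting, not an algorithmic one. Passing tests on these
clicks therefore demonstrates correctness of the timing chain, not that
narrow splits are recoverable from real pediatric PCGs.

Respiration enters three ways: the instantaneous split is
`split + resp_mod * sin(phase)`; the whole PCG amplitude is scaled by a
lung-volume proxy `(1 + cos(phase))/2` (so sounds are quietest at
end-expiration); and the phase itself is carried in the ground truth.
Controls default to `resp_mod = 10` ms, ASD subjects to `0.5` ms — the study
describes the physiology ("fixed" splitting with minimal respiratory
variation) but gives no numbers, so these are package choices in the 8–12 ms
range typical of pediatric respirophasic splitting. `generate_subject()`
additionally emulates the acquisition protocol with an end-expiratory
breath-hold segment (phase held at pi from 20 s to 48 s of a 70-s recording):
without an instructed hold, a free-running 4-s respiratory cycle never
contains 30 *consecutive* gated beats, so the protocol itself implies one.
Within-subject beat-to-beat variability of the indices defaults to a 2-ms SD
(mean-centred per subject, so targets are hit exactly); the study reports no
such figure and this parameter makes no fidelity claim.

Index-level cohorts (`generate_cohort_indices()`) draw per-group normal
marginals with the published means and SDs. S2 splitting and S1–S2/RR share a
latent correlation (`index_rho = 0.5`): both are driven by the same
right-ventricular overload, and with fully independent indices the four
published index–covariate correlations (0.72 and 0.65 with defect size, 0.76
and 0.69 with RVEDVI) are *jointly infeasible* — the implied correlation
matrix is not positive definite. Covariates are constructed from the
standardized indices so the requested Pearson correlations hold exactly in
expectation; infeasible requests are rejected rather than approximated.
Defect size (12 ± 4 mm) and RVEDVI (85 ± 15 mL/m²) marginals are plausible
pediatric values, chosen once; the group statistics never depend on them.

What the generator does **not** emulate: murmurs and S3/S4, non-sinus
arrhythmia, sensor coupling variation, pink/ambulatory noise (noise is white
at a stated SNR), or pediatric growth effects on the indices. Recovery
results on clean synthetic subjects therefore bound the pipeline's numerical
error, not its field performance.

## Signal-processing choices

* **Filters.** Zero-phase Butterworth throughout, so group delay cannot bias
  timing indices. PCG: 4th-order 20-Hz high-pass plus a 950-Hz low-pass guard
  (the nominal 1,000-Hz upper edge equals Nyquist and is unrealizable).
  ECG: 2nd-order 0.5-Hz high-pass plus 6th-order 40-Hz low-pass; the
  double-pass application attenuates 50/60-Hz mains by > 20 dB.
* **Artifact mask.** Contiguous 1-s windows. "Amplitude variation" is
  undefined in the source protocol; here a window is rejected when its peak
  envelope deviates from the recording-median per-window envelope peak by
  more than 30% (a literal max-minus-min within a window would reject every
  normal cardiac cycle, whose envelope swings from diastolic silence to the
  S1 peak). The SNR metric is the in-window burst-to-gap power ratio in dB,
  thresholded at 10 dB and applied to the PCG (heart-sound quality is the
  binding constraint; the channel is configurable).
* **R peaks.** Smoothed squared-derivative energy with an adaptive threshold
  and 200-ms refractory period, refined to the waveform maximum with
  parabolic interpolation.
* **Q onset.** In a 120-ms pre-R window, the first point where the smoothed
  absolute slope exceeds 6% of the window's peak slope — floored at
  median + 3 MAD of the baseline slope and required to persist for ~8 ms, so
  isolated noise excursions cannot fire early.
* **S1/S2 segmentation.** Shannon-energy-style envelope (smoothed squared
  signal, sigma 8 ms). S1 is the dominant peak in [R, R+200 ms], S2 in
  [R+200 ms, R+0.6 RR]; onsets at the 10%-of-peak crossing measured above the
  local envelope baseline (a raw 10% threshold drags onsets to the window
  edge once the noise floor exceeds it). Missing sounds flag the beat invalid.
* **A2/P2 splitting.** Within S2-onset −20/+120 ms, the segment is band-passed
  to 60–400 Hz and a fine envelope (sigma 1.2 ms) is peak-picked; the two
  dominant maxima (merged below 2 ms separation, threshold 35% of the window
  maximum) give A2 then P2 in time order; a single resolvable peak reports a
  zero split with coincident fiducials. Sub-sample positions come from
  parabolic interpolation. The S1–S2 interval ends at the **A2** peak; when
  splitting is wide, "peak of S2" is ambiguous and the global S2 envelope
  peak would drift toward P2 with the split itself.
* **Beat selection.** Earliest run of 30 consecutive beats that are valid,
  artifact-free and end-expiration-gated (phase within pi ± pi/4, from the
  ground truth, an auxiliary phase series, or the amplitude-modulation
  estimate); if no such run exists the longest qualifying run is used with a
  warning, and zero qualifying beats excludes the subject.

## Statistical conventions

Group comparisons use the pooled-variance Student's t (group order
control → ASD, so positive statistics mean higher in ASD); with equal group
sizes Welch's statistic would be identical to three decimals on the published
summaries, and the source analysis reports variance homogeneity. The 2×2
chi-square carries **no** continuity correction — the published sex statistic
(0.04) is only reproducible without it — and switches to Fisher's exact test
below an expected count of 5. Levene's test is the one-way ANOVA on absolute
deviations (mean-centred by default, median optional). The age × group
interaction is tested in a normal-errors linear model, the simplest model
consistent with a reported "P for interaction" on a continuous index.

ROC analysis uses the Mann–Whitney estimator (ties counted half), which the
test suite proves equal to the trapezoidal area and to a brute-force pairwise
oracle. The AUC standard error is Hanley–McNeil's closed form, with the Wald
interval auc ± 1.96 se — this reproduces the published CI structure; a DeLong
variance would also be defensible but is not what the source tables contain.
Youden-optimal cut-offs are reported as midpoints between adjacent distinct
scores under the rule "score ≥ cutoff is positive" (the published
quarter-value cut-offs, 31.75 ms and 35.25%, are characteristic of midpoint
reporting), with ties broken toward higher sensitivity. Cross-validation
(k = 10) and the bootstrap (B = 1,000, bias correction
2·AUC − mean bootstrap AUC, percentile CI) both stratify by class so every
resample contains cases and controls at n = 50/50. Logistic regression is
the IRLS maximum-likelihood fit with observed-information standard errors;
quasi-perfect separation is raised as an explicit error.

## Numerical tolerances and problem sizes

Fiducial recovery on clean synthetic subjects is accurate to well under
0.5 ms, against a ±2 ms acceptance band (timing) and ±0.5 percentage points
(ratio indices); the split estimator is linear over 5–60 ms with slope within
[0.9, 1.1] and |intercept| < 2 ms. Monte-Carlo checks in the test suite use
20 seeds (detector sensitivity/precision, noise-degradation monotonicity),
100 seeds (test calibration/power), 1,000 replicate cohorts (AUC closed-form
convergence), and single 100,000-per-group draws (cohort moment convergence,
binormal AUC within 0.005) — sizes chosen so each stochastic assertion sits
several standard errors from its threshold while the whole suite runs in
about a minute. Because a single 50/50 cohort's AUC has an SD of about 0.04,
single-cohort agreement with the published CIs is asserted over five seeds
(at least four must fall inside) rather than on one arbitrary draw.

## Known limitations

The delineation algorithm is validated only against the package's own
synthesizer; the manual-review step of the source protocol is replaced by
per-beat validity flags. The A2-before-P2 ordering is assumed (true for ASD
physiology; paradoxical splitting would swap the components). WAV/CSV I/O
covers the bundled two-channel layout only. The published Wald statistics and
two Table-1 t values differ from recomputation on the rounded summaries in
the last digit; these are reproduction limits of the printed tables, not
targets of the implementation.
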