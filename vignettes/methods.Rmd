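---
title: "Methods: from raw triaxial acceleration to a calibrated physical activity level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw triaxial acceleration to a calibrated physical activity level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actipal)
```

## Scope and model

`actipal` implements the processing chain of a waist-worn triaxial
accelerometer of the Active style Pro family and the downstream energy
model used to predict the physical activity level (PAL = TEE/BMR) of
community-dwelling older adults, together with a sex-specific linear
calibration of the device PAL against a reference PAL of the kind
obtained from doubly labeled water and Douglas-bag calorimetry. The
reference measurements themselves (isotope chemistry, gas analysis) are
outside the package: cohorts carry "measured" BMR and TEE as inputs, and
the synthetic generator produces them with known ground truth.

The chain is: raw 32 Hz, 3 mG-resolution triaxial signal → 0.7 Hz
high-pass filter → 10-s epochs of filtered and unfiltered synthesized
acceleration (ACfil, ACunfil) → three-way classification
(sedentary / locomotive / non-locomotive) with linear MET equations →
minute METs → non-wear detection and 0.9-MET imputation → valid-day
selection → Ganpule BMR, AEE, TEE = (BMR + AEE) × 10/9, PAL → per-sex
OLS calibration of measured on predicted PAL.

## Signal processing decisions

The published algorithm fixes the cutoff (0.7 Hz), epoch length (10 s),
sampling rate and resolution, but not the filter realization, the
across-axis synthesis, or how gravity is kept out of ACunfil. The package
makes these choices explicitly, and all of them are configurable through
`asp_params()`:

* **Filter realization.** A 4th-order Butterworth high-pass applied
  forward-backward (`signal::filtfilt`), i.e. zero phase. A causal filter
  would delay the filtered path by a few samples relative to the raw
  path; since the classifier thresholds the *ratio* of the two paths
  epoch by epoch, phase lag at epoch boundaries would create artificial
  ratio excursions. Zero-phase filtering removes that artifact class.
* **Per-bout filtering.** The filter is applied independently to each
  maximal contiguous stretch of recorded signal (samples not all-zero),
  after removing the stretch's mean. Synthetic non-wear is exactly zero;
  filtering across such gaps smears the ~1 g on/off step into a transient
  (time constant ≈ 0.23 s, but large amplitude) that contaminates the
  epochs on both sides of a wear boundary — enough to misclassify the
  first epoch after resumption of wear and to break exact-zero runs.
  Mean-removal before filtering is neutral for an ideal high-pass and
  shrinks the remaining start/end transients. Stretches shorter than
  about one second are only mean-centered, as the forward-backward pass
  is not stable on them.
* **Synthesis.** Per axis, the mean absolute value over the epoch; across
  axes, the Euclidean norm of the three per-axis values. Vector magnitude
  is the standard convention for this device family.
* **Gravity in ACunfil.** The unfiltered path subtracts the per-epoch,
  per-axis mean before taking absolute values. Without this, the static
  ~1000 mG gravity vector dominates ACunfil and the 1.16 ratio threshold
  is unreachable; with it, ACunfil retains exactly the 0–0.7 Hz band
  content (relative to the epoch mean) that the ratio is designed to
  detect.
* **Partial epochs and minutes** are dropped, never padded.

## Classification and MET assignment

The classifier is a total deterministic map: ACfil ≤ 29.9 mG →
sedentary; else ACunfil/ACfil ≥ 1.16 → non-locomotive; else locomotive.
Two boundary conventions are fixed here because the printed conditionals
leave them open: ACfil exactly 29.9 mG is assigned to sedentary (the
sedentary and non-locomotive equations differ by < 0.01 METs there, so
the choice is immaterial but must be deterministic), and ACfil = 0 —
where the ratio is undefined — is sedentary, so the ratio is never
evaluated on a zero denominator. The ratio threshold itself is evaluated
with ≥, as printed.

The intensity partition uses the continuous MET scale: sedentary ≤ 1.5,
light on the open interval (1.5, 3.0), MVPA ≥ 3.0. The conventional
discrete labels ("1.6–2.9 METs") are read as that open interval. One
internal inconsistency in the source literature (a sedentary bound
printed once as ≤ 0.5 METs and once as ≤ 1.5 METs) is resolved in favor
of 1.5, the standard sedentary-behavior definition.

## Wear filtering

"Zero counts" are flagged per epoch from the raw quantized samples: an
epoch is a zero-count epoch when the device recorded nothing (all samples
exactly zero). Flagging from the filtered path instead would fail at run
boundaries, where filter transients make the filtered magnitudes slightly
non-zero even though nothing was recorded; epoch files that lack the raw
flag fall back to requiring both synthesized accelerations to be exactly
zero. A minute is zero when all six of its epochs are; maximal runs of
≥ 60 zero minutes are non-wear; runs are detected within a calendar day
(no midnight spanning), the simplest convention consistent with day-level
wear accounting. Imputation completes every day to 1440 minutes at 0.9
METs for non-wear and unobserved minutes. Intensity minutes are tallied
over wear time only — imputed minutes count toward energy, not toward
observed behavior.

## Energy model

The AEE convention is `(MET − 1) ×` per-minute RMR with RMR = 1.1 ×
predicted BMR. The source sentence ("minute-by-minute METs multiplied by
the estimated resting metabolic rate") is ambiguous — read literally it
would double-count resting expenditure inside TEE = (BMR + AEE) × 10/9.
The (MET − 1) form is the convention of this device's validation
literature and back-calculates correctly: a predicted TEE near 1660
kcal/day on a ~960 kcal/day BMR implies a 24-h mean of ≈ 1.5 METs, which
is plausible, while the alternative implies ≈ 0.5 METs, which is not.
Negative minute contributions (imputed 0.9-MET minutes) are retained.
AEE, TEE and PAL are computed per valid day and averaged with equal
weights; whether the original macro averaged days or pooled 14-day totals
is unknown, and equal-weight day averaging is the declared convention.

The Nagayoshi adjustment (1.191 × MET + 0.106) is applied to observed
(wear) minute METs only; the imputed 0.9 is an assigned calibration
constant, not device output, and is left untouched. Applying the
adjustment to imputed minutes as well would shift the adjusted PAL up by
roughly 0.1 on a typical day; the choice is recorded here because the
source is silent on it.

## Calibration and validation statistics

`pal_calibration()` fits measured PAL on predicted PAL by OLS separately
per sex — never pooled, since the two sexes have visibly different lines
— and reports slope, intercept, residual SD (n − 1 denominator
throughout), Pearson r and n. The mean residual on the fitting sample is
zero by construction; the residual SD is the honest summary of the
correction's precision *on its own development sample*, and transferring
it to a new cohort will understate the true error. Paired t tests are
used for measured-versus-predicted comparisons on the same participants
and Welch tests between sexes; the paired choice is the natural design
but is a convention, not something the source states. Reported numbers
are rounded only at the reporting layer (PAL to 2 decimals, energies to
whole kcal/day, r to 3 decimals).

## What the synthetic generator does and does not emulate

`gen_activity_signal()` builds minimal signals that land robustly on the
designed side of each threshold: locomotive segments are a sinusoid at
2 Hz (default 200 mG) on the vertical axis; non-locomotive segments split
their amplitude equally between the fundamental and a 0.2 Hz component
(the filter removes the latter, driving the ratio to ≈ 1.27); sedentary
segments are 5 mG white noise (ACfil ≈ 7 mG); non-wear is exactly zero.
Worn segments carry a 1000 mG gravity offset and 5 mG noise. These are
*designed margins*, not gait biomechanics: passing classification tests
shows the decision logic and signal path are correct, not that the
device's equations are accurate on real human movement.

`gen_cohort()` draws anthropometry from sex-specific normals (women
74 ± 6 y, 149.4 ± 6.6 cm, 52.5 ± 9.8 kg; men 75 ± 5 y, 162.0 ± 4.8 cm,
62.7 ± 9.4 kg) truncated at ±3 SD and at physiological limits. Daily
schedules place a contiguous sleep/off block (wear ≈ 930 ± 60 min/day)
and fill wear time with a sedentary/light/MVPA mixture centred at about
63% / 32% / 5%, METs drawn uniformly within each band. A latent
per-participant activity propensity shifts the mixture and the typical
light-activity intensity, giving a predicted-PAL dispersion of ≈ 0.19 SD
— comparable to the ≈ 0.2 SD of measured PAL in older cohorts and chosen
once, at design time, so that the per-sex calibration fit is
well-conditioned at the study's sample sizes (47 women, 22 men). The
measured quantities are then generated from the declared truth: measured
PAL = slope × predicted PAL + intercept + N(0, resid SD) with defaults
0.949/0.205/0.20 (women) and 0.899/0.371/0.17 (men); measured BMR is the
Ganpule prediction with 7% CV multiplicative noise (typical
indirect-calorimetry repeatability); measured TEE = PAL × BMR exactly.

Not emulated: realistic gait or step counts (no step algorithm is
implemented), sleep-versus-device-removal distinctions, within-day
autocorrelation of behavior beyond the block schedule, seasonal or
day-of-week structure, and any misspecification of the linear
measured-versus-predicted relation. Parameter-recovery results therefore
demonstrate the estimator's correctness under the generating model, not
the realism of that model.

## Numerical conventions and problem sizes

All sub-streams of randomness derive from one top-level seed per
generator call; identical spec + seed reproduce cohorts and signals
bit-for-bit. The test suite exercises filter responses on 30–60 s
signals, scripted multi-segment schedules of ~2 h, cohorts of 5–69
participants over 1–14 days, 200 replicate cohorts of 47 women for the
OLS recovery check, and 1000 null replications for the t-test size check
— sizes chosen to give stable Monte-Carlo margins while keeping the whole
suite around a minute of compute. Degenerate inputs are defined rather
than left to chance: zero-variance predictors and sub-3 observation
groups are rejected with errors, constant paired differences yield
t = 0, p = 1, and an all-excluded cohort produces a report of zero
retained participants, not a failure.

## Known limitations

The correction equations are cohort-level affine maps: they repair the
aggregate PAL and TEE but cannot repair minute-level MET estimates, and
applied to a different population (different health status, age range, or
ethnicity) their error will exceed the development-sample residual SD.
The BMR component inherits the Ganpule equation's bias for older or
clinical populations. The wear rules (60/600/3) and the 0.9-MET
imputation are conventions taken from the device's ecosystem; alternative
non-wear algorithms (Choi, Troiano) are deliberately out of scope.
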