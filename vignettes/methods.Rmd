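---
title: "Methods: saccadic deviation and dwell-proportion measures of social preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saccadic deviation and dwell-proportion measures of social preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socgaze)
```

## Scope and model

`socgaze` analyzes two eye-tracking paradigms that separate *orienting
toward* social content from *engaging with* it.

In the **global-effect task**, a fixation cross jumps 6° left or right
along the horizontal meridian while a matched social/nonsocial image pair
flanks the target location above and below it.  Short-latency saccades in
such displays land toward the "center of gravity" of the configuration,
so the first saccade deviates toward whichever flanker captures attention.
The trial statistic is the signed angle between the saccade displacement
vector and the direct origin→target path, positive toward the social
image.  Averaged over trials and participants, a positive mean deviation
indicates that social content is more salient than matched nonsocial
content.

In the **freeview task**, a social and a nonsocial image (5.59° × 4.19°)
appear side by side for 5 s with no task.  The trial statistic is the
proportion of fixation dwell time on the social image,

$$p_\text{social} = \frac{T_\text{social}}{T_\text{social} + T_\text{nonsocial}},$$

with 0.5 meaning indifference.  Relative dwell time in two-alternative
displays tracks relative value, so this measure indexes the value of
social content.

Both tasks are run with intact and grid-scrambled versions of the same
image pairs; the scrambled condition controls for low-level image
properties.  Trait empathy (EQ) enters as an individual-differences
covariate at the cohort level.

Assumptions inherited from the recording setup: monocular 500 Hz sampling,
a single gaze channel, trial-relative timestamps with stimulus onset at
t = 0, coordinates in degrees of visual angle in a screen-centered frame
(+x rightward, +y upward).  Pixel-coded input is converted per axis with
the exact relation deg = atan(offset_mm / distance_mm).

## Event detection

Saccades are detected with the conventional dual criterion: a sample is a
saccade candidate when smoothed speed exceeds **22 °/s** or |acceleration|
exceeds **8000 °/s²**; a saccade runs until both fall back below
threshold.  The thresholds are the task's standard settings; the
differentiation scheme around them is our choice and is documented here
because it affects boundary placement:

- velocity components by central differences on position, speed smoothed
  with a 3-sample moving average (stabilizes the acceleration estimate,
  matching common EyeLink-style parsers);
- acceleration by central differences of smoothed speed;
- onset = first supra-threshold sample (velocity **or** acceleration);
  offset = last sample before both measures are sub-threshold.  The OR
  onset is the standard convention when the criteria are named jointly;
- two crossings separated by < 20 ms merge into one saccade (tie-break for
  noise-split events);
- samples within 20 ms of an invalid span are excluded from detection
  (blink-adjacent velocity artifacts), and events touching that margin are
  discarded;
- fixations are the maximal valid spans left over; spans shorter than
  **32 ms = 16 consecutive samples at 500 Hz** are dropped.  A fixation's
  duration includes one sample interval beyond offset − onset so that a
  16-sample span counts as exactly 32 ms, keeping the duration identity
  consistent with the sample-count rule.

Degenerate inputs: streams with fewer than 3 valid samples refuse
differentiation; an all-invalid stream parses as a single blink; a
zero-length saccade vector is an error in the deviation computation rather
than a silent 0.

## Trial and participant filters

- **Latency window**: trials whose first saccade starts before 70 ms or
  after 500 ms are excluded.  The boundaries are kept *inclusive* (70 and
  500 ms survive): the rule as stated excludes strictly "before" and
  "after".
- **First saccade** means the earliest saccade with onset ≥ 0 ms;
  anticipatory movements launched before stimulus onset are ignored for
  selection.  Saccades under 1° amplitude are ineligible (microsaccade
  guard; configurable).  The source procedure is silent here; without the
  floor, fixational microsaccades would occasionally win the "first"
  race and inject noise unrelated to target selection.
- **Capture rule**: a participant is dropped when usable gaze covers less
  than 75% of trials — per scramble condition in the global-effect task,
  and on scrambled trials in the freeview task, matching how the two
  tasks state the rule.  Exactly 75% is kept ("fewer than" is strict).
- **Freeview AOIs** are the exact image rectangles (zero padding,
  configurable).  Fixations are assigned by centroid, crediting full
  duration; a sample-level mode exists in spirit via the AOI test on any
  fixation table the user supplies.  Trials with no in-AOI fixation time
  contribute nothing (they are not counted as 0.5).  The initial central
  fixation is *included* by default (`drop_first = FALSE`): nothing in the
  procedure mandates discarding it, and because the center lies outside
  both AOIs it is inert anyway.

Every exclusion carries a machine-readable reason code, and the pipeline
report reconciles counts, percentages and per-participant averages against
the input totals.

## Statistics layer

All tests are two-tailed.  One-sample and paired t tests wrap
`stats::t.test()` and add Cohen's *d* computed with the sample SD (n − 1
denominator): d = (mean − mu0)/SD, so a cohort with mean 1.433 and SD
1.395 yields d = 1.027.  Pearson correlations wrap `stats::cor.test()`
and are computed on the complete-case subset when EQ is missing for some
participants, so printed dfs reflect the contributing n.

**Steiger's Z** compares two dependent correlations sharing one variable
(EQ–dwell for intact vs scrambled images).  We use the pooled-r
$\bar Z_1^*$ form: Fisher transforms of the two correlations, covariance
estimated at $\bar r = (r_{jk}+r_{jh})/2$ via
$\bar\psi = r_{kh}(1-2\bar r^2) - \tfrac12 \bar r^2 (1-2\bar r^2-r_{kh}^2)$,
$Z = (z_{jk}-z_{jh})\sqrt{(n-3)/(2-2\bar\psi/(1-\bar r^2)^2)}$.  The
source names the test but not the variant; the pooled form is the common
implementation, and its behavior is pinned by a dual-coded formula test
and a type-I calibration simulation (nominal 5% at n = 68).

**Cousineau within-subject error bars** re-center each participant
(value − participant mean + grand mean) before taking per-condition SEs.
No condition-count (Morey) correction is applied, since the method is used
as originally described; with two conditions the correction would scale
both SEs by a common √2 factor and is easy to apply downstream.

No multiple-testing correction is applied anywhere — the pipeline mirrors
the single-experiment reporting style — but the report states how many
tests it ran.

## Stimulus-matching metrics

Global RMS contrast is SD/mean of luminance, with the *population* SD so
the value depends only on the pixel distribution (a half-0.5/half-1.5
image gives exactly 0.5).  Local RMS contrast tiles the image with
non-overlapping windows (default 10% of the smaller dimension; the cited
computation does not fix a window) and averages per-window SD/mean; as the
window grows to the whole image it converges to the global value.  RGB
input is collapsed with Rec. 601 weights; the stimuli themselves were
presented in greyscale.  Grid scrambling permutes 10 px tiles uniformly
under a seed; edge tiles permute only among same-shape tiles so dimensions
are preserved and the pixel multiset is exactly invariant.  The matching
verdict for an image-pair parameter is a one-sample t test of the
social/nonsocial ratios against 1, "matched" when the 95% CI covers 1.

## Synthetic cohorts

The generator produces raw 500 Hz streams so that every pipeline stage —
parsing, detection, filtering, aggregation, inference — is exercised by
data whose ground truth is known.  Its defaults *are* the study
conditions: 40 trials per scramble condition, 6° eccentricity, 5 s
freeview trials, and cohort-level anchors taken from the quantities the
tasks are known to produce (mean deviation 1.433° intact / ≈0 scrambled;
dwell proportion 0.57 / 0.523; EQ–dwell correlation 0.278; ≈1.7% of
trials lost to the latency window).  Where a needed value is not stated
anywhere, we chose once what a practitioner would call realistic and did
not revisit it:

- **Kinematics**: minimum-jerk position profiles with a main-sequence
  duration (2.2 ms/deg + 21 ms), giving peak velocities well above
  threshold for amplitudes ≥ 1°.  The simulator is a test vehicle, not a
  kinematic claim.
- **Fixational noise**: low-pass drift (moving-average-filtered white
  noise, ~4 Hz bandwidth) at 0.05° RMS.  White sample-level noise would
  be unphysiological and would alias into the velocity trace.
- **Variance decomposition**: between-participant SDs are solved from the
  target cohort SDs minus the expected trial-noise contribution at 40
  trials — deviation: trial SD 4° ⇒ between-SD 1.24° (intact), 0.65°
  (scrambled); dwell: beta-distributed trial bias (κ = 50) plus
  duration-weighted fixation assignment ⇒ between-SD 0.088 / 0.038.
- **Latency**: truncated normal, mean 230 ms, SD 75 ms, bounds
  [10, 600] ms; the mass outside [70, 500] ms reproduces the ≈1.7%
  latency-exclusion rate.
- **EQ**: rounded 0–80 scores (mean 40, SD 12), 10% missing; the EQ–dwell
  link uses a Gaussian copula whose latent correlation is inflated by the
  analytically estimated trial-noise attenuation so the *pipeline-level*
  correlation hits the configured target.  The attenuation estimate
  assumes an effective count of ~12 duration-weighted fixations per trial;
  it is an approximation, so recovered correlations can sit a few percent
  from the target (inside the Monte-Carlo bands the tests use).
- **Blinks and dropout**: one 100 ms blink in 5% of trials (placed after
  the primary saccade in the global-effect task) and sporadic per-sample
  dropout at 5 × 10⁻⁵.

`simulate_cohort(raw_streams = FALSE)` draws per-trial statistics from the
identical statistical model without kinematics.  Many-replicate
calibration and recovery studies use this mode; single-cohort end-to-end
checks use raw streams.  The two modes are compared against each other in
the test suite.

What the generator does **not** emulate: smooth pursuit, saccadic
undershoot with corrective saccades, pupil-size artifacts, calibration
drift, head motion, or any dependence of fixation durations on image
content.  Passing recovery tests therefore shows the pipeline is unbiased
under its own generative assumptions, not that real data meet them.

## Problem sizes and numerical choices in the test suite

Recovery suites run at the study's sample sizes — 67 participants × 80
trials (deviation grid 0/0.5/1.5°) and 76 × 80 (dwell grid
0.3/0.5/0.57/0.7) with raw streams, 50–60 replicate cohorts of n = 68 in
summary mode for the correlation targets — with acceptance bands of
3 Monte-Carlo SEs.  Type-I calibration uses 2000 replicates (±1
percentage point).  Event-boundary equivalence is checked against a
brute-force per-sample scan on streams ≤ 200 samples.  These sizes keep
each suite to a few minutes while leaving the Monte-Carlo bands narrow
enough to catch percent-level bias.

## Known limitations

- The deviation sign convention assumes targets on the horizontal meridian
  with flankers above/below; other geometries would need a generalized
  "social side" test.
- Centroid-based AOI assignment ignores fixations straddling an AOI edge;
  with zero padding this is conservative.
- The ASC reader covers the plain-text sample dialect (samples, blink
  markers, messages), not binary EDF or binocular records.
- The pooled-r Steiger variant is asymptotic; at small n its type-I rate
  is only approximately nominal, which the calibration test bounds but
  does not remove.
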