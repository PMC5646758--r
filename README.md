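# socgaze

Eye-tracking measures of social salience and social value.

`socgaze` is an R package for researchers in behavioral and cognitive
neuroscience who study social reward processing with video eye tracking.
It implements, as a tested and reusable pipeline, the two complementary
paradigms used to dissociate *orienting toward* from *engaging with* social
stimuli:

- **Global effect (center-of-gravity) task** — a fixation cross jumps 6° of
  visual angle left or right while a vertical pair of matched images (one
  social, one nonsocial) flanks the target location.  The first saccade is
  "pulled" toward salient flankers; its signed angular deviation from the
  direct path indexes the *salience* of social content.
- **Preferential-looking (freeview) task** — a social and a nonsocial image
  (5.59° × 4.19°) are shown side by side for 5 s with no instructions.
  The proportion of dwell time on the social image indexes its relative
  *value*.

Both measures are computed from raw 500 Hz gaze streams and related to
trait empathy (Empathy Quotient, EQ) at the cohort level.

## The measures

For a trial with fixation origin **o**, saccade target **g**, and first
saccade with displacement vector **v** (start → end), the deviation angle
is

```
theta = angle(v, g - o)            # magnitude, degrees
deviation = |theta| * s,  s = +1 if the saccade endpoint lies on the
                               social image's side of the o→g line, else -1
```

Saccades are parsed from the stream with the standard velocity +
acceleration criteria (22°/s, 8000°/s²); trials whose first saccade starts
before 70 ms or after 500 ms are excluded, and participants with usable
gaze on fewer than 75% of trials in either scramble condition are dropped.

For a freeview trial, each fixation's full duration is credited to the
image rectangle containing its centroid, and

```
p_social = dwell_social / (dwell_social + dwell_nonsocial)
```

so `p_social = 0.5` means equal looking.  Fixations shorter than 32 ms
(16 consecutive samples at 500 Hz) are discarded and blinks are discounted.

The inferential layer provides two-tailed one-sample and paired t tests
with Cohen's *d*, Pearson correlations with EQ, Steiger's Z for comparing
two dependent correlations, and Cousineau within-subject error bars.
Stimulus-side utilities compute global and local RMS contrast, 10-pixel
grid scrambling, and the paired ratio test used to certify that social and
nonsocial image sets are matched.

Because raw gaze data for these paradigms are rarely shareable, the package
ships a synthetic-data generator (`simulate_cohort()`) that emits raw
500 Hz streams — fixational drift, minimum-jerk saccades, blinks, dropout —
with known ground-truth deviation bias, dwell proportion and EQ–dwell
correlation, so the entire pipeline is testable end to end.

## Worked example

```r
library(socgaze)

cfg    <- sim_config(n_participants = 16, trials_per_condition = 20, seed = 42)
cohort <- simulate_cohort(cfg)     # raw 500 Hz streams + ground truth
result <- run_pipeline(cohort)     # detection -> metrics -> exclusions -> stats
print(result)
```

```
== Global effect task (saccadic deviation toward social images) ==
included participants: 16
unscrambled vs 0 deg: mean = 1.607 (SD 1.498, SE 0.375), t(15) = 4.291, p = 0.0006438, d = 1.073
scrambled vs 0 deg: mean = 0.316 (SD 1.058, SE 0.265), t(15) = 1.195, p = 0.2506, d = 0.299
unscrambled - scrambled: mean = 1.291 (SD 1.954, SE 0.488), t(15) = 2.643, p = 0.01845, d = 0.661
Cousineau within-subject SE: unscrambled 0.2442, scrambled 0.2442
EQ correlation (unscrambled): r(13) = -0.179, p = 0.5227
EQ correlation (scrambled): r(13) = 0.248, p = 0.3728
== Freeview task (social dwell proportion) ==
included participants: 16
unscrambled vs 0.5: mean = 0.562 (SD 0.126, SE 0.031), t(15) = 1.960, p = 0.06884, d = 0.490
scrambled vs 0.5: mean = 0.514 (SD 0.052, SE 0.013), t(15) = 1.079, p = 0.2975, d = 0.270
unscrambled - scrambled: mean = 0.047 (SD 0.134, SE 0.033), t(15) = 1.418, p = 0.1765, d = 0.355
Cousineau within-subject SE: unscrambled 0.0167, scrambled 0.0167
EQ correlation (unscrambled): r(13) = 0.252, p = 0.3646
EQ correlation (scrambled): r(13) = 0.119, p = 0.6724
Steiger's Z (EQ-dwell, unscrambled vs scrambled): Z = 0.352, p = 0.725
== Exclusion audit ==
trials excluded: 10 (0.781%), mean 0.625 per participant
participants excluded: 0
  latency: 9
  no_saccade: 1
tests run (no multiplicity correction applied): 11
```

Reading the output: the simulated cohort has a positive deviation bias for
intact (unscrambled) social images (mean 1.607°, reliably above 0) but not
for their scrambled controls — the signature dissociation of social
salience from low-level image properties.  The freeview dwell proportion
sits above 0.5 for intact images.  At 16 participants the EQ correlations
are dominated by sampling noise, as the wide CIs and p values show; the
exclusion audit accounts for every removed trial.

Data ingestion from files is available via `read_gaze_csv()` (tabular
samples, degree- or pixel-coded), `read_gaze_asc()` (EyeLink-ASC-like
text), and `read_cohort()` (a manifest-based dataset directory);
`screen_geometry()` handles exact pixel ↔ degree conversion.  A thin
command-line wrapper (`inst/scripts/socgaze`) exposes `simulate`, `run`
and `stimmatch` subcommands over the same functions.

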