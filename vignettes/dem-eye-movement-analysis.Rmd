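---
title: "Analysing eye movements during the digital DEM test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing eye movements during the digital DEM test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculodem)
```

## The problem

The Developmental Eye Movement (DEM) test is a timed visual-verbal
number-naming task used clinically to screen children for oculomotor
dysfunction. The child first reads two vertical columns of 20 numbers each
(subtests A and B; vertical time = A + B) and then a two-dimensional array
of 16 rows of five numbers (subtest C; horizontal time). The ratio of
horizontal to vertical time is interpreted as an oculomotor index: the
vertical subtest is assumed to isolate automatic naming, the horizontal
subtest to add a saccadic load. Whether the ratio really reflects
oculomotor skill can only be settled by recording eye movements while the
test is performed — which is what this package's pipeline analyses.

`oculodem` implements the full analysis chain for such recordings:

1. **Stimulus geometry** — the digital DEM layout (positions in mm and
   degrees), plus the photometric/angular conversions (Michelson contrast,
   logMAR).
2. **Signal preprocessing** — irregular monocular gaze streams are
   median-prefiltered, resampled to 500 Hz, low-pass filtered with a
   zero-phase Butterworth, and differentiated with a noise-robust kernel.
3. **Event detection** — saccades from adaptive MAD-based velocity and
   acceleration thresholds with a pre/post position verification;
   fixations as the inter-saccadic intervals, with MAD-based duration
   outlier flagging.
4. **Epoch segmentation** — each recording is split into
   *number-identification* epochs (reading along a line) and *return-sweep*
   epochs (travelling from a line's end to the next line's start), with
   per-epoch oculomotor metrics.
5. **Scoring** — DEM times (error-adjusted horizontal time, ratio, naming
   percentage, the half-record duplication rule) and reaction-time cleaning
   for speed-acuity and detection tasks.
6. **Statistics** — Pearson and age-partialled correlations, paired t
   tests, Williams' test for dependent overlapping correlations, BH-FDR,
   and power/sample-size routines.
7. **Synthetic data** — a generator that emits gaze recordings and
   reaction-time tables with known ground truth, so that every stage is
   testable without access to a child cohort.

## Preprocessing model and assumptions

Raw input is an irregularly sampled stream (timestamp, horizontal and
vertical gaze angle in degrees, validity flag) from one eye — the eye with
the larger fraction of valid samples (`select_best_eye()`, ties to the
right eye). The chain is fixed: **13-sample running median → linear
resampling to 500 Hz → zero-phase 5th-order Butterworth, 40 Hz cutoff →
9-point noise-robust differentiation**.

Numerical choices worth knowing:

* The median prefilter runs over the *sample index* of the irregular
  stream, not over a time window; at ~500 Hz a 13-sample window spans
  ~26 ms. Whether the original analysis filtered in samples or time is
  unobservable at this scale; we chose the literal sample window.
* Gaps between valid samples longer than 75 ms (default
  `max_bridgeable_gap_ms`) are *not* interpolated; the recording is
  segmented there. Blinks last roughly 100–300 ms, and bridging them
  linearly would fabricate smooth gaze where none was measured. The
  fixation-duration outlier rule later absorbs blink-adjacent artifacts.
* Zero-phase filtering runs forward and backward per contiguous valid
  segment with ~100 samples of reflective padding; two passes put the
  cutoff attenuation at −6 dB (amplitude ×0.5 at 40 Hz) with zero net
  phase. Segments shorter than three filter orders are left unfiltered
  with a warning.
* The differentiator is the 9-tap smooth noise-robust central kernel
  (antisymmetric taps `(14, 14, 6, 1)/128`), exact for constant and linear
  signals; the outermost four samples of each segment fall back to
  one-sided first differences. On white noise its output standard
  deviation is about a third of the 2-point central difference's.
* Track velocity is the vector norm `sqrt(vx^2 + vy^2)`; track
  acceleration is its time derivative — the quantity thresholds operate
  on.

## Saccade detection

Thresholds adapt to each recording's noise: on the rectified track
velocity (and acceleration) series, a provisional threshold is placed
3 × MAD above the median; samples below it are treated as noise, and the
final threshold is the median + 3 × MAD of those noise samples. The MAD
is unscaled throughout (no 1.4826 normal-consistency factor) — the rule is
"3 MADs from the median", not "3 robust standard deviations". Anchoring
the deviation at the median matters because rectified track velocity is
non-negative and right-skewed (Rayleigh-like under Gaussian component
noise): a bare 3 × MAD value would land *inside* the noise bulk. The
velocity threshold is clamped to [10, 100] deg/s to guard degenerate
traces; on default synthetic noise it sits in the tens of deg/s.

A candidate saccade opens where track velocity crosses its threshold
upward with the acceleration threshold exceeded somewhere in the preceding
20 ms (the acceleration criterion gates onsets only — at offsets the
acceleration is noise-dominated), and closes where velocity falls back
below threshold. Candidates closer than 20 ms are merged (replacing the
original study's manual inspection step with a deterministic rule), and
candidates shorter than 6 ms are dropped. Each survivor must pass a
position verification: the mean gaze position in the 20 ms before onset
must differ from the mean in the 20 ms after offset by more than 3 × the
pooled within-window position MAD. No statistical test is named in the
source description of this check; the displacement rule is our scale-free
operationalisation and is flagged as such.

Saccades with a direction strictly within 45° of the horizontal meridian
(either side) are horizontal; all others — including a direction at
exactly 45° — are vertical. Fixations are the inter-saccadic intervals
(plus each segment's leading and trailing intervals); together with the
saccades they tile every valid segment exactly, which the tests assert to
numerical precision. Fixations whose duration exceeds the recording's
median + 3 × MAD are flagged as outliers (typically blink bridges): they
keep contributing to epoch *time* but are excluded from duration
*statistics*, so time conservation stays exact.

## Epoch segmentation

The source definitions of the two epoch kinds are verbal — gaze "arriving
at the beginning of a line" and "starting to move towards the beginning of
another line" — so the quantification is ours, and all parameters sit in
`segmentation_config()`:

* **Line arrivals** are detected from displacement between consecutive
  fixations: a leftward jump of at least half the row extent (the sweep
  trigger fraction, default 0.5) marks a line transition, and the arrival
  is the fixation that settles within 2° of the leftmost column.
  Corrective hops still closing in on the line start supersede the
  arrival; a near-line-start hop followed by further leftward movement is
  not yet an arrival. Detection is deliberately *relative* (jump sizes,
  not absolute row positions), because slow calibration drift of the
  magnitude real trackers exhibit (~0.7°) exceeds half the angular row
  spacing (0.64°) and would defeat absolute row matching.
* **Sweep start** is the onset of the first leftward saccade of at least
  the trigger amplitude after the gaze has entered the final-position
  region of the current row. When that saccade is unobservable — a blink
  can swallow an entire sweep — the sweep starts at the end of the last
  fixation on the origin line, so segmentation degrades gracefully instead
  of losing the line.
* **Sweep end** is the start of the arrival fixation; saccades straddling
  an epoch boundary belong to the sweep they initiate (epoch membership is
  by onset). Everything between a sweep's end and the next sweep's start
  is that line's identification epoch, so epochs are contiguous,
  non-overlapping, and tile the interval from the first to the last number
  fixation.
* Subtests A/B run the same logic mirrored: one rightward-and-up sweep
  from the bottom of column 1 to the top of column 2, two identification
  epochs.

Row labels for fixations (`assign_rows()`) use the nearest row centre
within half the row spacing; fixations outside every tolerance stay
unlabeled and are simply not counted in row-conditioned metrics. An
errorless reading of subtest C therefore yields exactly 16 identification
epochs and 15 return sweeps; of subtest A or B, 2 and 1.

Per-epoch metrics: duration, fixation time, saccade time, counts, median
fixation duration (outliers excluded), median saccade amplitude, backwards
saccades (horizontal-class leftward during C identification;
vertical-class upward during A/B identification) and orthogonal saccades
(vertical-class during C identification; horizontal-class during A/B).

## Scoring

Horizontal (C) time is error-adjusted as
`raw x 80 / (80 - omissions + additions)`; A and B times are never
adjusted. Naming responses are aligned to the 80-number target sequence by
a longest-common-subsequence alignment; a fully repeated line counts five
addition errors and a fully skipped line counts **two** omission errors.
The two-omission weight for a five-number line is implemented as printed
in the scoring convention this package follows, and is exposed as
`skip_line_omissions` for users who prefer a per-number count. The DEM
ratio is adjusted C / vertical time and the naming percentage is
vertical / adjusted C × 100, both computed from the *adjusted* horizontal
time. When only one vertical subtest has usable data its time (and its
oculomotor summaries, when requested) is duplicated and the record
flagged `A-only`/`B-only`.

Reaction-time cleaning: trials under 0.1 s are discarded, then trials more
than 3 × MAD from the subject/task median. The MAD rule is applied to a
fixed point, which makes cleaning a projection — re-cleaning a cleaned
table changes nothing — without altering first-pass behaviour on typical
data. Subjects whose mean deviates more than 3 group standard deviations
from the group mean are flagged excluded; with an all-equal trial set the
MAD is zero and the strict inequality keeps every trial.

## Statistics

`pearson()` and `partial_corr()` use the t transform with n − 2 and n − 3
degrees of freedom; the partial correlation is validated in the tests
against an explicit residual-regression oracle to 1e-10.
`compare_dependent_correlations()` implements Williams' t (Steiger's
procedure) for two overlapping correlations sharing a variable; no method
is named in the source analyses, and Williams' t is the standard choice
for this design. Its type-I error under a seeded trivariate-normal null
(2000 replicates, n = 30) measures 0.043. `bh_fdr()` wraps the
Benjamini–Hochberg step-up with an explicit rejection set.

`required_n_paired_t()` searches the smallest n whose noncentral-t power
(df = n − 1, noncentrality dz·√n) reaches the target; for dz = 0.5,
α = 0.05, power 0.80 the one-sided answer is 27 and the two-sided 34.
Sidedness is always explicit: the printed sample size this package
reproduces is consistent with a one-sided test, so that is the default,
and the record carries the setting. `required_n_correlation()` offers an
exact mode — numerical integration of the sampling density of r under a
bivariate normal population, with the critical r from the null t
transform — and a labelled Fisher-z approximation. The exact one-sided
answer for ρ = 0.5 at power 0.80 is 23 (Fisher-z: 24), validated against
a Monte-Carlo oracle before being pinned in the tests.

## The synthetic cohort generator

No gaze recordings are distributed with the study this pipeline targets,
so `simulate_trial()` / `simulate_cohort()` generate them with full ground
truth. The generator's central latent variable is a reader's processing
speed *s*, the median identification fixation duration in ms, log-linearly
decreasing with age (median 550 ms at age 6, −5.5 %/year, 0.12 lognormal
between-subject sd — scales chosen to put cohort fixation durations and
completion times in the range school-age readers produce). Everything
slow readers do more of is coupled to *s*: extra refixations, regressions,
and splitting the return sweep into 1–3 hops (a large undershooting
saccade covering 65–85 % of the distance plus corrective hops, the pattern
developing readers actually show) with ~250 ms intermittent fixations.

Saccades follow a duration main sequence (21 ms + 2.2 ms/deg, standard
literature values) with raised-cosine velocity profiles — smooth,
closed-form displacement, trivially integrable, which keeps the ground
truth exact. Measurement imperfections are applied last: two asynchronous
~250 Hz camera clocks with 10 % timestamp jitter merging to an irregular
~500 Hz stream; white noise of 0.03° (below the 0.05° the emulated
tracker specifies); a slow sinusoidal bias of up to 0.7° per axis
(20–40 s period) emulating the tracker's limited spatial accuracy; and
Poisson blink dropouts (2/min, 100–300 ms). Reaction-time tables couple
the subject's mean speed-acuity RT to *s* with γ = 1.2 ms RT per ms of
fixation duration plus between-subject and trial noise, and the visual and
auditory detection tasks share the same latent with smaller loadings.

What the generator does *not* emulate: cognitive naming processes and
crowding, pupil-size artifacts, head-motion-induced error beyond the slow
bias, vergence, and any fitting of the generator's distributions to the
study cohort's real data. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes — event timing, epoch counts,
correlation signs — not that the generator statistically matches real
children.

Distributional families are assumptions, config-exposed: lognormal
fixation durations (`fix_sdlog`), the age→s link linear on log s.

## Problem sizes and determinism

All randomness flows from explicit integer seeds; identical seeds give
byte-identical streams. The test suite exercises one errorless C trial
end to end, stress batches of error-prone trials, and a 36-subject cohort
(the eye-tracked subsample size of the emulated study) analysed through
the full pipeline — about half a minute of compute in total, memoized
across test files. The parameter-recovery check regresses the measured
median identification fixation duration on the true *s* across that
cohort (slope within 10 % of unity); the sign-structure check requires
negative age–time correlations, a positive fixation-duration–RT
correlation surviving FDR, and positive saccade-count–time correlations,
mirroring the qualitative pattern of the emulated analyses.

## Known limitations

* Epoch boundaries depend on config tolerances (2° line-start tolerance,
  0.5 trigger fraction); pathological reading styles (re-reading whole
  lines, skipping to arbitrary rows) are segmented by the same rules but
  were only validated for skips the generator can produce.
* The verification step's "significantly different" pre/post windows are a
  displacement heuristic, not an inferential test.
* Recordings with more than 10 % invalid samples should be treated as
  lost-signal (`max_invalid_fraction`); the exclusion threshold used in
  the original cohort is not quantified anywhere, so no fidelity is
  claimed.
* `count_errors()` scores substitutions (wrong digit at a matched
  position) as neither omission nor addition, because the adjustment
  formula has only those two terms.

## A worked example

```{r example, eval = FALSE}
library(oculodem)

layout <- build_layout("C")
trial <- simulate_trial(reader_profile(age = 10), layout, noise_model(),
                        seed = 42, errorless = TRUE)
sig <- preprocess_gaze(trial$stream)
saccades <- detect_saccades(sig)
fixations <- assign_rows(parse_fixations(saccades, sig), layout)
epochs <- segment_epochs(saccades, fixations, layout)
table(epochs$kind)
#> identification   return_sweep
#>             16             15

met <- epoch_metrics(epochs, saccades, fixations)
met$summary[, c("kind", "total_time", "fixation_time", "saccade_time")]
```

The cohort-level run is a single call:

```{r cohort, eval = FALSE}
cohort <- simulate_cohort(36, seed = 2026)
analysis <- analyse_cohort(cohort)
stats_report(analysis$measures)
```
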