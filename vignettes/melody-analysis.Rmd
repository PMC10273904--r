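---
title: "Melody arcs, segmentation and complexity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melody arcs, segmentation and complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melodyarc)
```

## The problem

Infants organise their vocal output around melody — the time course of the
fundamental frequency (f0) during one expiration. Over the first year, simple
melodies consisting of a single ascending-then-descending f0 arc give way to
complex ones: concatenations of several arcs, and melodies rhythmically broken
by laryngeal constrictions. `melodyarc` implements this analysis as a tested
pipeline: it classifies each vocalization's melody as single-arc (SA),
double-arc (DA), triple-arc (TA), multiple-arc (MA, four or more) or
segmented (SEG), aggregates developmental profiles by age and vocalization
type, and models binary melody complexity (0 = SA, 1 = anything else) with a
mixed-effects logistic regression.

Because infant recording archives are generally not shareable, the package
ships a synthetic-corpus generator that renders f0 contours with known ground
truth. Every downstream stage is validated against those plantings; what that
does and does not demonstrate about real recordings is discussed at the end.

## Preprocessing

**Semitone scale.** All melody measurements are musical: f0 is converted to
semitones, `st = 12 log2(f / f_ref)`, so that equal pitch intervals are equal
distances. FM amplitudes are semitone *differences*, hence the reference
frequency (default 440 Hz) cancels in every criterion; it matters only for
display. A quarter-tone (0.5 st) grid is available for plotting and export
(`quantize_quartertone()`), but quantization is never applied before
thresholding — the 1.0/1.5/2.0 st criteria would otherwise become
grid-dependent.

**Uniform grid.** Input tracks arrive at whatever rate the pitch tracker
produced (PRAAT PitchTiers store voiced points only; the CSV dialect carries
an explicit voicing column). The pipeline interpolates the semitone contour
linearly onto a uniform 200 Hz grid (5 ms hop). 200 Hz keeps the 40 Hz filter
cutoff far below the Nyquist rate while representing the modulation noise the
filter must remove. Interpolation is strictly run-local: unvoiced dropouts up
to `gap_bridge_ms` (default 20 ms — sub-perceptual dropouts are tracker
artifacts, not constrictions) are bridged; anything longer splits the contour
into separate voiced runs. One rule covers both input formats: consecutive
voiced samples are split when their spacing exceeds 1.5x the median spacing
*and* the estimated silent stretch exceeds the bridge length.

**Gaussian low-pass.** The semitone contour of each voiced run is smoothed
with a Gaussian filter with cutoff "about 40 Hz" to remove high-frequency
modulation noise and artifacts. Two conventions had to be fixed:

* *Cutoff convention*: the -3 dB point. The frequency-domain gain is
  `exp(-f^2 / (2 sigma_f^2))` with `sigma_f = cutoff / sqrt(ln 2)`
  (equivalently a time-domain Gaussian kernel with
  `sigma_t = 1 / (2 pi sigma_f)`, about 3.3 ms at 40 Hz).
* *Filter space*: semitones, the space in which arcs are measured.

The filter is applied in the frequency domain (reflection-padded FFT
multiplied by the exact transfer function), so its gain matches the
closed-form expression at any represented frequency; with `sigma_t` under one
sample at 200 Hz, a sampled time-domain kernel would deviate from the
continuous response by several percent. Runs are filtered independently —
voiced-run boundaries never mix.

## Inclusion filter

Melody analysis requires a melody that can unfold and be tracked:

* **too_short** — total *voiced* duration of at most 300 ms (inclusive
  bound). Note the deliberate asymmetry with the arc criterion below: a
  vocalization of exactly 300 ms is excluded, while an arc must last
  *strictly more* than 300 ms.
* **no_pattern** — a manual flag (for phonatory noise/chaotic episodes judged
  on spectrograms, which an f0 track cannot reveal), or an automatic flag for
  sudden f0 shifts: a sample-to-sample step beyond `max_jump_st` (default 6
  st) within a voiced run. Octave jumps, the archetypal tracking failure, are
  12 st. Steps across unvoiced gaps carry no continuity expectation and are
  ignored.

## Arc decomposition

Arcs are defined by two criteria: duration strictly greater than 300 ms, and
a minimum FM amplitude that depends on the vocalization type — 2 st for cry
(C), 1.5 st for early non-cry (NC), 1 st for marginal and canonical babbling
(BM, BC) — reflecting the decreasing modulation depth from crying toward
babbling. FM amplitude is anchored as *peak minus the higher flanking
minimum*: the stricter of the two drops, so both the rise and the fall reach
criterion depth.

The decomposition works on the alternating minimum/maximum sequence of each
smoothed run:

1. **Extrema.** Turning points are located per run; plateaus of equal values
   collapse to their midpoint; the sequence is anchored at the run boundary
   samples. Extremum pairs spanning less than a prominence floor (0.25 st,
   half the smallest FM criterion) are cancelled smallest-first so grid noise
   cannot seed candidates.
2. **FM criterion.** A candidate arc is a min-max-min triplet. The condition
   `peak - max(flanks) >= min_fm` is equivalent to *every adjacent extremum
   pair spanning at least `min_fm`*, so sub-threshold candidates are removed
   by the same smallest-pair-first cancellation, now at the FM threshold.
   This reduction has the property one wants from merging: a 0.5 st ripple
   riding on a large arc disappears into it, while a deep inter-arc junction
   minimum is never consumed by an adjacent noise ripple. (The alternative of
   always cancelling toward the *lower* flanking minimum lets each ripple
   delete a true junction; junctions then ratchet upward until neighbouring
   arcs merge — on synthetic corpora at default noise this cost roughly one
   in seven double-arc melodies. The smallest-pair rule was adopted for this
   reason.)
3. **Duration criterion.** Any surviving candidate lasting 300 ms or less is
   merged by cancelling its peak with the higher flanking minimum, and step 2
   is re-run, to a fixpoint.
4. **Plateau.** A run longer than 300 ms whose total range stays below the FM
   criterion is the flat-melody prototype: it yields one plateau arc.

Accepted arcs are labelled by relative peak position
`r = (t_peak - t_start) / duration`: left-accentuated (`r < 0.4`), symmetric,
or right-accentuated (`r > 0.6`); plateau is the fourth prototype.

A degenerate case: an included vocalization can end up with zero accepted
arcs and no plateau (e.g. a monotone run with a large range). The five
categories must partition included vocalizations, so such contours are
classified SA; at default settings this arises only for borderline inputs.

## Segmentation events

Melodies containing at least one laryngeal constriction are segmented (SEG),
*independent of arc count* — SEG takes precedence over the arc-count
categories.

* **Complete constrictions** interrupt phonation: every internal unvoiced gap
  longer than the bridge length and at most `max_pause_ms` (default 250 ms)
  is one event. A single-expiration vocalization cannot contain long silence,
  so longer gaps are flagged for review (suspected upstream segmentation
  error) rather than counted.
* **Incomplete constrictions** leave phonation running but creaky. True creak
  identification is audio-visual; on an f0 track the package uses a declared
  proxy: the rolling median (50 ms window) of the absolute *second*
  difference of the semitone track, computed on the raw *pre-smoothing*
  samples, compared against 5x the vocalization's overall median with an
  absolute floor of 0.5 st. The second difference is the crucial choice: a
  first-difference score confounds steep-but-smooth melody slopes with
  irregularity (a fast 8 st rise moves ~0.2 st per 5 ms step and can clear a
  median-relative threshold), whereas curvature per step stays below ~0.15 st
  for any smooth arc and reaches several semitones for alternating
  creak-like jitter. Stretches of at least 50 ms above threshold are events.
  The manual no-pattern channel can override the proxy in both directions.

## Synthetic corpus

The generator (`generate_corpus()`) renders a corpus whose design mirrors the
reference study: 9,237 included vocalizations distributed over 10 infants and
months 1--12 by a fixed per-cell count table, plus 1,751 planted-excluded
records; ground-truth categories mixed at 39/21/7/3/30 percent
(SA/DA/TA/MA/SEG); cry:non-cry at 1,141:4,667 within months 1--6 and
marginal:canonical babbling at 2,754:675 within months 7--12. Choices that
the source design leaves open, fixed here once:

* **Deterministic apportionment.** Categories, types and exclusions are
  apportioned by the largest-remainder rule per infant-month cell, not drawn
  multinomially, so ground-truth shares equal the configured mixture up to
  integer rounding and changing the seed changes contours but never a count.
* **Exclusion split.** The division of the 1,751 excluded records between
  too-short and no-pattern is unpublished; the default is 50/50
  (`too_short_frac`). No downstream result depends on the split, only on the
  total.
* **Contour shapes.** Arcs are piecewise raised cosines (peak at 25/50/75% of
  duration for the left-accentuated/symmetric/right-accentuated prototypes),
  0.35--1.2 s long, with per-type FM ranges C 2--8, NC 1.5--6, BM/BC 1--5 st
  and baseline registers of roughly 250--500 Hz. The plateau prototype
  (flat, 0.3 st drift) is drawn only for single-arc melodies — a flat
  *segment* inside a multi-arc melody would not satisfy the arc criteria and
  would falsify the planted arc count. Real FM and duration distributions are
  unpublished; these ranges are declared assumptions.
* **Noise.** Per-sample Gaussian jitter (sd 0.1 st) and sinusoidal tremor
  (70 Hz, 0.3 st) — deliberately above the 40 Hz cutoff, so the filter's
  stated purpose is exercised: classification of a clean contour and its
  noisy twin must agree.
* **Plantings.** Complete pauses are 40--200 ms unvoiced gaps inserted
  *between* arcs (extending the timeline, so flanking arcs keep their
  duration); creak is 60--100 ms of alternating ±1.5 st added at an arc
  junction; too-short contours are 150--280 ms single arcs; no-pattern
  contours carry a 100 ms *downward* octave jump — downward so the planted
  track stays inside the loader's plausibility range (50--1200 Hz) even at
  high registers.

What the generator does **not** emulate: voice quality, formants, amplitude,
subharmonics and genuine chaotic episodes, tracker octave errors beyond the
planted jump, or any dependence of melody structure on age and type (the
mixture is constant across cells). Passing the recovery tests therefore shows
that the pipeline implements the stated criteria faithfully and robustly to
the modelled noise — not that it would reproduce a human rater's judgements
on real audio.

## Statistics

`build_profiles()` tabulates per-(month x type) category shares among
included vocalizations, the layout used by developmental diagrams.
`fit_complexity_glmm()` fits `complexity ~ age_months + voc_type +
(1 | infant_id)` with a logit link via `lme4::glmer` (Laplace approximation),
with reference-cell coding (C is the reference in months 1--6, BM in months
7--12); the two age strata are fitted separately
(`fit_complexity_models()`), never pooled. Records excluded upstream never
enter a model. A single-infant data set is an error (the random intercept is
unidentifiable), and non-convergence is reported in the result
(`converged = FALSE`) rather than silently worked around. The estimation
contract is parameter recovery on simulated outcomes
(`simulate_complexity_outcomes()`): a planted age effect of 0.3 with 10
infants x 500 observations and random-intercept sd 0.5 is recovered within
±0.15, and the Wald test holds its nominal 5% type-I error on planted nulls.
AIC values from archive data depend on that data and are not reproducible
from synthetic corpora; AIC is reported for model comparison within a fit.

## Numerical choices

* Comparisons against the printed 300 ms bounds use a 1e-9 s slack: 0.300 s
  built on a 5 ms grid is not exactly representable in binary, and the
  inclusive (vocalization ≤ 300 ms) versus strict (arc > 300 ms) senses must
  survive rounding.
* Ties: quarter-tone quantization rounds ties away from zero; apportionment
  breaks remainder ties by category order; equal flanking minima merge
  rightward.
* The FM measurement of an accepted arc is taken from the smoothed contour,
  so a planted amplitude sitting exactly on a criterion can measure a few
  thousandths of a semitone away; exact-boundary behaviour is asserted on
  unsmoothed tracks where construction is exact.

## Problem sizes used in the test suite

The packaged checks run the full 10,988-vocalization default corpus once for
the composition and filter-count checks (a few minutes), an 18-point
(K arcs x S pauses) noise-free grid replicated to ~500 cases for oracle
equivalence, 1,000 clean/tremor contour pairs for filter invariance, and
20 + 200 simulation replicates for coefficient recovery and type-I
calibration. Unit tests use corpora scaled down by one to two orders of
magnitude.

## Limitations

The incomplete-constriction detector is a proxy; its agreement with
perceptual creak labelling on real recordings is unknown. The inclusion
filter's automatic no-pattern flag only sees f0 — phonatory noise visible in
a spectrogram but not in the track must come through the manual flag. The
arc criteria are threshold rules; melodies hovering at a criterion boundary
are assigned, not flagged as uncertain. And all quantitative guarantees in
the test suite are statements about the synthetic corpus design described
above.
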