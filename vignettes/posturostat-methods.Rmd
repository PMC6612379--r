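---
title: "Methods: weight-distribution indices and multiple-response association tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weight-distribution indices and multiple-response association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturostat)
```

## The measurement problem

A subject stands barefoot on a resistive pressure platform — a grid of
sensing elements sampled at 50 Hz — while holding one of four occlusal
conditions: mandibular rest with no tooth contact (`RES`), a bilateral
clench at maximum intercuspation (`CL`), and unilateral clenches on the
right (`CLR`) and left (`CLL`) with a leaf gauge creating 1 mm of
disocclusion on the opposite side. The question is whether clenching and
occlusal instability displace the standing load laterally or
anteroposteriorly relative to rest.

`posturostat` implements the full chain from raw sensor frames to the
inferential statistics: recording I/O, foot segmentation, the
weight-distribution indices, categorical shift classification, the
modified and corrected chi-squared test for multiple-response tables, and
correspondence analysis of significant associations.

## Indices

Let `left%` be the percentage of total load carried by the left foot on
the time-averaged frame, and `post%` the posterior share of one foot's own
load. The two indices are

- **OLWD** (overall lateral weight distribution) `= 50 − left%`:
  zero when balanced, positive for a rightward shift, negative leftward;
- **APWD** (anteroposterior weight distribution, one per foot)
  `= 50 − post%`: positive anterior, negative posterior.

Both are bounded by ±50. Three normalisation choices deserve making
explicit, because the index definitions do not fix them:

- *APWD is per foot.* The posterior percentage is taken of that foot's own
  load, not of total body load. Only this reading makes APWD zero for any
  anteroposteriorly balanced foot regardless of the lateral split, which
  the zero convention requires.
- *Time aggregation is the arithmetic mean* over all frames (the indices
  are therefore invariant to frame order); a median alternative is exposed
  via `aggregate = "median"` for heavy-tailed artefacts.
- *The anterior/posterior boundary* of each foot is the midpoint row of its
  occupied row span, with row 1 the anterior (toe) edge. The mat's column 1
  is the subject's left.

Segmentation (`segment_feet()`) thresholds the mean frame at a small
fraction of its maximum, labels connected components
(`EBImage::bwlabel`), keeps the two heaviest, and assigns left/right by
load-weighted column centroid; a single component spanning the midline is
split at the midline, and anything less is a segmentation error rather
than a guess.

## Shift classification

Each clenching condition is compared with the same subject's rest
recording: `Δ = index(condition) − index(rest)`. Since a continuous index
never reproduces exactly, a tolerance `ε` (default 0.5 percentage points,
closed band: `|Δ| ≤ ε`) defines "no change"; beyond it the sign gives the
direction (right/left laterally, anterior/posterior per foot). The
tolerance is deliberately small — half a point on indices that move by
several points under real effects — and is exposed everywhere
(`epsilon_pp`). Growing `ε` can only move subjects *into* the no-change
category, and negating all differences swaps the directional labels;
both properties are tested.

The labels populate shift-by-condition tables: 3×3 for the lateral
analysis (columns `CL`, `CLR`, `CLL`) and 3×6 for the per-foot AP analysis
(columns `CL-LF` … `CLL-RF`). Because every subject contributes exactly
one response per column, all column sums equal the number of subjects,
and the same subject recurs across columns.

## The modified and corrected chi-squared test

The classical Pearson test is invalid on such tables for two reasons: the
marginal grand total (`n` subjects × `c` columns) inflates the expected
counts, and responses from the same subject are correlated across
columns. Following the approach of Decady and Thomas for multiple-response
tables, the package computes:

- `χ²ₘ`: the Pearson form on the marginal table, expected cell
  `(i, j) = rowᵢ·colⱼ/grand total`, referred to `r(c−1)` degrees of
  freedom (for one-of-`r` responses in each of `c` columns there are
  `r−1` free proportions per column under the marginal-homogeneity null);
- `δ = (r−1)/r`: the first-order design correction for the exactly-one-of-`r`
  response constraint — with three shift categories `δ = 2/3` whatever the
  number of columns;
- `χ²c = χ²ₘ/δ`, compared with the chi-squared law at the same `r(c−1)`
  degrees of freedom.

Since `δ < 1` the correction strictly inflates the statistic. The general
Rao–Scott-type estimator of `δ` from subject-level response covariances is
out of scope: the closed form is exact for the one-of-`r` design used
here, and no subject-level data beyond the marginal tables is required.
A simulation in the test suite confirms the corrected test holds its
nominal level under a zero-effect null (see below).

Display tables mirror the usual crosstabulation format: within-condition
percentages at one decimal place, rounded half-up, with a row-margin
`Total` column.

## Correspondence analysis

For tables whose corrected test is significant at `α` (the map depicts an
established association; it is not itself a test), `run_pipeline()` fits a
correspondence analysis: with correspondence matrix `P = N/n`, row and
column masses `r`, `c`, the standardized residuals
`S = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}` are decomposed by SVD, and both row
and column categories are displayed in principal coordinates (the
symmetric, French-school map). Axis inertias are the squared singular
values; their sum times the grand total equals `χ²ₘ` exactly, an identity
the tests enforce to 1e−9. Because an SVD's singular-vector signs are
arbitrary, each axis is canonically oriented so that the column point with
the largest mass-weighted coordinate magnitude is positive; all
association statements (which categories share a side of an axis) are
invariant to this convention.

## The synthetic generator

No instrument data ships with the package; `generate_recording()` and
`generate_cohort()` stand in for the platform.

- **Feet** are elliptical Gaussian-weighted blobs with finite support
  (exactly zero outside the ellipse), separated by an empty column band,
  so segmentation is unambiguous and recovers the generator's own masks.
  The default grid is 52 × 44 = 2288 sensors, the longer mat axis along
  the rows.
- **Effects are exact by construction.** A lateral shift of `s` percentage
  points rescales the two feet's total weights (not their positions), so
  the measured OLWD changes by exactly `s` in the noiseless limit; AP
  shifts rescale each foot's anterior versus posterior half about the same
  boundary row the analysis uses. Mirroring a map left↔right therefore
  negates OLWD and swaps the per-foot APWDs.
- **Noise is multiplicative log-normal** per sensor per frame with mean 1,
  preserving non-negativity and total-load conservation in expectation;
  indices are invariant to global rescaling.
- **Cohorts** draw per-subject baselines around a balanced stance
  (truncated Normal(50, 2 pp)) and per-condition effects from a spec.
  `default_effect_spec()` encodes the direction the design probes —
  unilateral clenching displaces weight toward the opposite side
  (CLR −3 pp, CLL +3 pp, CL 0, between-subject SD 2.5 pp, a mild +1 pp
  anterior tendency) — as free simulation parameters, not estimates of
  any cohort. Crucially, the rest recording carries the same measurement
  noise as every other: all condition-vs-rest differences then share the
  rest error, reproducing the within-subject correlation across table
  columns that motivates the correction.

What the generator does **not** emulate: sway dynamics and serial
correlation between frames, sensor calibration drift, partial foot
contact, or any physiology linking head posture to load shifts. Passing
tests show the pipeline's algebra and statistics behave correctly on maps
with known ground truth; they say nothing about biomechanics.

## Simulation design and problem sizes

Simulation-heavy checks run on a reduced scale chosen once: a 26 × 22
grid with 2–3 frames per recording (defaults remain 52 × 44 × 400; the
indices depend only on the frame mean, so frame count affects noise, not
structure).

- *Shift recovery*: injected lateral shifts of 1, 2 and 5 pp at 200
  subjects with small sensor noise (`noise_sd = 0.05`) are recovered
  within 3 Monte-Carlo standard errors, the SE taken over independent
  per-subject means because the three conditions share each subject's
  rest measurement.
- *Type-I error*: 500 zero-effect cohorts of 20 subjects with
  `noise_sd = 0.5`, a scale at which the OLWD measurement SD is about
  1 pp, so classification against `ε = 0.5` produces genuine label noise
  in all three categories. The corrected test's rejection rate at
  `α = 0.05` must stay within the exact binomial 99% band around ≤ 0.05
  (it is in fact conservative, ≈ 0.03, because the shared rest reference
  correlates columns), and the corrected statistic rejects at least as
  often as the naive one at the same degrees of freedom.

## Numerical and degenerate-input choices

- A table with an empty shift category has no well-defined test
  (an expected count of zero): `naive_pearson()` raises an error, while
  `run_pipeline()` — which can legitimately meet this on an all-no-change
  cohort — reports the table with a `NULL` test and fits no CA.
- Singular values below 1e−12 are treated as null axes; a rank-1
  (independence) table yields zero axes and zero inertia.
- A foot mask supplied by the caller may carry zero load (e.g. extreme
  constructed cases); its AP split is `NA`. Automatic segmentation never
  returns an unloaded mask.
- Recording files round-trip bit-identically: frame values are written
  with 17 significant digits.
- Ties in classification (`|Δ| = ε` exactly) are "no change".

## Limitations

The closed-form `δ` is tied to the exactly-one-response-per-column
design; pick-any multiple-response tables would need the covariance-based
correction, which this package does not implement. The no-change
tolerance `ε` has no empirical calibration — published tables, where
available, are the authoritative classification, and the pipeline's
classifier is a simulation tool. CA coordinates are reported without
confidence regions.
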