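---
title: "Methods: 4D lymphocyte motility, contact graphs and behavior classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D lymphocyte motility, contact graphs and behavior classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LymphoDyn4D)
```

## Scope and data model

LymphoDyn4D analyzes 4D lymphocyte tracking data at the granularity of a
spot-tracking export: one row per (track, frame) with a 3D centroid in
micrometers, acquisition time in minutes, spot intensity and the staining
marker. Spot detection and track linking themselves are upstream of this
package; so is any morphology information — a centroid track carries no
cell size or shape. Tracks enter a `TrackSet`, which enforces the
integrity assumptions everything downstream relies on: at least two points
per track, strictly increasing time, no duplicated frames, finite
coordinates. Internal frame gaps are allowed and never interpolated: a gap
simply contributes no step, no MSD pair and no contact evidence. The
acquisition interval is not part of such exports, so `frameIntervalMin` is
always supplied by the user (the simulator defaults to 0.5 min, a typical
confocal 4D cadence).

Track duration is defined as last-minus-first observed time, not point
count times interval, so tracks with internal gaps keep their wall-clock
span. The standard curation step `filterMinDuration()` removes tracks
shorter than 5 minutes; the boundary is inclusive (a track of exactly
5.0 min survives), a convention this package fixes because "minimum
duration" phrasing leaves the boundary open.

## Motility features

The five per-track features mirror the conventional spot-tracking export:
displacement length, track length, mean speed, straightness, mean
intensity. Two definitions deserve comment:

* **Mean speed** is the mean of per-step instantaneous speeds. Under
  uniform sampling this is algebraically identical to track length divided
  by duration, and the test suite asserts both computations agree to 1e-9
  on uniform fixtures; under gapped sampling the per-step mean is the more
  faithful reading of "speed mean".
* **Straightness** at zero path length is defined as 0. A perfectly
  stationary cell is maximally non-straight for classification purposes;
  the division 0/0 has no natural value and 0 groups such cells with the
  low-motion class where they belong.

## Mean squared displacement

`computeMSD()` uses overlapping time-averaged windows per track — for lag
ℓ frames, the average of squared displacements over every pair of observed
frames exactly ℓ apart — followed by an ensemble mean over tracks. This is
the standard estimator for short tracks; it trades independence between
lags for much lower variance. Lags start at one frame (lag 0 is excluded
by construction) and the largest lag must stay below the shortest track's
frame span so every track contributes everywhere.

`fitAlpha()` estimates the anomalous-diffusion exponent as the
least-squares slope of log MSD versus log lag over the first quarter of
lags by default. The early-lag window avoids the long-lag tail, which is
averaged over few window positions and dominated by noise; for detecting
the MSD plateau of strongly confined motion one fits the whole curve
(`fitFraction = 1`) instead. Zero MSD values in the fit window (perfectly
stationary input) are an error with guidance rather than a silent -Inf.

Calibration anchors, both asserted in the tests: a noiseless ballistic
track has MSD(τ) = v²τ² and recovers α = 2 to machine precision; 200
simulated Brownian tracks (Gaussian steps with per-axis variance 2DΔt)
recover MSD within 10% of 6Dτ at small lags and α within [0.9, 1.1].

## Temporal cell graphs and contact statistics

For every frame of every movie, cells form the nodes of a unit-disc graph
with an edge whenever the centroid distance is at most r = 7 µm. The
radius approximates the surface reach of two adjacent lymphocytes, and the
boundary is inclusive — the unit-disc convention; since coordinates are
continuous the measure-zero boundary choice is immaterial in practice but
fixed for determinism. Edges join any marker pair (B–B, B–T, T–T) and
never cross movies. The per-frame construction is the vectorized
all-pairs distance; correctness is defined by — and tested against — an
independent brute-force oracle on randomized instances up to 200 cells ×
50 frames.

A **contact event** is a maximal run of consecutive frames with an edge
for a given pair. A single missing frame splits a run, and a frame where
either track is unobserved also splits it: absence of evidence of
proximity is treated as absence of contact, the conservative choice for
data with detection dropouts. Per track, `contactStats()` reports the
number of events and their mean duration in frames. "Number of contacts"
counts events, so a pair that separates and re-meets counts twice; the
alternative reading (distinct partners) is available via
`countBy = "partners"`, and mean contact time is averaged per event.

## Behavior classification

Tracks are classified twice, independently: track types LM/MT/LD describe
the movement pattern, action types PC/IC/AC the interaction behavior. Two
separate three-class random forests are used rather than one nine-class
joint model because the two tasks are scientifically distinct and reported
separately. Each forest sees the same 7 features (5 motility/intensity +
number of contacts + mean contact duration), 100 trees, sqrt-features per
split, unlimited depth; forests are scale-invariant so no feature scaling
is applied. None of these hyperparameters is tuned — they are the standard
defaults, recorded in the model object.

"Repeated stratified cross-validation" is implemented as stratified
5-fold CV repeated 20 times with distinct fold shuffles (both knobs
configurable; the phrase "20-times stratified cross-validation" is read as
20 repetitions, not 20 folds). Accuracy is pooled over folds within a
repeat, giving one hold-out accuracy per repeat; the confusion matrix is
pooled over everything. All RNG — fold shuffles and forest fits — draws
from one seeded stream, making reports bit-reproducible.

Prediction assigns the class with maximal predicted probability, with ties
broken by the fixed class orders LM < MT < LD and PC < IC < AC. Class
imbalance is not reweighted by default, mirroring a plain CV protocol.
`compareLabels()` provides the manual-validation mode: an agreement report
between a prediction table and a human annotation table.

## The synthetic generator

The simulator exists so that every pipeline stage — including the
classifier — can be validated end to end without imaging data. It
emulates the *structure* of the real data (archetypes, markers, movies,
cohorts), not its biology; parameter values are package choices, fixed
once and documented here.

Motion models, per track type:

* **LM**: random walk confined to a reflective sphere of radius 2 µm,
  step 0.3 µm/frame (0.6 µm/min at the default cadence);
* **MT**: the same with radius 8 µm and step 1.2 µm/frame (2.4 µm/min);
* **LD**: persistent random walk, persistence 0.95, step 3 µm/frame
  (≈ 6 µm/min). With persistence 0 this reduces to an unbiased walk with
  MSD exponent ≈ 1, which the tests assert.

Step lengths have 30% relative jitter; a 0.1 µm Gaussian centroid
measurement noise is added; walls of the default 200 × 200 × 60 µm
imaging volume reflect specularly. The class speeds (0.6 / 2.4 / 6
µm/min) bracket the few-µm/min range reported for B and T lymphocytes in
live lymphoid tissue, with deliberate separation between classes so that
label-recovery tests measure the pipeline, not the generator's noise
floor.

Action types are operationalized through placement and coupling:

* **PC**: isolated (initial nearest-neighbor distance > 12 µm), LM
  motion. PC is only compatible with LM — passive means nearly
  stationary.
* **IC**: cells placed as pairs 5 µm apart; the partner is pulled back
  toward the leader whenever separation exceeds 6 µm (90% of the excess
  removed per frame), for the first 80% of frames (the contact dwell
  fraction), then released. The deterministic coupling window is the
  simplest mechanism with an exactly tunable dwell fraction.
* **AC**: mobile (MT or LD motion), placed isolated; contacts happen only
  incidentally. Morphology change — the classic hallmark of active
  cells — cannot exist in centroid tracks, so AC is operationalized as
  mobile + low-contact, consistent with the 7 features the classifier
  sees.

The default labeled cohort is 6 movies × 100 tracks (50 per marker,
combination counts chosen so track types are near-balanced at 216/204/180
over 600 tracks — balance matters for the permutation-null check, whose
chance level is then 1/3). The `overlap` knob blends class parameters
toward their common mean and inflates measurement noise, producing a
controlled degradation ladder for the monotonicity test.

The reactive-vs-neoplastic cohort uses track-type mixtures 45/40/15%
(reactive) versus 80/17/3% (neoplastic), with PC/IC/AC shares shifting
accordingly. These mixtures encode the qualitative contrast — neoplastic
tissue slower, fewer interactions — not any measured distribution; the
pipeline-level checks assert orderings (higher LM and PC proportions,
lower mean speed in the neoplastic group), never magnitudes.

What passing these tests shows: the feature definitions, graph and event
segmentation, CV harness and pipeline plumbing are correct, and the
classifier can recover well-separated behavioral archetypes. What it does
not show: performance on real imaging data, where class boundaries are
fluid, annotation is noisy, detection dropouts correlate with crowding,
and intensity carries staining artifacts. Real-data accuracies will be
substantially lower than the synthetic ones, and nothing here claims
otherwise.

## Cohort summaries and comparisons

`summarizeCohort()` reports class proportions per (diagnosis × marker)
with every track weighted equally (per-movie weighting of heterogeneous
cohorts is a deliberate non-default; movie counts per case vary wildly in
real cohorts and the package keeps the simple convention, leaving
reweighting to the caller). All three classes are always reported so
tables stay rectangular; declared-but-empty groups appear with NA
proportions rather than vanishing. `compareGroups()` adds seeded bootstrap
percentile intervals over tracks for group differences — an uncertainty
quantification this package adds on top of the traditional descriptive
percentage plots.

## Validation problem sizes

The shipped test suite validates at these scales, chosen to exercise every
code path while keeping a full run under a minute on one core: 100
randomized graph instances up to 200 cells × 50 frames against the
brute-force oracle; 10,000 random tracks for the feature invariants; 200
Brownian tracks × 100 frames for the MSD closed form; the 600-track
default cohort with 20×5-fold CV (plus a 10-repeat permutation null); and
the 480-track two-group cohort end to end. `scripts/acceptance.R` rebuilds
the same quantities from scratch at the same sizes.

## Known limitations

* No morphology: centroid tracks cannot distinguish cell sizes or shape
  changes, so neither cell subtypes nor shape-based activity are
  representable.
* Contact is a centroid-distance proxy: a fixed 7 µm radius over-counts
  contacts between small distant cells and under-counts touching large
  cells.
* The simulator places cells uniformly; it does not model tissue zonation
  (germinal-center center/edge/periphery structure) or any spatial prior
  on where archetypes occur, and its archetypes are deliberately cleaner
  than real behavior.
* MSD assumes uniform sampling when converting lags to minutes.
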