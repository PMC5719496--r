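---
title: "Methods: cross-modality MALDI lipidomics concordance and exposure response patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modality MALDI lipidomics concordance and exposure response patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maldiconcord)
```

## The analytical problem

Myelin-rich cerebral white matter is dominated by phospholipids
(phosphatidylserines, phosphatidylinositols) and sulfatides, which
ionize well in negative-ion-mode MALDI-TOF in the m/z 600–1300 Da
window. Two acquisition routes are in routine use: lipid *extracts*
spotted onto a ground-steel target (cheap, high-throughput) and imaging
mass spectrometry (*IMS*) of fresh-frozen sections (in situ, spatially
resolved; this package treats each tissue region as one mean spectrum —
spatial rasters are out of scope). The two routes see overlapping but
distinct ion populations, and the overlap itself is informative: shared
ions can serve as cross-platform biomarkers, and a shared ion that never
moves under exposure is a natural internal negative control.

`maldiconcord` implements the comparison end to end for a four-group
smoke-exposure design — A8 (air, 8 weeks; control), CS4, CS8 (cigarette
smoke, 4 or 8 weeks), CS8+R (8 weeks smoke + 2 weeks recovery) — with
six replicate animals per group.

## Preprocessing model

**Peak picking.** Profile spectra are modelled as sparse peaks on a flat
baseline with stationary noise. The baseline is estimated by the median
of the trace and the noise level by `mad(x)` (median absolute deviation
× 1.4826, a robust Gaussian-scale estimate that ignores the sparse peak
mass). A candidate peak must be a strict local maximum that exceeds
`baseline + snr_threshold × noise` (default SNR 3) *together with both
immediate neighbours*. The neighbour requirement is a resolved-peak
width criterion: at the default grid step (0.01 Da) and peak width
(sigma 0.05 Da) a genuine peak spans dozens of samples, whereas a noise
excursion above threshold is almost always a single sample. Without it,
a 70,000-point trace at SNR 3 yields dozens of single-point false peaks
(about 0.13% of samples exceed 3 sigma by chance); with it, the
false-positive count over 100 simulated pure-noise traces is zero (the
test suite asserts a bound of 2). Centroids are intensity-weighted mean
m/z over ±0.1 Da (baseline-subtracted weights); candidates closer than
the window to a stronger candidate are suppressed; reported intensity is
the baseline-subtracted apex height. Picking is restricted to the
600–1300 Da analysis window.

**TIC normalization.** Each peak list is divided by its summed intensity
(per spectrum, before any aggregation), making intensities unit-sum.
Normalization preserves intensity ratios exactly and is idempotent.

**Replicate aggregation.** Peaks from all replicates of one
group × modality are pooled, sorted, and chained into consensus ions by
single linkage: a gap larger than `cluster_tol` (default 0.25 Da) starts
a new ion. Per consensus ion we report the mean m/z, the detection
frequency, and the mean normalized intensity with non-detections counted
as zero (`absent_as_zero = TRUE`, so consensus intensity reflects both
abundance and detectability; a detections-only mean is available by
flag). A replicate contributing several pooled peaks to one ion counts
once, via its most intense peak. Ions detected in fewer than
`min_frequency` (default 0.5) of replicates are dropped — the least
surprising presence rule where no explicit one is established, and
configurable.

## Cross-modality concordance

**Matching.** Extract and IMS consensus lists are paired one-to-one:
all candidate pairs within `tolerance` (default 0.25 Da, wide enough to
absorb reported transcription-level m/z discrepancies of 0.1–0.15 Da
between sources; configurable) are accepted greedily by ascending
|Δm/z|, ties broken toward the lower-m/z extract peak. Greedy matching
is compared in the tests against a brute-force maximum-cardinality,
minimum-total-|Δm/z| assignment on instances with ≤ 8 peaks per side:
cardinalities agree on 56/60 dense random instances (the discrepancy
rate is asserted ≤ 0.15) and always agree when true co-locations are
separated by ≥ 3× the tolerance, which is the regime the generator
guarantees.

**Isotope flagging.** A peak is flagged as a first C13 isotopologue if a
peak exists 1.00335 ± 0.1 Da below it whose intensity is at least as
large (`max_ratio = 1`): for lipids of 40–50 carbons the first-isotope
abundance is near 45% of the monoisotopic peak and cannot exceed it.
Flags are computed on each modality's full consensus list, because a
satellite's parent need not be a shared ion.

**Concordance categories.** For each shared ion the signed percent
difference is `pct = 100 (I_IMS − I_extract) / I_extract`, computed on
A8-control consensus intensities (pooling across groups is available by
flag). The five categories use half-open intervals with the boundary in
the larger-difference class: |pct| < 10 → `=`; 10 ≤ |pct| < 50 → `>` or
`<`; |pct| ≥ 50 → `≫` or `≪`. The classification is total on positive
intensity pairs; a zero intensity on either side means the ion is
modality-only, not shared, and is rejected.

## Multivariate stage

Row z-scoring uses the sample standard deviation (n−1); constant rows
are returned as zero with a warning. Hierarchical clustering of ions is
agglomerative on Euclidean distances with complete linkage by default
(the common heat-map default; only the distance function is fixed by
convention) and deterministic lowest-index-pair tie-breaking; the merge
sequence is validated against a naive O(n³) re-computation oracle for
all three linkages and against `stats::hclust` partitions. Cutting a
dendrogram at k severs the k−1 highest merges. PCA is a singular value
decomposition of the column-centered (and by default unit-variance
scaled — intensities span decades) sample × ion matrix; scores and
explained-variance fractions are validated against an independent
eigen-decomposition of the covariance matrix to 1e−8. Heat-map rendering
(6-color diverging palette over z clipped to [−1, 1]) is a thin export,
not part of the tested core.

## Response-pattern taxonomy

Classification operates on group mean consensus intensities (matching
averaged-data practice; per-replicate testing is a non-goal). With fold
changes f = group/control and the fold distance e(f) = max(f, 1/f):

* the **no-change band** is the open interval
  (1/`change_threshold`, `change_threshold`), default 1.25-fold; a fold
  exactly at the threshold counts as changed, consistent with the
  concordance boundary rule;
* **direction** is the sign of the CS8 effect, or of the CS4 effect when
  CS8 is back inside the band; unchanged ions (both exposures in the
  band) get progression and recovery `n/a`;
* **progression**: `transient` if CS8 is inside the band while CS4 was
  not; `progressive` if e(f_CS8) > e(f_CS4) × `progress_threshold`
  (default 1.15); otherwise `sustained`;
* **recovery**: `full` if CS8+R is inside the band; else `partial` if
  e(f_CS8+R) ≤ e(f_CS8)/threshold (moved toward control), `paradoxical`
  if e(f_CS8+R) ≥ e(f_CS8)×threshold (moved further away), else `none`.

The thresholds are package defaults chosen where only qualitative
descriptions exist ("sharply reduced", "progressive decline"); both are
configurable and recorded in the run summary. Classification depends
only on ratios and is therefore invariant to global intensity
rescaling; the taxonomy is exhaustive and exclusive on positive
profiles (property-tested).

`recovery_fraction()` reports the share of ions with partial or full
recovery among a subset that defaults to *persistently suppressed* ions
(direction inhibited, progression not transient). Transient ions are
excluded because their CS8 level is already at control, making
withdrawal recovery vacuous; this matches reading the published 60%
figure as referring to ion clusters suppressed in both CS4 and CS8. The
summary reports the fraction per modality.

`identify_diagnostic_ions()` splits (shared) ions into a responsive set
(e(f_CS8) ≥ `responsive_fold`, default 2 — candidate exposure markers in
the spirit of the reported m/z 697.35 / 713.75 / 729.22 trio) and a
stable set (all folds within `stable_band`, default 1.25 — internal
negative controls in the spirit of m/z 834.67). The sets are disjoint
whenever `responsive_fold` exceeds `stable_band`.

## The synthetic-data generator

The generator exists so that every stage is testable without any
external data. Its defaults *are* the study conditions: 83 extract
ions, 62 IMS ions, 25 shared (hence 120 distinct), m/z 600–1300 Da,
4 groups × 6 replicates × 2 modalities.

**Ion placement.** Modality bias is realized by band-weighted sampling
over three m/z bands — shared ions favour 700–800 (weights
0.25/0.50/0.25 over 600–700/700–800/800–1300), extract-only ions the
low/mid range (0.45/0.40/0.15), IMS-only ions the high range
(0.10/0.15/0.75) — a quantitative stand-in for a qualitative
description. Positions are drawn by exact feasible-interval sampling:
the allowed set is maintained as a union of intervals after subtracting
(i) ±`min_ion_separation` (default 0.6 Da, chosen to exceed twice the
0.25 Da match tolerance so planted cross-modality matching is
unambiguous) around every occupied position and (ii) an *isotope guard*
of ±0.25 Da around any accidental 1.00335 Da spacing, so that isotope
flagging on synthetic data recovers exactly the planted satellites.
Sampling from the remaining measure cannot stall; an empty feasible set
raises a configuration error.

**Satellites are panel members.** With probability `isotope_prob`
(default 0.20, matching 5 isotope-flagged rows among the 25 published
shared ions) a panel slot is filled by a C13 satellite of the preceding
ion at +1.00335 Da with intensity ratio U(0.3, 0.6) (first-isotope
ratios for 40–50-carbon lipids cluster near 0.45). Satellites count
toward the per-modality ion totals — exactly as isotope peaks do in
published shared-ion counts — which is what makes the zero-noise
detection arithmetic exact.

**Responses.** Each non-satellite ion draws a category from
`effect_mix` (default: 12% stable, 48% inhibited, 40% stimulated,
split over sustained/progressive/transient), with multipliers sampled
from sub-intervals that keep a safety margin to every classification
boundary (e.g. sustained suppression draws m_CS8 ~ U(0.35, 0.5) with
m_CS4/m_CS8 ~ U(0.9, 1.0), strictly inside the sustained region).
Stable ions have all multipliers exactly 1. Among persistently
suppressed (and mirrored stimulated) ions, `recovery_fraction` (default
0.60) receive partial or full recovery (2:1), the rest none or
paradoxical (3:1). Satellites inherit their parent's category and
multipliers. Stimulated multipliers are reciprocals of inhibited draws,
so the two directions are exact mirrors on the fold scale.

**TIC balance.** Per-spectrum TIC normalization couples every ion to
every other: suppressing half the panel inflates the normalized values
of the rest, which would corrupt the planted fold changes. The
generator therefore projects the base intensities of each modality onto
the subspace where every exposure group's total planted intensity
equals the control total. The projection is intensity-weighted
(minimizing summed squared *relative* perturbation), which keeps bases
positive and preserves each satellite's intensity ratio exactly; the
measured normalized fold change of every ion then equals its planted
multiplier exactly at zero noise. This is a deliberate idealization:
real exposure data need not be TIC-balanced, and compositional
distortion of fold changes under TIC normalization is a known hazard of
the normalization itself.

**Forward model.** A profile spectrum is a sum of Gaussians (sigma
0.05 Da on a 0.01 Da grid) with heights = base × group multiplier ×
lognormal replicate jitter (sigma_log 0.15 — replicate variability is
unreported in the source setting; lognormal keeps intensities positive
and 0.15 gives a realistic ~15% CV), riding on a flat baseline of
5 × `noise_sd` with additive Gaussian noise (`noise_sd` default 1,
roughly 1/150 of a median peak height) clipped at zero. The baseline
offset makes the median/MAD noise estimate well-posed; at
`noise_sd = 0` the trace is the exact noiseless forward model. A
`peaklist` output mode emits the same heights as idealized centroids,
skipping rendering — useful for fast statistical tests of the
classifier itself.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: mass-calibration drift and alignment error
between modalities; Poisson/detector noise scaling with intensity;
peak-shape asymmetry and overlapping isobars; chemical noise and matrix
clusters; spatial heterogeneity within tissue; ion-suppression effects
that couple co-located ions; and any real biological covariance between
lipids (ions are planted independently). Results on synthetic data
validate the *pipeline logic*, not instrument physics.

## Numerical conventions and degenerate inputs

* All category/band boundaries are half-open with the boundary in the
  changed / larger-difference class.
* Ties in clustering break toward the lowest-index pair; matching ties
  toward the lower-m/z extract peak — all outputs are deterministic
  given a seed.
* Constant rows (z-score) and constant columns (PCA scaling) are
  handled with a warning rather than an error; single-column matrices,
  all-zero peak lists, empty subsets, non-positive control means, k out
  of range, and rank-exceeding component requests raise classed errors.
* Derived sub-seeds stay below 2^31; identical configurations give
  byte-identical outputs.

## Problem sizes used in the tests

Unit and property tests run on small instances (≤ 10 peaks per side for
the brute-force matching oracle, n ≤ 8 rows for the O(n³) clustering
oracle, 12 × 30 matrices for PCA) plus full-design synthetic studies
(120 ions, 48 cells) at zero noise for exact planted-truth recovery,
and 20 seeded full-design studies at default noise for the statistical
assertions; the whole suite completes in about a minute on one CPU. The
acceptance script renders and analyses 21 full-design studies in about
two minutes.

## Known limitations

* The recovery-fraction estimate at default noise carries a small
  (~2 percentage point) upward bias relative to the planted proportion,
  because the classification leaks asymmetrically at two boundaries:
  a transient ion whose noisy CS8 mean escapes the no-change band joins
  the persistent denominator with its near-control CS8+R level scored
  as full recovery, and a no-recovery ion is more likely to drift into
  `partial` (toward control) than the reverse. With ~25 ions per study
  the per-seed binomial scatter (sd ≈ 13 points) dominates this bias;
  the zero-noise estimate is exact.
* Greedy matching is not guaranteed optimal in dense ion neighbourhoods
  (closer than ~2 matching tolerances); the measured disagreement with
  the optimal assignment is a few percent of dense random instances and
  zero at the separations the generator enforces.
* Concordance uses A8-group intensities by default; ions absent from
  the A8 consensus of either modality are excluded from concordance
  records (they remain in the detection counts).
* The dendrogram cluster count k is descriptive, not inferred; no gap
  statistic or height-based cut criterion is provided.
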