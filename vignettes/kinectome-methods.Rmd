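---
title: "Kinectome analysis of whole-body gait coordination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinectome analysis of whole-body gait coordination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectome)
```

## The kinectome

Walking coordinates the whole body: arms swing against the contralateral
leg, the trunk counter-rotates against the pelvis, and the vertical
bounce of every segment repeats with each step. The **kinectome**
summarises this coordination as a network. For one *gait acquisition* —
a data window containing one full gait cycle of each body side — the
acceleration time series of all 22 body segments are correlated pairwise
(Pearson), separately in the anteroposterior (AP), mediolateral (ML) and
vertical (V) movement directions. The result is a symmetric
22 x 22 x 3 correlation array. Treating segments as nodes and signed
correlations as edge weights of a complete undirected graph turns
questions about coordination into questions about weighted graphs.

The analysis pipeline is:

1. **Markers to segments.** A 47-marker optical motion-capture layout
   (200 Hz, mm) is reduced to 22 segment trajectories: the four head
   markers, the three sternum markers and the four-marker thigh and
   shank clusters collapse to centroids; upper-arm and forearm markers
   are dropped; heel markers are kept only as auxiliary channels for
   gait-event detection.
2. **Preprocessing.** Trials are trimmed to the 5 m cone-bounded
   walkway (pelvis centroid between the cones); heel strikes are
   detected; acquisitions are cut; gaps of at most 271 samples (1.355 s)
   are linearly interpolated; a zero-phase 2nd-order Butterworth low-pass
   at 6 Hz is applied; the horizontal plane is rotated by PCA so +X is
   the walking direction; positions are differentiated twice by central
   differences; each acquisition is time-normalised to 500 samples.
3. **Aggregation.** Acquisition kinectomes are averaged element-wise
   into one person-mean and one person-SD kinectome per (speed,
   direction) — 9 + 9 matrices per subject over three speeds — and
   person kinectomes are averaged into group mean/SD kinectomes.
4. **Statistics.** Group kinectomes are compared by a permutation test
   on the Spearman correlation of their upper-triangle vectors; pattern
   values are compared between groups with normality-gated tests; and a
   bootstrap quantifies the stability of the group correlation across
   sample size.

## Greedy maximum-weight path patterns

A *pattern* is a path: an ordered sequence of distinct segments.
`strongest_pattern()` starts at a given node and repeatedly appends the
unvisited node whose connecting edge has the largest **absolute** weight
from the current node, until the requested length is reached. Only the
length is constrained; there is no target node. Scanning all 22 start
nodes and lengths 2-20 yields 418 patterns per (speed, direction).
Lengths 2-6 are *local* patterns, 7-14 *multi-segmental*, 15+
*whole-body*.

Group comparison follows a reference-pattern logic: the source group's
reference pattern for each (start, length) is extracted from that
group's kinectomes, the reference's value (mean absolute edge weight
along the path) is read off every subject's person-mean kinectome in
both groups, and the two value samples are compared. P-values are
Bonferroni-adjusted with n = 22 across start nodes within each length.
Two references whose node sets overlap at Jaccard index >= 0.8 count as
the same pattern when deduplicating control-derived and PD-derived
scans.

Design choices in this module, made where the procedure was genuinely
open:

* **Reference "averaging".** The group reference is the greedy pattern
  of the element-wise mean of the group's person-mean kinectomes
  (deterministic); a per-position majority vote across individual
  patterns is available as `strategy = "majority_vote"`.
* **Pattern value.** Mean of absolute edge weights (comparable across
  lengths, bounded in [0, 1]); `method = "sum"` is available.
* **Ties.** Greedy ties break by lexicographic segment label — a
  measure-zero event on real data but a certainty in constructed tests,
  so determinism is guaranteed.
* **Jaccard on node sets**, not edge sets ("80 % overlap" of a path
  reads most naturally on segments); both interpretations share the
  same function surface.

## Statistical machinery

`compare_groups()` assesses normality per group once, on the original
values, with Shapiro-Wilk at alpha = 0.05; constant samples are treated
as non-normal because the test is undefined there. Outliers are then
screened per group — |z| > 3 under normality, 1.5 IQR beyond the
type-7 quartiles otherwise — and the test branch uses the same flags:
pooled-variance Student t when both groups are normal, Mann-Whitney U
otherwise. Cohen's d uses the pooled SD with sign group1 − group2 and
labels negligible/small/medium/large at 0.2/0.5/0.8. Two constant equal
samples return p = 1 by convention; a zero pooled SD with unequal means
keeps d finite through an epsilon-regularised denominator.

The permutation test shuffles the vectorised strictly-upper-triangle of
the control matrix 5000 times and reports the one-sided exceedance
p-value with +1 smoothing, `p = (1 + #{null >= observed}) / (n + 1)` —
high observed rho means the two group kinectomes agree far beyond
chance. The bootstrap resamples both groups independently with
replacement at fractions 0.10-0.90, rebuilds the group matrices and
records the Spearman correlation between them; its spread shrinks as
the fraction grows.

## The synthetic gait generator

No clinical trajectories ship with the package; every downstream stage
is instead exercised on synthetic cohorts with *known* coordination
structure. The generator emulates: 22 segment trajectories (optionally
the raw 47-marker layout), three speed conditions, quasi-periodic gait
with contralateral phase structure, configurable coupling and
cycle-to-cycle variability, a heading that need not align with the lab
axes, and injectable missing samples.

**Signal model.** Each trial has a stride clock `theta(t)`; per-stride
frequencies are drawn with jitter and interpolated between stride
midpoints so the clock rate — and hence the progression velocity — is
continuous (a piecewise-constant rate would put spurious acceleration
spikes at stride boundaries). Per direction, segment accelerations are a
linear mix of an exactly orthonormalised basis: the quadrature pair of
the stride-frequency harmonic, the quadrature pair of the step-frequency
harmonic, and band-limited (0.5-5 Hz) noise sources, QR-orthonormalised
together. The mixing matrix is the eigenfactor square root of the target
coupling matrix, so the realized correlation of the generated
accelerations equals the target exactly up to filtering and
discretisation bias (< 2 % in practice). Accelerations are
double-integrated (cumulative trapezoid, polynomial drift removal) to
positions, translated forward along the walkway, and rotated to the
requested heading. All stochastic draws happen in the body frame with
the rotation applied last, so two trials differing only in heading are
exact rotations of one another — heading invariance of the pipeline
holds to machine precision even with measurement noise.

**Default coupling.** When no coupling matrix is supplied it is derived
from the segment model: each segment loads on the two harmonics with its
phase and a communality `amp^2 / (amp^2 + noise_sd^2)`, and the implied
correlation is the loading inner product. Contralateral limbs are
anti-phase (stride-frequency components correlate negatively); vertical
motion is step-frequency dominated and positively coupled body-wide.
With `noise_sd = 0`, equal-phase segments couple at +1 and anti-phase
segments at −1.

**Cycle variability.** Within each stride, every segment's harmonic
component is rotated by an independent Gaussian phase offset and the
whole per-stride signal is scaled by an independent amplitude factor,
both with SD `cycle_variability_sd`. Defaults are 0.02 for the control
group and 0.08 for the deficit group; the ratio was chosen so that the
synthetic deficit group reproduces the qualitative clinical picture —
element-wise higher SD kinectomes and lower between-group SD-kinectome
correlations than mean-kinectome correlations — at a clinically
plausible multiple of healthy stride-to-stride variability.

**Planted deficits.** `plant_coordination_deficit()` multiplies the
coupling entries along a chosen path by an attenuation factor in (0, 1],
creating a group whose coordination is weaker exactly where specified.
Attenuation can push the matrix slightly outside the positive
semidefinite cone; generation always works on the nearest valid
correlation matrix (eigenvalue clipping with diagonal rescaling).

**Speed conditions.** Preferred 1.10 m/s at 1.05 strides/s, fast
1.45 m/s at 1.30, slow 0.65 m/s at 0.85 — stride lengths of roughly
0.75-1.1 m, representative of an older clinical cohort and chosen so a
5 m walkway contains at least three full gait acquisitions per trial,
the availability the analysis assumes.

**What the generator does not emulate.** It is not a musculoskeletal
simulation: no ground-reaction forces, no double-support timing, no
freezing episodes, no soft-tissue artefact. Passing tests demonstrate
that the pipeline recovers known coordination structure from realistic
signal geometry; they do not validate clinical sensitivity on real
patients.

## Numerical choices and known limitations

* **Acquisition windows and correlation bias.** An acquisition spans
  one full cycle of each side — from an anchor-side heel strike to the
  first opposite-side strike after the next anchor strike, about 1.5
  stride periods. Over 1.5 periods the stride- and step-frequency
  quadratures are not mutually orthogonal (the window correlation of
  `cos(theta)` with `sin(2 theta)` is about 0.28), so Pearson over such
  windows systematically differs from the long-run correlation for
  segment pairs that mix both harmonics — by up to ~0.1 at the default
  harmonic weights. This is a property of windowed correlation itself,
  not of the estimator; the test suite checks measured kinectomes
  against a closed-form window-Gram oracle that accounts for it.
* **Heel-strike detection** is coordinate-based: local maxima of the
  heel's along-track position relative to the pelvis centroid, with a
  minimum peak separation of 0.4 s. It needs no force plates and is
  exact for the generator's heel model; real data with pathological
  foot trajectories may need the threshold parameters in
  `preproc_params()`.
* **Filtering** is zero-phase (forward-backward), because phase
  distortion would corrupt the inter-segment correlation timing; the
  "2nd order" of the design is the filter order before the
  forward-backward pass. Reflection padding suppresses edge transients.
* **Differentiation** uses second central differences (exact for
  quadratics); the first and last samples are dropped before time
  normalisation, so acceleration row *t* corresponds to position sample
  *t + 1*.
* **Aggregation conventions.** Sample SD (n − 1) for person-SD
  kinectomes; correlations are averaged directly without Fisher
  z-transform, matching the plain-averaging description of the method
  (z-averaging would be a one-line change in `aggregate_person()`).
* **Affected-side rules.** The side with the higher MDS-UPDRS III
  sub-score (upper: items 3.3 + 3.4 + 3.5 + 3.6; lower:
  3.3 + 3.7 + 3.8) is most affected when the difference is >= 1 point;
  even scores, and all controls, fall back to the non-dominant side;
  missing handedness defaults the non-dominant side to left. After
  relabelling, channels are reordered to a canonical mas/las order so
  every subject's kinectome shares one label order.
* **Problem sizes in the test suite.** The statistical suites run at
  desk scale: 10 subjects per group and 20 replicate cohorts for null
  calibration and planted-deficit recovery, 6 per group for the
  variability and bootstrap checks, 500-5000 permutations, 200
  bootstrap draws per fraction. These sizes were chosen to make the
  Monte-Carlo error comfortably smaller than the effects being checked.
* **Reference-pattern selection.** The source group both selects the
  reference pattern (greedy on its group-mean kinectome) and contributes
  values to the comparison. When the coupling hierarchy is not well
  separated relative to sampling noise, this makes single-cohort pattern
  comparisons mildly anti-conservative in the source group's favour — a
  property of the reference-pattern design, worth keeping in mind when
  interpreting borderline p-values. The package's null-calibration
  checks use exchangeable groups and pool across replicate cohorts.
* **Side assignment differs between groups by construction.** PD sides
  come from lateralized MDS-UPDRS III scores, control sides from
  handedness, so mas/las relabelling is itself a group-dependent
  transformation; analyses that require exchangeable groups (null
  calibration) should run on raw left/right labels
  (`cohort_kinectomes(..., relabel = FALSE)`).
* **Clinical counts are out of scope.** The package does not attempt to
  reproduce the clinical study's significant-pattern counts; those
  depend on the patient dataset. The synthetic studies check
  calibration (nothing found when nothing is planted) and recovery
  (planted deficits found where they were planted, with the correct
  direction).

## Reproducing a run

```{r, eval = FALSE}
library(kinectome)

config <- study_config(
  cohort = cohort_config(
    n_per_group = 10, speeds = "preferred", seed = 1,
    attenuation = list(path = c("ankle_l", "hand_r", "wrist_r",
                                "shank_l", "elbow_r"),
                       direction = "AP", factor = 0.5)),
  stats = list(n_perm = 5000,
               bootstrap = list(enabled = TRUE,
                                fractions = seq(0.1, 0.9, 0.1),
                                n_boot = 200),
               seed = 1))
res <- run_pipeline(config, out_dir = "results/run1")
res$permutation
dplyr::filter(res$patterns, p_bonferroni < 0.05)
```

Every output table carries the hash of the configuration that produced
it, and re-running an identical configuration reproduces all numbers
exactly.
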