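# kinectome

Whole-body inter-segmental gait coordination analysis in R.

People coordinate the entire body when they walk — arms swing against the
contralateral leg, the trunk counter-rotates over the pelvis, and every
segment bounces with each step. `kinectome` quantifies that coordination
as a network: for each *gait acquisition* (a window containing one full
gait cycle of each body side) it computes the **kinectome**, the
symmetric matrix of pairwise Pearson correlations between the
acceleration time series of 22 body segments, per movement direction
(anteroposterior, mediolateral, vertical):

```
K[i, j] = cor(a_i, a_j),   a_i = 500-sample normalised acceleration of segment i
```

Kinectomes are aggregated into person mean/SD and group mean/SD
matrices, compared between groups by permutation testing on the Spearman
correlation of their vectorised upper triangles, and mined for
**maximum-weight path patterns**: from a start node, greedily follow the
edge with the highest absolute weight to an unvisited node until the
path has the requested length (2–20 nodes; 2–6 = local,
7–14 = multi-segmental, 15+ = whole-body). A group's reference pattern
is evaluated on every subject of both groups and the value samples are
compared with normality-gated t / Mann–Whitney U tests, Cohen's d, and
Bonferroni adjustment (n = 22 start nodes per length). Patterns whose
node sets overlap at Jaccard index ≥ 0.8 count as the same pattern.

The package covers the full chain:

* **Synthetic gait generator** — cohorts of 200 Hz marker trajectories
  with *known, controllable* coordination structure (target coupling
  matrix realized exactly in the acceleration domain), contralateral
  phase structure, three walking speeds, per-stride variability,
  arbitrary heading, missing samples, and plantable coordination
  deficits. Real motion-capture data is not required for any test.
* **Marker IO** — BIDS-like tabular layout (TSV + JSON sidecar,
  `participants.tsv`), 47→22 marker reduction, most/least-affected-side
  assignment from MDS-UPDRS III items with mas/las relabelling.
* **Preprocessing** — walkway trimming, coordinate-based heel-strike
  detection, acquisition cutting, gap interpolation (≤ 271 samples),
  zero-phase 6 Hz Butterworth, PCA heading alignment, double
  differentiation, 500-sample time normalisation.
* **Statistics** — outlier screening, Shapiro–Wilk-gated two-group
  tests, permutation and bootstrap procedures, Bonferroni adjustment.
* **Pipeline** — `run_pipeline()` orchestrates everything from a single
  YAML-serialisable `study_config()` and writes TSV tables plus a run
  manifest with a config hash.

## Worked example

Plant a 50 % coordination deficit along a 5-node anteroposterior path in
the "PD-like" group and recover it:

```r
library(kinectome)

planted <- c("ankle_l", "hand_r", "wrist_r", "shank_l", "elbow_r")
config <- study_config(
  cohort = cohort_config(
    n_per_group = 8, speeds = "preferred", seed = 42,
    attenuation = list(path = planted, direction = "AP", factor = 0.5)),
  patterns = list(lengths = 2:20, bonferroni_n = 22,
                  jaccard_threshold = 0.8, value_method = "mean",
                  strategy = "group_mean", sources = "control"),
  stats = list(n_perm = 500, bootstrap = list(enabled = FALSE), seed = 1))
res <- run_pipeline(config)

res$permutation
#> # A tibble: 6 × 6
#>   speed     direction role         rho       p n_perm
#>   <chr>     <chr>     <chr>      <dbl>   <dbl>  <dbl>
#> 1 preferred AP        group_mean 0.896 0.00200    500
#> 2 preferred AP        group_sd   0.814 0.00200    500
#> 3 preferred ML        group_mean 0.909 0.00200    500
#> 4 preferred ML        group_sd   0.693 0.00200    500
#> 5 preferred V         group_mean 0.914 0.00200    500
#> 6 preferred V         group_sd   0.706 0.00200    500

sig <- dplyr::filter(res$patterns,
                     p_bonferroni < 0.05,
                     direction_of_difference == "pd_weaker")
dplyr::select(sig, start, length, level, p_bonferroni, cohens_d)[1:3, ]
#> # A tibble: 3 × 5
#>   start     length level p_bonferroni cohens_d
#>   <chr>      <int> <chr>        <dbl>    <dbl>
#> 1 ankle_mas      4 local     4.64e- 8     6.73
#> 2 elbow_las      4 local     1.25e-13    17.3
#> 3 elbow_las      5 local     2.06e-14    19.7
```

Reading the output: both groups share the same overall coordination
architecture (`rho ≈ 0.9` between group mean kinectomes, far beyond the
permutation null, `p = 0.002`), yet the pattern scan pinpoints the
planted deficit — the significant comparisons start on the planted
path's segments, are labelled `pd_weaker`, and their references overlap
the planted path at Jaccard 1.0. SD-kinectome correlations sit below
the mean-kinectome ones, reflecting the deficit group's larger
stride-to-stride variability.

`vignettes/kinectome-methods.Rmd` documents the signal model, every
tunable parameter with its default and units, and the design decisions.

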