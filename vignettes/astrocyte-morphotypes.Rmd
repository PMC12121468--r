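---
title: "Astrocyte morphometry and morphotype clustering: methods"
author: "astromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Astrocyte morphometry and morphotype clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Protoplasmic astrocytes tile the hippocampus with bushy, highly ramified
arbors whose complexity changes with age and with neurodegenerative
pathology. `astromorph` quantifies that complexity from 3D skeleton
reconstructions (SWC files, one per cell), classifies cells into
*morphotypes* — clusters of cells sharing a morphological profile — and
tests how morphotype composition and individual features differ between
genotypes and age groups when cells are nested within animals.

The pipeline is, per age group:

1. ten morphological features per cell (including a 1-µm 3D Sholl
   profile);
2. optional log10 transform of skewed features, then z-scaling;
3. correlation-matrix PCA with component retention by the conjunction of
   Kaiser's criterion and Horn's parallel analysis;
4. clustering in retained PC space with four algorithms (hierarchical,
   k-means, PAM, SOM), the number of clusters chosen by an eight-index
   vote and the algorithm by internal-validation score;
5. variable filtering by cluster contribution, then refinement of the
   partition by discriminant analysis of principal components (DAPC);
6. group statistics: cluster proportions with Pearson chi-square,
   Kruskal–Wallis + Dunn (BH-corrected) cluster characterization, a
   complexity ranking of clusters, nested ANOVA per feature with mouse
   as a random factor nested in genotype, and per-radius Sholl-profile
   contrasts.

A branching-process simulator generates whole cohorts with known
morphotype, genotype, age and mouse structure, so every stage is testable
without any imaging data.

# Morphometric features

For a skeleton rooted at its soma node the package computes:

| feature | definition | units |
|---|---|---|
| `soma_diameter` | twice the root radius, unless a measured value is supplied via the manifest | µm |
| `total_process_length` | sum of all non-soma segment lengths | µm |
| `branch_depth_median` | median over branches of the number of bifurcations between soma and branch start | count |
| `branch_level_median` | median branch depth + 1 | count |
| `n_branches` | number of maximal paths between topological nodes (soma, bifurcation, tip) | count |
| `n_branching_points` | non-soma nodes with ≥ 2 children | count |
| `sholl_median` | median Sholl count over radii 1..R~max~ | count |
| `sholl_peak_count` | maximum Sholl count | count |
| `n_primary_branches` | Sholl count at radius 1 µm | count |
| `ramification_index` | `sholl_peak_count / n_primary_branches` | — |

Decisions worth making explicit:

* **Sholl counting** uses the straddle rule: a straight segment with
  endpoint distances `d_min < r ≤ d_max` from the soma centre crosses the
  sphere of radius `r` exactly once. The half-open convention makes a
  sphere passing exactly through a node count once, deterministically.
  The analytic rule is verified in the tests against a dense-resampling
  oracle that walks every segment in 5-nm steps and counts indicator
  transitions.
* **Primary branches** are estimated *only* from the Sholl count at
  radius 1 µm, not by counting soma children; this matches how tracing
  software estimates them and keeps the ramification index internally
  consistent. Cells with no intersection at 1 µm get a missing
  ramification index and are dropped (with a logged count) before
  clustering.
* **The soma root is not a branching point**, however many primary
  processes it bears; bifurcations are counted within the arbor only.
* **Peak ties** are resolved toward the smallest radius; the Sholl median
  is taken over radii 1..R~max~ inclusive (interior zeros count, zeros
  beyond the cell boundary do not).
* Per-branch quantities (depth, level) are summarized by medians;
  totals and Sholl summaries are not.

# Scaling, PCA and component retention

Branching counts and lengths in both real and simulated astrocyte data
span one to two orders of magnitude and are strongly right-skewed. On a
linear z-scale the heavy right tail dominates every Euclidean distance,
so the package's default configuration applies `log10(1 + x)` to the
seven count/length features (`total_process_length`, `n_branches`,
`n_branching_points`, `sholl_peak_count`, `sholl_median`,
`n_primary_branches`, `ramification_index`) before z-scaling. The
transform can be disabled or redirected via
`pipelineConfig(features = list(log10 = ...))`.

PCA is computed on the correlation matrix (equivalently, on z-scores);
eigenvalues therefore sum to the number of features, and Kaiser's
criterion (eigenvalue > 1) is meaningful. Horn's parallel analysis
simulates `pca.nIter = 1000` same-shaped standard-normal datasets and
takes, per rank, the 95th percentile of the null eigenvalues as the
threshold (the mean is available by option; the 95th percentile is the
standard conservative choice). A component is retained only if **every
earlier component is retained and it passes both criteria** — retention
is a leading prefix. If the conjunction retains nothing, the pipeline
floors retention at `pca.minComponents = 2`, because clustering needs at
least a plane; the floor is reported.

# Clustering and k selection

Clustering operates on the retained PC scores only. Four algorithms are
fitted: agglomerative hierarchical clustering (Ward linkage by default —
the standard choice for compact morphotypes; average/complete/single are
available), k-means (best of 25 seeded restarts), PAM (BUILD + SWAP on
Euclidean distances), and an online self-organizing map on a k×1 grid
with linearly decaying learning rate and Gaussian neighbourhood.

The number of clusters is chosen over `cluster.kRange = 2..8` by a
defined panel of eight internal indices, each voting for its optimal k:
Calinski–Harabasz (max), mean silhouette (max), Dunn (max),
Davies–Bouldin (min), the gap statistic with 50 uniform reference sets
and the one-standard-error rule, Hartigan's rule (first k with statistic
≤ 10), C-index (min) and Krzanowski–Lai (max). The majority vote wins;
ties break toward smaller k (parsimony), and a fully tied vote falls
back to the silhouette optimum with a warning. The panel replaces a
30-index battery with a documented, reproducible subset.

The algorithm is then selected at the chosen k by the three classic
internal validation measures — connectivity with 10 nearest neighbours
(lower better), Dunn index, and mean silhouette — standardized across
candidates and averaged.

# DAPC refinement and variable filtering

Features are first filtered for cluster characterization: a feature's
*contribution* to a cluster is the absolute mean of its z-scores within
that cluster, and a feature is kept when its maximum contribution
exceeds 0.7 **and** a Kruskal–Wallis test across clusters is significant
at 0.05. (The discriminant-axis loading definition of contribution is an
alternative; the cluster-wise mean was chosen because the threshold is
applied "in at least one cluster".)

DAPC is a multi-class linear discriminant analysis on the PC scores of
the retained variables with the cluster labels as classes: the
between/within scatter eigenproblem yields up to k − 1 axes normalized
to unit within-class variance, and per-cell posterior memberships follow
from a shared within-class covariance with uniform priors. The partition
is refined by one round of maximum-posterior reassignment (iteration is
available but off by default; one round is a validation step, not an EM
loop). A cluster emptied by reassignment keeps its highest-posterior
cell, with a warning. The number of PCs is fixed upstream by the
retention step; DAPC performs no internal cross-validated PC choice.

# Group statistics

* **Nested ANOVA.** Cells from one mouse are not independent replicates
  of genotype. The genotype contrast is therefore tested against the
  mouse-within-genotype mean square: F = MS~genotype~ / MS~mouse(genotype)~
  with (g − 1, m − g) degrees of freedom, computed via `aov` with a
  mouse error stratum (sequential SS under unbalance). With one mouse
  per genotype the test is refused. The tests verify both the sums of
  squares against explicit arithmetic and the empirical type-I error
  (~5%) under a null with real mouse variance — the design reason for
  nesting — alongside the anticonservatism of the naive cell-level
  ANOVA in the same simulation.
* **Cluster characterization** uses Kruskal–Wallis (tie-corrected) and
  Dunn's pairwise z tests on pooled ranks, BH-corrected within one
  Kruskal–Wallis family (one variable, one age group).
* **Cluster distributions** per genotype are compared by Pearson
  chi-square without continuity correction; expected counts below 5
  produce a warning.
* **Sholl profiles** are zero-padded to the cohort maximum radius
  (absent processes are true zero intersections), compared by two-way
  ANOVA (genotype × radius) and per-radius two-sample contrasts with
  Bonferroni correction across radii at a 0.01 display threshold.
* **Complexity score** of a cluster is the mean z-score of
  `n_branching_points`, `n_branches` and `ramification_index`; clusters
  are ranked low → medium → high.
* Within-genotype age contrasts use one-way ANOVA with Bonferroni
  pairwise contrasts; Dunnett's exact multivariate-t quantile is
  deliberately approximated by Bonferroni (conservative).

Age groups are always analysed independently: three separate
clusterings, no cross-age label matching. Cluster "1" at one age has no
relation to cluster "1" at another. Nested ANOVAs and Sholl contrasts
run per subregion within each age group.

# The synthetic cohort generator

The generator grows rooted 3D trees by a stochastic branching process:
`max(2, Poisson(nPrimary))` primary processes leave the soma in
quasi-uniform directions; growth advances in 1-µm steps with the
direction perturbed by a tortuosity of 0.25 rad and a slight outward
bias; bifurcations occur along the path at `branchRate` per µm with
gamma-distributed inter-bifurcation distances (shape 8), daughters
diverging by a 25° half-angle; a branch ends at the territory radius or
when its gamma-distributed length budget is exhausted; radii taper
outward with a 0.1-µm floor. Territory radius, soma radius and branch
rate receive a per-cell log-normal jitter (sd 0.05).

Two variance-control choices matter. First, the gamma (shape 8) rather
than exponential inter-event lengths: with memoryless budgets the
branching cascade is so heavy-tailed that single "lucky" cells span the
whole feature range and morphotypes blur into a continuum; shape 8
keeps the event *rates* as specified while giving the within-type
variability a realistic spread. Second, the mouse-level random effect
is multiplicative on `branchRate` (sd 0.1), which makes the nested
ANOVA's variance decomposition meaningful in simulated cohorts.

Three archetypes of graded branching complexity are the default
morphotypes:

| archetype | nPrimary | branchRate (/µm) | meanBranchLength (µm) | territory (µm) | soma radius (µm) |
|---|---|---|---|---|---|
| simple | 3 | 0.004 | 9 | 15 | 2.2 |
| medium | 6 | 0.03 | 30 | 46 | 4.6 |
| complex | 12 | 0.1 | 24 | 30 | 2.8 |

Their generated feature distributions are ordered in `n_branches`,
`n_branching_points` and `ramification_index` (verified as a property
test), and they remain separable after the full pipeline. The default
cohort structure emulates a longitudinal tauopathy study design:
2 genotypes × 3 age groups × 3 mice × 3 subregions × 15 cells, with
per-genotype-and-age mixture proportions over the archetypes that follow
the reported pattern of wild-type complexity peaking at middle age while
the transgenic cohort is simplified early and partly complexified late.

What the generator does **not** emulate: leaflet-scale nanomorphology,
vascular endfeet, anisotropic territories, tracing artefacts
(disconnected fragments, loops), or the absolute feature values of any
real dataset. Passing tests on simulated cohorts therefore demonstrate
the *internal correctness and statistical behaviour* of the pipeline,
not biological conclusions about real tissue.

# Numerical choices and degenerate inputs

* All randomized stages draw named sub-seeds from one master seed
  (`subSeed`), so a pipeline run is a pure function of (inputs, config,
  seed); reruns are bitwise-identical.
* PCA component signs are fixed (largest-magnitude loading positive);
  hierarchical cuts are relabelled in order of first appearance — both
  for determinism.
* A singular within-class scatter in DAPC receives a 1e-8 ridge, with a
  message.
* Dunn index on a zero-diameter cluster is 0 by convention, flagged;
  singleton-cluster silhouettes are 0.
* Constant feature columns abort scaling with the feature named; cells
  with undefined ramification index are dropped with a logged count.
* A k range collapsed to a single value forces that k and is reported.

# Problem sizes

The test suite and the acceptance script run entirely on simulated
data at the sizes the analysis is designed for: single-age cohorts of
~300 cells (2 genotypes × 3 mice × 3 subregions) for cluster-recovery
checks, 360-cell cohorts for end-to-end determinism, 100 skeletons for
Sholl-oracle equivalence, and 1000–2000 replicates for the nested-ANOVA
type-I-error simulations.

# Known limitations

* The index panel is a fixed eight-member subset, not the full 30-index
  battery of the NbClust tradition; votes can differ from that tool on
  borderline geometries.
* DAPC posteriors assume a shared within-class covariance; strongly
  heteroscedastic clusters will see over-confident posteriors.
* The nested ANOVA uses the sequential-SS/error-stratum formulation, not
  REML; heavily unbalanced designs are handled but a mixed model may be
  preferred there.
* Starting from SWC skeletons means upstream tracing choices (seed
  diameters, gap closing) are out of scope, as are volume/surface
  measures that require the image.
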