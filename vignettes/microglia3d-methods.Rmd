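---
title: "Methods: automated 3D microglial phenotyping with microglia3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated 3D microglial phenotyping with microglia3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

Microglia change shape with functional state: surveillant cells are
ramified (small soma, long branching processes), primed cells are rod-like
(elongated soma, retracted processes), and activated cells are amoeboid
(enlarged soma, few or no processes).  `microglia3d` turns a 3D
fluorescence stack of labelled microglia into per-cell morphometric
features, clusters the cells into these three states, and tests whether
state proportions differ between experimental groups.  The stages are:
segmentation, eight-feature morphometry, z-scoring, correlation-redundancy
filtering, cluster-count selection by the gap statistic, UMAP embedding,
PAM (k-medoids) clustering, rubric-based state assignment, and per-animal
proportion statistics (pooled t-tests, two-way sex-by-state ANOVA, Cohen's
*d*).  A synthetic-data module generates ground-truthed image stacks and
calibrated feature tables so that every stage is testable without
microscopy data.

## Morphometry

**Segmentation.** The stack is binarized (Otsu threshold over a 256-bin
histogram by default; a fixed threshold can be supplied), and 26-connected
components are labelled.  Components smaller than `min_voxels` (default
50) are treated as debris.  Components touching the lateral (x/y) image
border are excluded so that only whole cells are measured; the thin z
extent of typical stacks (about 20 optical sections at 1 µm) makes z
clipping unavoidable, so z borders are tolerated.

**Territorial volume (A).** The volume of the 3D convex hull enclosing
all extreme points of the cell.  The hull is computed over the *corner*
points of every mask voxel rather than voxel centers, with exact integer
predicates on the corner lattice (an incremental hull; candidate points
are first reduced to the per-lattice-line extremes).  The corner
convention guarantees that the hull contains the voxel union, hence
territorial volume ≥ cell volume and ramification index ≥ 1 for every
mask; a center-based hull can undercut the cell volume for thin cells.

**Cell volume (B)** is the voxel count times the physical voxel volume,
and the **ramification index (C)** is the ratio A/B — high for ramified
cells whose processes claim much more territory than they fill.

**Skeleton features (D, E).** Cells are reduced to a curve skeleton by
sequential 3D thinning under the standard (26, 6) digital topology: a
voxel may be deleted only when it is *simple* (its object neighbors form
one 26-connected component and its background face-neighbors one
6-connected component within the 18-neighborhood), so topology is
preserved exactly.  Deletion proceeds in six directional subiterations
(up/down/north/south/west/east) in deterministic scan order.  Instead of
preserving endpoints — which freezes arbitrary residual line fragments
when a compact soma erodes — the thinning anchors *isthmus* voxels: once
a voxel's object neighborhood splits into two or more components it is a
curve-interior point and is kept forever.  Blobs therefore collapse to a
single voxel (no endpoints, so a process-free amoeboid cell reports zero
branch metrics), while curves keep their interiors and lose only their
original unanchored tip voxels.  Thinning a thick tube can leave sub-voxel
side twigs; terminal spurs shorter than `prune_um` (default 2 µm) that end
at a junction are pruned.  Endpoints are skeleton voxels with exactly one
26-neighbor in the skeleton, branchpoints those with three or more.  On a
voxel lattice any junction produces a small *cluster* of branchpoint
voxels (the first steps of three arms leaving one voxel are mutually
26-adjacent), so branchpoint counts are systematically higher than a
graph-theoretic branch count; they are used comparatively, which is all
the clustering requires.

**Branch lengths (F–H).** Each endpoint is traced back to the cell
centroid *along the skeleton*: path length is the shortest-path distance
on the 26-adjacency voxel graph, with edge weights equal to the Euclidean
step between physical voxel centers, from the endpoint to the skeleton
voxel nearest the centroid.  The mean, maximum and minimum over endpoints
are reported; a skeleton without endpoints reports zeros.  A disconnected
skeleton (possible after aggressive thresholding) is handled per
component with its own root, with a warning.  Straight-line
endpoint-to-centroid chords are available via `mode = "euclidean"` for
sensitivity checks, since tracing conventions differ between tools.

## Feature table processing

Cells with any missing feature are dropped (with a logged count).
Features are z-scored with the sample (n−1) standard deviation; scaling
parameters are retained.  Because clustering uses Euclidean distance,
unscaled volumes (10^5 µm³) would swamp counts and lengths.

Redundant features are removed from the Pearson correlation matrix by
iterative pairwise elimination: while any pair exceeds the threshold
(default |r| > 0.9), the member of the worst pair with the *higher mean
absolute correlation* against all other features is dropped (ties go to
the later feature in canonical order, logged).  This is the
`findCorrelation`-style procedure; the test suite cross-checks it against
caret's exact implementation.  On calibrated synthetic tables the endpoint
count tracks the branchpoint count at r ≈ 0.97 and carries the higher
mean absolute correlation, so exactly it is removed and 7 of 8 features
survive.

## Cluster analysis

**PAM.** Partitioning around medoids under Euclidean distance.  For tiny
problems (n ≤ 40 and at most 20 000 medoid subsets) the exact optimum is
found by exhaustive enumeration — classic PAM is only a local optimizer
and demonstrably misses the global optimum on a few percent of small
random instances, so exactness is cheap insurance where it is affordable.
Larger problems use the classic greedy BUILD seeding followed by
best-improvement SWAP iterations to a local optimum; the swap search
evaluates all (medoid, candidate) pairs in O(n²) per iteration through
the nearest/second-nearest decomposition, which accepts exactly the same
swap as the naive O(k n²) scan.  Ties break toward the lowest candidate
then medoid index; assignment goes to the nearest medoid, ties to the
lowest medoid index, so results are fully deterministic.

**WCSS and the gap statistic.** The elbow curve reports the within-cluster
sum of squares of the PAM partition at each k, computed through the
pairwise identity W = Σ_r D_r/(2 n_r) with D_r the summed squared
within-cluster Euclidean distances (equal to summed squared distances to
cluster means).  The gap statistic compares log W on the data with log W*
on B reference datasets drawn uniformly over the per-feature bounding box
of the data: Gap(k) = mean_b log W*_kb − log W_k, with the usual
sd·sqrt(1 + 1/B) Monte-Carlo error.  The chosen k is the global gap
maximum; the conservative one-standard-error rule is available via
`rule = "1se"`.  A warning is raised when the maximum does not rise above
the k = 1 baseline by more than the combined Monte-Carlo error — the
signature of a structureless table.  The implementation is validated two
ways: planted three-blob data (separation ≥ 10 σ) recover k = 3 in ≥ 95 %
of seeds, and gap values agree with `cluster::clusGap` (whose log W
differs by a constant pair-counting convention that cancels in the gap).

**A candid note on gap model selection for this data shape.**  On
synthetic tables calibrated to the published per-state feature summaries
(see below), the argmax-gap rule over k = 1..8 does *not* settle on 3,
in either the 7-feature space or the embedding: the curve keeps creeping
upward.  The geometry is generic: in d dimensions the uniform reference
dispersion falls like k^(−2/d) — only ~0.08 in log W per step at d = 7 —
while splitting the dominant (ramified) cluster, whose per-feature spread
after z-scoring is comparable to the between-state separation, buys
0.10–0.14.  Isotropic, well-separated mixtures do peak at the true k
(the package's tests verify this), but the published per-state spreads
pin the anisotropy.  Those spreads are post-hoc summaries of a
partitioned morphological continuum, and a separable class mixture that
reproduces them verbatim cannot also exhibit a clean three-cluster gap
maximum.  The gap curve and chosen k are therefore reported as computed,
with the low-contrast warning where applicable, and the pipeline accepts
a fixed `k` in its configuration for the (common) situation where the
analyst fixes k = 3 on biological grounds after inspecting the curve.

**UMAP and the clustering space.** The scaled, filtered features are
embedded in 2D by uniform manifold approximation and projection (uwot),
with n_neighbors = 7, min_dist = 0.001, Euclidean metric, and a fixed
seed (single-threaded optimization, so coordinates are reproducible).
By default the pipeline clusters *on the embedding* — reduce, then
cluster — which matches the published workflow this package automates and
measurably improves class recovery on calibrated synthetic tables
(adjusted Rand index vs planted classes ≈ 0.92 on the embedding against
0.73–0.81 in the 7-feature space, where the wide ramified and rod classes
overlap).  Clustering in the scaled feature space remains available via
`cluster_space = "features"`.

**Outliers.** Within each cluster, a cell is flagged when its distance to
the medoid exceeds the cluster median plus 3 MAD-based robust standard
deviations of that cluster's distances — a scale-free rule that flags
under 2 % of points in clean Gaussian clusters.  Clusters with fewer than
5 cells are skipped with a warning.

**State assignment.** With k = 3, the activated cluster is the one with
the lowest median average branch length (ties: lower median branchpoint
count, then higher median cell volume, since activated somata enlarge);
of the remaining two, the higher median territorial volume is surveillant
and the third is primed.  The per-cluster medians behind the decision are
attached as evidence.

## Group statistics

All tests run on **per-animal** state proportions (each animal one
observation; cells are never pseudo-replicated), computed for the full
field and separately for the superficial (ROIs 1–2) and deep (ROIs 3–4)
dorsal-horn regions.  Group summaries average animals and rescale the
three state means to total exactly 100 %, with the SEM across animals
alongside.  Comparisons use the two-tailed Student's t-test with pooled
variance — consistent with the pooled-SD Cohen's *d*, whose magnitude
bands are ≤ 0.2 negligible, (0.2, 0.5] small, (0.5, 0.8] medium, > 0.8
large; Welch's correction sits behind a flag.  Normality is checked with
the Lilliefors-corrected Kolmogorov–Smirnov test (plain KS p-values are
anticonservative with estimated parameters).  The sex-by-state interaction
is assessed by a two-way ANOVA with type-II sums of squares on the
proportions; partial η² is reported together with the conversion
d = 2·sqrt(η²/(1−η²)), which is labelled a convention — interaction
"d" values have no unique definition.  P-values are reported unadjusted,
matching the single-comparison framing of the planned contrasts
(stress priming SSN vs CSN, nociceptive priming CNN vs CSN, additivity
SSN vs SSS, each per sex and pooled, plus the male/female battery per
depth region); Holm-adjusted values are appended as an extra column.
With proportions summing to 100 within each animal the sex main effect is
structurally zero; the interaction is the scientifically meaningful term.

## The synthetic-data generator

The generator emulates the study conditions end to end: 2 sexes × 4
treatment groups (SSN, CSN, SSS, CNN — stress/control × saline/NGF
injection sequences) × 4 animals × 4 ROIs, with about 27 cells per
256 × 256 × 20 µm ROI at 0.5 × 0.5 × 1 µm voxel spacing (≈ 3500 cells at
full design; the lateral pixel size is a package choice, as only the ROI's
physical extent is fixed by the acquisition it mimics).  Per-(sex, group)
mixtures over the three morphology classes are fixtures chosen to plant
the study's qualitative contrasts (females richer in ramified cells;
a stress-priming excess of amoeboid cells in male SSN), derived from
per-group cell tallies; they are not biological claims.

**Image path.** A cell is a soma (ellipsoid, elongated for the rod class)
plus tubular processes grown as persistent random walks with stochastic
branching, damped and reflected in z to respect the thin section; the
rasterized mask keeps the soma-connected component, guaranteeing a single
26-connected cell.  ROIs place cells with rejection of soma–soma overlap
(arbors may interdigitate, as in tissue) and a placement margin so that
blurred cells stay off the lateral border; stacks get Gaussian background
noise, a 0.5 µm point-spread blur, and 16-bit quantization so that TIFF
round trips are exact.  What the image path does *not* emulate: staining
chemistry, depth-dependent attenuation, anisotropic PSFs, touching-cell
splitting, and real arbors' tortuosity statistics — passing tests show the
pipeline recovers what this model plants, not that segmentation is robust
to every real-tissue artifact.

**Feature-table path.** For clustering and statistics tests at scale the
generator bypasses imaging and samples the eight features directly from
class-conditional distributions calibrated to published per-state
summaries (`state_reference_params()`): truncated normals for territorial
volume and ramification index (cell volume is their ratio, which keeps
the ramification identity and lands all three volume locations
correctly), truncated normals for branch features, exact zeros for every
branch metric of the amoeboid class, and endpoint counts built as
branchpoints plus loadings on branch length plus noise — reproducing both
the near-unit endpoint–branchpoint correlation (r ≈ 0.97) and the higher
mean absolute correlation of endpoints that makes the redundancy filter
remove endpoints rather than branchpoints.  Within-class features are
otherwise independent; the calibration targets locations and spreads, not
the full joint law of real morphometry (see the gap-statistic note above
for the structural consequence).

## Numerical choices and problem sizes

Exact integer predicates make the hull volume deterministic and exact
(a solid n³ cube yields exactly its analytic volume).  PAM accepts a swap
only below −10⁻¹²; z-scoring asserts covariance–correlation equality on
scaled tables to 10⁻⁹.  The test suite runs the calibrated table at 3072
cells, the headline gap computation at B = 50 references and reseeded
stability checks at B = 12 (the argmax decision is a comparison of means
whose Monte-Carlo error shrinks like B^(−1/2); B = 12 already puts it an
order of magnitude below the inter-k differences that matter), planted
blob recovery over 20 seeds, and 200 null-cohort replicates for the
type-I calibration of the comparison battery.

## Known limitations

Segmentation does not split touching cells (connected components only);
branchpoint counts are lattice-cluster counts, not graph branch counts;
the published per-state feature spreads cannot be reproduced verbatim by
any separable class mixture that is also cleanly recoverable (discussed
above); the interaction effect-size conversion is a labelled convention;
and Lilliefors requires n ≥ 4 rather than 3.  TIFF input is limited to
single-channel multi-page stacks — vendor formats should be converted
upstream.
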