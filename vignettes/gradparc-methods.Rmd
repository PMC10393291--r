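---
title: "Local-gradient parcellation of cortical surfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-gradient parcellation of cortical surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradparc)
```

# The problem

Functional areas of the cerebral cortex are separated by relatively sharp
transitions in resting-state functional connectivity (RSFC). `gradparc`
implements a surface-based workflow that locates these transitions and
turns them into a fine-grained parcellation, together with the evaluation
battery and downstream network/developmental analyses such parcellations
are normally subjected to. Everything operates on a triangulated spherical
cortical surface: per-vertex BOLD time courses in, per-vertex maps and
parcel tables out.

# The per-scan model

For one fMRI scan on a hemisphere with $V$ vertices:

1. **First-order RSFC.** $R_{ij}$ is the Pearson correlation between the
   time courses of vertex $i$ and cortex vertex $j$ (`compute_rsfc`).
   Vertices with zero-variance signals are flagged and propagate as
   undefined — never as silent zeros, which would create spurious
   gradients.
2. **Fisher z.** $Z = \operatorname{arctanh}(R)$ normalizes the profiles
   (`fisher_z`); correlations at $|r| = 1$ are clipped to $1 - 10^{-7}$ so
   $z$ stays finite while preserving order.
3. **Second-order connectivity.** $S_{ij}$ is the correlation between rows
   $Z_{i\cdot}$ and $Z_{j\cdot}$ (`compute_second_order`). First-order
   maps vary smoothly along the cortex; the correlation *of the maps*
   drops abruptly at areal borders, which is what makes boundary detection
   possible. The computation streams in row blocks so a 32k hemisphere is
   feasible.
4. **Visit averaging.** All second-order matrices of one visit are
   averaged (`average_visit_rsfc2`) so subjects with different scan counts
   contribute equally.
5. **Gradient matrix.** Every row of $S$ is treated as a scalar map and
   differentiated on the mesh (`gradient_matrix`): per-triangle
   linear-interpolation gradients lie in the triangle plane (the local
   tangent plane of the sphere) and their magnitudes are area-averaged to
   vertices. Triangles touching the medial wall are excluded.
6. **Watershed boundary maps.** Each gradient row is flooded
   (`watershed_boundary_map`): seeds are local minima of 3-ring
   neighborhoods, regions grow in globally ascending gradient order, and a
   vertex reachable from two or more regions at its turn is an ambiguous
   location — a putative border.
7. **Local gradient map.** The vertex-wise mean of the $V$ binary boundary
   maps (`local_gradient_map`, or `scan_gradient_map` for the whole
   per-scan pipeline). Values near 1 mark vertices that are boundaries
   from almost every seed's viewpoint.
8. **Hierarchical averaging.** Phase-encoding pairs average into session
   maps, sessions into visits, visits into age groups, and the age-group
   maps (equally weighted) into the age-independent map (`combine_maps`).
   No smoothing is applied at any averaging level.

`watershed_parcellate` applies the same flood to a group map but keeps the
region labels: basins become parcels, ambiguous vertices stay label 0 as
borders, without thresholding or manual editing. Merging of
over-segmented parcels is supported (`merge_parcels`) but only as explicit
input data — the package does not pretend to have an automatic
over-segmentation detector, because no objective criterion for one exists.

## Watershed determinism

The flood is implemented in compiled code with fully specified tie rules:
a vertex is a seed candidate when its value is $\le$ every defined vertex
within 3 edges; equal-valued, edge-connected candidate plateaus contribute
a single seed (their lowest vertex index), so a constant map yields one
region per connected component rather than an arbitrary shattering;
flooding pops vertices in ascending (value, index) order. The test suite
checks the implementation against an independently coded brute-force
flood on random fields.

# Smoothing and the resolution question

BOLD time courses are conventionally pre-smoothed on the surface with a
small Gaussian kernel, $\sigma = 2.55$ mm on a 32k surface whose vertices
sit about 2 mm apart — a kernel of about 1.275 vertex spacings. On the
desk-scale meshes this package is validated on (a 642-vertex icosphere
with ~15 mm spacing), 2.55 mm falls entirely between vertices and the
kernel degenerates to the identity, which silently *removes* a step of
the workflow. `scaled_smoothing_sigma()` therefore expresses the kernel
in resolution units: $\sigma = (2.55 / 2)\times$ mean edge length. This is
not a tuning constant; it is the same kernel measured in the mesh's own
unit. Without it, the vertex-noise floor of the gradient maps carries
systematic texture (sampling variance of correlations depends on the true
correlation, so the texture follows the planted geometry and does not
average away) and watershed seeding degrades sharply.

Smoothing itself (`smooth_scalar_map`) uses great-circle distances within
a $3\sigma$ cutoff. The kernel matrix is balanced to be doubly stochastic
(a few Sinkhorn iterations), which makes constants exact fixed points and
preserves the map mean over defined vertices — a property plain row
normalization only has approximately on irregular meshes. Medial-wall
vertices carry `NA`, receive no weight, and contribute none.

# Spherical registration

Individual local gradient maps are co-registered to their evolving
population mean (`build_group_template`): average, register each map to
the mean, resample, re-average; four outer iterations by default, with an
early stop when the mean map changes by less than $10^{-4}$. The
registration (`register_to_template`) is a deliberately simple
demons-style scheme — the displacement force is the feature residual times
the template's tangent gradient (normalized demons form), fluid-smoothed
per iteration ($\sigma = 6$ mm), with diffusion smoothing of the
accumulated displacement ($\sigma = 4$ mm), a coarse-to-fine
feature-smoothing pyramid (12, 6, 3 mm by default), step halving until no
spherical triangle inverts orientation (a cheap diffeomorphism proxy), and
a line search that accepts a step only if the feature MSE does not
increase. The monotone objective and the no-fold condition are contracts,
not aspirations: they are asserted in tests. The multi-resolution schedule
uses feature smoothing rather than mesh coarsening — the same
coarse-to-fine effect without a mesh-resampling subsystem.

All published parameters of the upstream registration tool this stands in
for are unavailable, so every knob here is explicit in
`register_params()` and the defaults are declared choices, not inferred
ones.

## A known limitation

On coarse meshes, comparing the registered template's *maximum* against
the unregistered mean's maximum is structurally biased: misalignment below
one edge length blurs the naive mean by less than the barycentric
resampling loss the registered mean must pay, and the naive maximum is an
extreme-value statistic that always finds border segments displaced along
themselves. The registered template is sharper in aligned statistics (its
values on true borders), but its raw maximum typically sits 2–3% below
the naive mean's at 642 vertices. One validation assertion documents this
shortfall; at realistic resolutions (misalignment spanning several vertex
spacings) the contrast comes out the expected way.

# Evaluation battery

* **Reproducibility** (`split_half_reproducibility`): random disjoint
  subject halves, mean maps binarized to their top 25%, dice overlap;
  1000 repetitions by default.
* **Homogeneity** (`parcel_homogeneity`): percent variance of a parcel's
  vertex connectivity profiles explained by their first principal
  component. The PCA is *uncentered* (eigendecomposition of the raw
  profile scatter): a parcel whose vertices share one profile is rank one
  and scores 100. Centering would subtract exactly the shared profile and
  grade parcels by their noise, inverting the metric's meaning.
* **Variance** (`parcel_variance`): per parcel, the sum over profile
  dimensions of the standard deviation across the parcel's vertices;
  map-level value is the parcel mean.
* **Rotation nulls** (`generate_null_parcellations`): the whole
  parcellation rigidly rotated by independent uniform angles about x, y,
  z (in that fixed order), relabeled by nearest-vertex pullback — parcel
  number preserved, sizes preserved up to resampling. A parcel losing at
  least half its vertices to the medial wall in a null is flagged for
  that null, and its null reference averages only its surviving rotated
  versions. Ensembles regenerate bit-identically from their seed.
* **Null comparison** (`null_comparison`): add-one rank p-value,
  $p = (1 + \#\{\text{nulls at or beyond}\}) / (1 + n)$.
* **Border distance** (`hausdorff_spherical`): two-sided Hausdorff
  distance between border vertex sets, in mm of great-circle distance.
* **Variability maps** (`variability_between`):
  $\mathrm{Var}_{g_1,g_2}(v) = 0.5\,(1 - \mathrm{corr}(p_{v1}, p_{v2}))$
  over 10-ring patches; vertices with under 3 jointly defined patch
  values, or constant patches, are undefined rather than zero.

# Networks and development

Parcel-level analysis follows the standard route: parcel mean time
courses (borders and medial wall excluded), per-subject parcel
correlation matrices binarized to their top 10% so every subject
contributes the same connection count, group averaging, and clustering of
connectivity profiles. The clustering is spherical k-means over cosine
similarity with restarts (`cluster_parcels`) — a documented stand-in for
the mixture-model clustering used upstream, whose parameters are not
published. The cluster number is selected by split-half stability
(`stability_curve`): 200 random splits per k over $k \in [2, 30]$,
compared with an Amari-type similarity (`amari_similarity`) built from the
k-by-k confusion matrix: the index averages row- and column-wise
$(1 - \max/\mathrm{sum})$ mismatch, normalized by $k/(k-1)$ to span
$[0, 1]$; the similarity is one minus the index, permutation-invariant and
1 exactly for identical partitions. The package emits the curve and its
peaks; it never auto-selects k, because the published selection mixes
stability with unformalized empirical factors.

Per-parcel development uses node local efficiency,
$E_{\mathrm{local}} = \frac{1}{N(N-1)}\sum_{j \ne k \in G_i} 1/L_{j,k}$,
over the neighbors-of-$i$ subgraph, with unreachable pairs contributing 0
and under-2-neighbor nodes scoring 0 by convention. Thresholds sweep
retained-connection fractions from 50% down to 5% in 1% steps (46
points); the trapezoidal AUC is normalized by the 0.45 grid span so it is
a density in $[0, 1]$ invariant to uniform weight rescaling. Age windows
are centered at whole months 2–24 with width $90 + 4(m - 2)$ days; the
increment rule gives 178 days at 24 months, not the round 182 sometimes
quoted — the stated increment is implemented and the 4-day discrepancy is
an off-by-one in month counting, not resolved silently. Month centers are
converted to days at 30.4375 days/month.

# The synthetic cohort

`synth_cohort()` generates everything the pipeline consumes: an icosphere
(default $s = 3$, 642 vertices, 100 mm radius) with a 5% polar medial-wall
cap (so null-rotation medial-wall logic is actually exercised), a planted
parcellation, network labels, per-scan time series, and a metadata table
with subject/session/visit/age/phase-encoding columns.

* **Parcels** are geodesic Voronoi regions of random seed vertices with a
  few rounds of Lloyd (centroidal) relaxation to geodesic medoids.
  Unrelaxed random seeds plant parcels down to ~7 vertices on a
  642-vertex sphere — below the resolution of 3-ring watershed seeding,
  i.e. structures no boundary method at this resolution could separate.
  Relaxation keeps the construction but plants parcels at a scale
  comparable to cortical areas at the mesh's resolution.
* **Signals** are unit-variance AR(1) series ($\rho = 0.3$, so sample
  correlations have realistic variance rather than the white-noise
  optimum): each network has a latent signal, each parcel mixes its
  network latent (weight 0.5) with a parcel-specific signal, each vertex
  mixes its parcel signal (coherence 0.9) with a private signal, plus
  i.i.d. Gaussian noise of standard deviation $1/\mathrm{SNR}$. SNR is
  the parcel-signal-to-vertex-noise sd ratio; the validation conditions
  use SNR 5, T = 300, 12 subjects with one AP/PA pair each.
* **Misalignment** is a band-limited random tangent field (white noise
  smoothed at 30 mm, tangent-projected, rescaled so the largest angular
  displacement equals the stated cap); a subject's vertices sample the
  parcel planted at their displaced position, emulating residual
  functional misalignment after folding-based registration.

What the generator does **not** emulate: hemodynamics, motion and
distortion artifacts, distance-dependent noise correlations, genuinely
fuzzy areal borders, or folding geometry (every surface is a sphere).
Passing the recovery tests therefore shows the algorithms are correctly
implemented and statistically sound at the stated noise levels — not that
real infant parcellations at 32k resolution would reach the same accuracy.

At the validation scale (desk conditions above), watershed parcellation
of the group local gradient map recovers the planted 20-parcel map at
adjusted Rand index above 0.8 across seeds, split-half stability selects
the planted network count, and the planted parcellation beats 200
rotation nulls on homogeneity (higher) and variance (lower) at rank
$p \le 0.05$ — these are exactly the checks in
`tests/testthat/test-acceptance.R`, which is also where the problem sizes
are fixed.

# Numerical conventions

* Vertex and triangle indices are 1-based in R; GIFTI files store 0-based
  triangles and are converted at the I/O boundary. Label 0 always means
  border or medial wall.
* Undefined values are `NA` everywhere, never 0.
* The sphere radius is 100 mm by convention, so Hausdorff distances and
  kernel widths are in mm; it is configurable per mesh.
* Dice of two empty sets is 1 (identical emptiness), documented in
  `dice()`.
* Single-vertex parcels: homogeneity 100, variance 0, both flagged.
* `binarize_top` keeps exactly $\lceil f N_\mathrm{defined} \rceil$
  vertices, ties broken toward lower vertex index.
* All stochastic procedures take explicit seeds and regenerate
  bit-identically.
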