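---
title: "Quantifying the foreign body reaction around implanted nerve conduits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the foreign body reaction around implanted nerve conduits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbrquant)
```

## The measurement problem

When a device is implanted into a peripheral nerve, the foreign body
reaction (FBR) builds a fibrotic capsule around it: a ring of
myofibroblasts (stained by alpha smooth-muscle actin, aSMA) forms at the
nerve edge, with macrophages (CD68) sitting somewhat deeper and axons
(beta3-tubulin) distributed through the regenerating interior. Assessing an
anti-fibrotic intervention means answering quantitative questions from
fluorescence cross-sections:

* how **thick** is the capsule, per animal;
* how does stain **intensity fall off with depth** from the implant edge,
  so that irregularly shaped capsules can be compared across animals;
* what is the **axon density** in the regenerated nerve;
* what **immune cell populations** are present (from bulk RNA-seq), and
  which genes change expression (from counts and from qPCR).

`fbrquant` implements this measurement chain. The only manual input on the
imaging side is the traced capsule edge (and, for thickness, a second inner
boundary); everything downstream is deterministic given the configuration
and seeds.

## Depth alignment

Capsules are irregular, so profiles indexed by image coordinates are not
comparable across sections. The package aligns sections by
*depth*: for every pixel inside the traced contour, the depth is the exact
Euclidean distance (in micrometers) to the nearest point of the contour
polygon (`compute_depth_map()`). This reparameterization turns any capsule
into a one-dimensional profile of intensity versus distance from the
implant edge. Distances are computed against the polygon itself
(point-to-segment, subpixel), not against a rasterized boundary, so the
depth map is exact up to the placement of pixel centers; the test suite
checks it against dense boundary resampling to 0.5 px.

Three summaries are derived from the depth map:

* `intensity_profile()` bins pixels by depth (default 1 um bins) and
  reports the mean intensity and pixel count per bin. Empty bins are `NA`,
  never zero.
* `near_edge_mean()` is the pixel-weighted mean over all pixels with depth
  at most a window `w`. The default window is **25 um**; for CD68 a
  **50 um** window is conventional because macrophages sit deeper than the
  myofibroblast ring, and a **15 um** window is also in use for near-edge
  summaries of capsule stains. All three are plain parameters; none is
  hard-coded. We deliberately weight by pixel (annulus area) rather than
  averaging binned means: "mean intensity from the edge to depth w" reads
  as a region mean, and bin-averaging would over-weight sparsely populated
  deep bins.
* `normalize_to_control()` divides each animal's near-edge mean by the
  mean of the control group, so the control group averages to exactly 1 and
  the ratios are invariant to any global intensity rescaling (gain,
  exposure).

## Capsule thickness

`capsule_thickness()` takes two traced contours — the outer capsule edge
and the inner capsule boundary — and measures, at points spaced uniformly
by arc length along the outer contour (default 360 positions), the distance
to the nearest point of the inner contour. The per-animal value is the mean
over positions. We use nearest-point distance rather than a normal-ray
intersection: it is well defined for any pair of nested polygons, does not
depend on a normal estimate at the sample point, and equals the normal-ray
length wherever the boundaries are locally parallel (the usual capsule
geometry). Contours that touch or cross are rejected rather than clamped.

## Axon counting

`sample_boxes()` draws square counting frames (default three 100 x 100 um
boxes per image, following common practice for this assay) uniformly over
all placements that fit inside the allowed region; boxes may overlap, and a
fixed seed fixes the boxes. `detect_axons()` thresholds the box
(Otsu on the box's own histogram by default, so counts are invariant to
intensity rescaling; a fixed threshold is available), labels connected
components with 8-connectivity, discards components smaller than
`min_area_px` (default 4 px at ~1 um/px, suppressing single-pixel noise),
and counts a component if and only if its **centroid** lies inside the box.
The centroid rule is the standard unbiased simplification of a counting
frame: every punctum is attributable to exactly one box regardless of how
boxes tile or overlap the section. Components are labeled on a crop padded
beyond the box edge so that a punctum straddling the edge is measured whole
before the rule is applied. Two puncta merged by blur into one component
count as one — the detector counts components, not underlying objects.
`axon_density()` converts counts to per-mm^2 densities and averages per
image; `aggregate_axon_density()` averages per animal, which is the
experimental unit for statistics.

## Immune cell-type deconvolution

Bulk expression is modeled as a linear mixture of reference cell-type
profiles: x = S f with S the genes x types signature matrix and f on the
probability simplex. `deconvolve()` solves

    minimize ||S f - x||^2  subject to  f >= 0,  sum(f) = 1

exactly, with a primal active-set quadratic program: each working set is
solved through its KKT system, variables that would go negative are clamped
at zero, and clamped variables re-enter when their Lagrange multiplier is
negative. Stationarity is checked to 1e-9. Genes are matched
case-insensitively; no transformation is applied to the expression values,
matching the linear mixing model. The solver is checked in the tests
against an exhaustive simplex grid search at 0.001 resolution and recovers
noiseless mixtures to machine precision. A rank-deficient signature (after
gene intersection) is solved through a pseudoinverse and flagged, since the
fractions are then not unique.

`aggregate_fractions()` sums fine-type fractions into major types. The
bundled `default_cell_grouping()` is a synthetic 25-type taxonomy mapping
onto six major types (granulocytes, B cells, T cells, NK cells, dendritic
cells, mono/macrophages); any signature TSV and grouping table can be
supplied instead — published mouse hematopoietic signatures are not
redistributed with the package.

## Expression arithmetic

* `filter_samples_by_rin()` keeps samples with RIN **strictly above** 3 by
  default — a sample at exactly 3.0 fails QC.
* `size_factors()` implements median-of-ratios depth normalization: for
  each sample, the median over genes (restricted to genes with a positive
  geometric mean) of count/geometric-mean. No rescaling is applied beyond
  the median. For a matrix whose columns differ only by depth, the
  recomputed factors after normalization are exactly 1; in general they are
  all equal, which is the operative idempotence property.
* `de_test()` is a deliberately simple per-gene stand-in: Welch's t on
  log2(normalized + 1) with Benjamini-Hochberg adjustment. It is **not** a
  negative-binomial analysis; its contract is calibrated type-I error on
  null data (checked at n = 6 per group over 40,000 simulated null genes),
  which is all the downstream filter requires. Genes with zero variance in
  both groups receive p = 1. BH is used because only an "adjusted p" is
  specified by the filtering convention, and BH is the default of the
  standard count-based pipelines.
* `deg_filter()` applies the three-part rule: at least a twofold change
  (|log2FC| >= 1, **inclusive** — "a minimum of a twofold change" includes
  exactly twofold; an exclusive variant is a flag), base mean **above** 3
  (strict), adjusted p **below** 0.01 (strict).
* `top_k_variable_genes()` ranks by across-sample variance of
  log2(normalized + 1) and returns the top 500 by default. Selection of
  "top differentially expressed genes" for PCA is underspecified in common
  usage; variance ranking is the standard default and is documented here as
  an interpretation, with ties broken by gene id.
* `compute_rq()` implements delta-delta-Ct: dCt per sample, averaged
  within group before differencing (the per-replicate alternative would
  propagate replicate pairing that qPCR plates do not guarantee), RQ =
  2^(-ddCt), and the strict two-fold rule: RQ above 2 or below 0.5 is
  flagged; RQ exactly 2 is not. Per-sample Ct offsets (machine drift)
  cancel in dCt by construction.

## Statistics

Animals, not sections, are the experimental unit: all per-section values
are averaged per mouse before testing. `one_way_anova()` is the classical
fixed-effects F (computed from sums of squares, so the all-equal corner
case yields F = 0 rather than 0/0). `dunnett_test()` performs many-to-one
comparisons against a named control with family-wise adjustment from the
equicorrelated multivariate-t null, evaluated by seeded Monte Carlo
(default 1e5 draws): this handles any number of groups and any imbalance,
and is validated against a direct numerical integration of the bivariate-t
case and against the established multivariate-t implementation. With one
treatment group it reduces to the pooled t test. `tukey_hsd()` uses the
studentized-range distribution. `two_way_anova()` (group x depth bin for
profile comparisons) uses marginal (Type II) sums of squares, appropriate
for the mildly unbalanced designs that arise with 7-8 mice per group; depth
is treated as a categorical bin. `t_test_groups()` is Student's t (pooled
by default) and `mann_whitney()` uses the exact null for groups of up to 8
without ties, otherwise the tie-corrected normal approximation.

## The phantom generator

`generate_nerve_phantom()` renders the geometry the capsule assay assumes:
a circular nerve disk with an annular capsule at its edge whose stain
intensity decays exponentially with depth, peak x exp(-depth/decay)
(defaults: peak 1000 a.u., decay 15 um), truncated at the capsule
thickness; disjoint axon puncta (radius 1.5 um) placed uniformly inside
the inner boundary at a known density (default 800/mm^2); and nuclei
speckle. The exponential form is a simulator choice — real capsule
profiles fall off with depth but are not parameterized in the literature —
and is exposed in `phantom_spec()`. Puncta are kept pairwise disjoint by
rejection sampling so that the ground-truth count is unambiguous; centers
are uniform over the full inner disk so that their density equals the
nominal count/area, at the cost of rim puncta straddling the boundary.
The default pixel size is 1 um/px, a plausible confocal scale; nothing
downstream depends on it being 1.

What the phantom deliberately omits: optical point-spread, channel
bleed-through, autofluorescence, 3D structure (sections are treated as
2D), and irregular capsule geometry (the contours are exact circles, so
thickness recovery tests measure algorithmic error, not tracing error).
Passing recovery tests therefore demonstrates correctness of the
measurement chain, not robustness to imaging artifacts — the latter is
bounded by the quality of the user's tracing in real data.

`generate_count_matrix()` draws negative-binomial counts (default
dispersion 0.05, typical of bulk RNA-seq after filtering) with log-uniform
base means in [5, 500], uniform size factors in [0.7, 1.4], and a
configurable fraction of genes with true log2 fold changes;
`generate_signature_and_mixtures()` builds marker-structured log-normal
signatures and Dirichlet-distributed fractions;
`generate_ct_table()` builds Ct values with per-sample machine offsets and
known delta-delta-Ct. Every generator is bitwise-deterministic under its
seed and records the truth it embedded.

## Numerical choices and degenerate inputs

* Pixel centers sit at integer coordinates, origin top-left, x rightward,
  y downward, 0-based; contour CSVs use the same convention.
* Self-intersecting contours, contours outside the image, touching
  outer/inner boundaries, empty near-edge windows, all-zero signature
  columns, negative counts, and empty design cells in the two-way layout
  are rejected with specific messages rather than silently handled.
* Ties in the nearest-point search are resolved by the first position along
  the resampled boundary; ties in variance ranking by gene id.
* The active-set solver tolerance is 1e-9 on stationarity; fractions are
  renormalized to sum exactly 1 on exit.
* Monte Carlo p-values (Dunnett) are reproducible under the caller's seed
  and never disturb the global RNG state (all generators restore it).

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to finish in minutes on one core while leaving the
statistical checks well powered: 256-420 px phantom images, 200 phantom
replicates for the axon-density unbiasedness check, 100 seeded mixtures
for deconvolution recovery, 20 x 2000 null genes for DE calibration, and
5000 replicates per test for null-rejection calibration. The `run_demo()`
pipeline (two groups of three mice, all stages) completes in well under a
minute.

## Limitations

* The DE stand-in does not model counts as negative binomial; with very
  small counts or n < 4 per group its calibration degrades.
* Capsule thickness requires a second (inner) traced boundary; the package
  does not segment the capsule automatically.
* Deconvolution assumes linear mixing in the expression space it is given;
  the package does not decide whether to deconvolve raw or normalized
  values, it records what it was given.
* The Mann-Whitney exact null is only used through n = 8 per group without
  ties.
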