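# fbrquant

Quantification of the foreign body reaction (FBR) around devices implanted
in peripheral nerve, from fluorescence micrographs and bulk expression
data.

When a conduit is implanted into a nerve, fibrosis builds a capsule — a
ring of myofibroblasts (αSMA⁺) at the nerve edge, with macrophages (CD68⁺)
deeper in the tissue and regenerating axons (β3-tubulin⁺) in the interior.
`fbrquant` turns a user-traced capsule edge plus the raw channels into the
standard readouts of this assay, and pairs every stage with a synthetic
ground-truth generator so the whole chain is testable by recovery.

## What it computes

**Depth-aligned capsule profiling.** For every pixel inside the traced
contour *C*, the depth is the exact Euclidean distance to the contour
polygon, d(p) = min_{q∈∂C} ‖p − q‖ (in μm). Profiles report mean intensity
per depth bin; the near-edge mean is the pixel-weighted mean over
{p : d(p) ≤ w} (w = 25 μm by default, 50 μm for CD68), expressed as a ratio
to the control group. Capsule thickness is the mean nearest-point distance
from arc-length-uniform positions on the outer contour to the inner
contour.

**Axon density.** Counts of thresholded (Otsu), 8-connected components
with centroid inside randomly sampled 100 × 100 μm boxes (3 per image by
default), converted to counts/mm² and averaged per image and per mouse.

**Immune cell-type deconvolution.** Given a signature matrix *S* (genes ×
cell types), fractions solve

    f̂ = argmin ‖S f − x‖²   s.t.  f ≥ 0,  Σ f = 1

by an exact active-set quadratic program, with fine types aggregated into
six major types (granulocytes, B, T, NK, dendritic, mono/macrophages).

**Expression arithmetic.** RIN > 3 sample QC; median-of-ratios size
factors; a calibrated per-gene Welch-t stand-in on log2(normalized + 1)
with BH adjustment; the DEG rule |log2FC| ≥ 1, base mean > 3, adjusted
p < 0.01; top-500-variance gene selection and PCA; qPCR relative
quantification RQ = 2^(−ΔΔCt) with the strict two-fold rule (RQ > 2 or
< 0.5).

**Statistics.** One-way ANOVA, Dunnett (Monte-Carlo multivariate-t) and
Tukey post hoc tests, Type-II two-way ANOVA for group × depth profiles,
Student's t, Mann–Whitney U — all on per-mouse values.

## Worked example

```r
library(fbrquant)

# a synthetic nerve cross-section with known truth
sp <- phantom_spec(nerve_radius_um = 100, capsule_thickness_um = 40,
                   axon_density_per_mm2 = 800, seed = 42)
ph <- generate_nerve_phantom(sp)

capsule_thickness(ph$outer, ph$inner)
#> <fbr_thickness> mean 40.00 um over 360 positions (sd 0.00)

dm <- compute_depth_map(dim(ph$channels$asma), ph$outer)
near_edge_mean(ph$channels$asma, dm, 25)
#> [1] 505.765

intensity_profile(ph$channels$asma, dm, bin_width_um = 5,
                  max_depth_um = 25)[, 1:4]
#>   depth_lo_um depth_hi_um mean_intensity pixel_count
#> 1           0           5          851.9        3064
#> 2           5          10          610.4        2908
#> 3          10          15          437.3        2752
#> 4          15          20          313.4        2588
#> 5          20          25          224.9        2416

mask <- !is.na(dm$depth_um) & dm$depth_um >= 40     # inner nerve region
boxes <- sample_boxes(mask, side_um = 50, n_boxes = 3, seed = 42)
axon_density(ph$channels$tubb3, boxes)$per_box
#>   box_id count density_per_mm2
#> 1      1     2             800
#> 2      2     1             400
#> 3      3     2             800
```

The thickness comes back at the phantom's true 40 μm; the profile shows
the capsule stain decaying from the edge inward (the phantom's exponential
with a 15 μm length constant); the per-box axon densities scatter around
the true 800/mm² with small-box Poisson noise — per-mouse averaging over
images is what the pipeline reports.

Deconvolution on synthetic mixtures:

```r
g <- generate_signature_and_mixtures(n_genes = 150, n_types = 25,
                                     n_samples = 2, noise_sd = 0.2, seed = 42)
fr <- deconvolve(g$mixtures, g$signature)
subset(aggregate_fractions(fr), sample == "sample_1")
#>      sample       major_type fraction
#> 1  sample_1          b_cells   0.2007
#> 3  sample_1  dendritic_cells   0.0188
#> 5  sample_1     granulocytes   0.3587
#> 7  sample_1 mono_macrophages   0.0786
#> 9  sample_1         nk_cells   0.1061
#> 11 sample_1          t_cells   0.2371
```

A full demo pipeline (phantom images, counts, signatures, Ct tables →
every stage, tidy CSVs, JSON summary) runs with:

```r
run_demo("demo_out", seed = 1)
```

or from the shell: `Rscript inst/cli/fbrquant.R demo --out demo_out`.
Other CLI verbs (`capsule`, `axons`, `deconv`, `expr`, `rq`, `stats`,
`run`) are thin wrappers over the same functions; see the header of
`inst/cli/fbrquant.R`.

## Documentation

The methods vignette (`vignettes/fbr-quantification.Rmd`) describes the
models and assumptions, every tunable parameter with units and defaults,
what the phantom generator does and does not emulate, and the package's
numerical choices and limitations.
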