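Package: fbrquant
Title: Quantification of the Foreign Body Reaction Around Implanted Nerve
    Conduits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Edge-aligned quantification of the fibrotic capsule that forms
    around implanted nerve conduits, from user-traced contours on
    fluorescence micrographs: per-pixel depth maps, stain-intensity versus
    depth profiles, near-edge mean intensities normalized to a control
    group, and capsule thickness. Includes automated axon counting in
    randomly sampled boxes of beta3-tubulin images, simplex-constrained
    least-squares deconvolution of bulk expression into immune cell-type
    fractions, size-factor normalization and differential-expression
    filtering of count matrices, qPCR relative quantification with the
    two-fold rule, and the group-comparison statistics used alongside
    (one-way and two-way ANOVA, Dunnett and Tukey post hoc tests, t and
    Mann-Whitney tests). A synthetic phantom generator provides images,
    contours, signatures, count matrices and Ct tables with known ground
    truth for recovery-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tiff,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    DESeq2,
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
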