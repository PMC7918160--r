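Package: gtvAgree
Title: Interobserver Agreement and PET-Threshold Delineation of Gross
    Tumor Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing interobserver variability in gross tumor
    volume (GTV) contouring and for background-relative PET SUV-threshold
    automatic tumor delineation. Provides voxel-grid image and mask
    containers with NIfTI-1 input/output, confusion-count agreement
    metrics (Dice similarity coefficient, precision, sensitivity,
    specificity), mean and maximum surface distance-to-agreement on
    anisotropic grids, rigid nearest-neighbour mask transfer between PET
    and planning-CT grids, a pairwise no-gold-standard comparison design
    with one-way ANOVA and Wilcoxon rank-sum statistics, and a synthetic
    PET/CT phantom cohort generator with simulated observers of
    calibrated agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Segmentation, Visualization
RoxygenNote: 7.3.3
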