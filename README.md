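# gtvAgree

Interobserver agreement analysis and background-relative PET-threshold
delineation of gross tumor volumes (GTVs).

## The problem

When several radiation oncologists contour the same tumor — for example a
locally recurrent pancreatic cancer that is hard to tell apart from
postoperative fibrosis on CT — their gross tumor volumes can differ
substantially. Because target definition is subjective there is no gold
standard, so variability has to be quantified *pairwise*: each observer's
contour is compared against every other observer's. High-contrast PET
tracers (such as fibroblast-activation-protein inhibitors, FAPI) suggest an
alternative: segment the tumor automatically by thresholding the
standardized uptake value (SUV) relative to the patient's own healthy-tissue
background, and compare the automatic volumes with the manual ones.

`gtvAgree` implements this whole analysis as a reusable, tested pipeline:

- **Voxel data model** — S4 classes `ImageGrid`, `SUVImage`, `BinaryMask`,
  `StructureSet`, `RigidTransform`; NIfTI input/output; volumes in ccm.
- **Automatic delineation** — background SUV *b* from a region of interest;
  the GTV at multiplier *m* is the set of voxels with SUV ≥ *m·b*
  (defaults *m* ∈ {1.5, 2.0, 2.5}), cleaned by 26-connected component
  filtering and replayable manual-correction edit lists.
- **Agreement metrics** — for an ordered pair (test, reference):
  DSC = 2·TP/(2·TP+FP+FN), precision = TP/(TP+FP), sensitivity =
  TP/(TP+FN), specificity = TN/(TN+FP) over an explicit evaluation region;
  mean and maximum surface distance-to-agreement (DTA, in cm; the directed
  maximum is the directed Hausdorff distance between surface voxel centers).
- **Rigid transfer** — nearest-neighbour resampling of masks from the PET
  grid to the planning-CT grid through a per-patient rigid transform.
- **Statistics** — the k·(k−1) ordered pairwise design (k−1 comparisons per
  observer per patient), per-observer mean/sd summaries, one-way ANOVA
  across observers per metric, and Wilcoxon rank-sum comparisons of manual
  vs automatic GTV sizes.
- **Synthetic phantoms** — PET/CT phantom cohorts with Gaussian-profile
  lesions (so the three thresholds genuinely differ), simulated observers
  with calibrated expected pairwise DSC, and ground-truth transforms; used
  to validate every stage against closed-form geometry.

For a Gaussian uptake profile with background B, peak P and profile sd σ,
the threshold surface at multiplier *m* is the sphere of radius

    r_m = σ √( 2 ln( (P − B) / (B (m − 1)) ) )

which makes the automatic segmentation analytically checkable.

## Worked example

```r
library(gtvAgree)

## a noiseless phantom: background SUV 1, one lesion (peak 9, sigma 10 mm)
ph  <- generatePhantom(phantomSpec(noise_sd = 0), seed = 1)
b   <- backgroundSUV(ph$suv, backgroundROI("sphere", c(20, 20, 20), 6))
gtvs <- generateFapiGTVs(ph$suv, NULL, thresholdSpec(b))
sapply(gtvs, volumeCcm)
#>    1.5      2    2.5
#> 54.208 35.328 25.472
```

The three automatic GTVs shrink as the threshold rises and agree with the
analytic sphere volumes (54.70, 35.53, 25.66 ccm) to within about 1% at
2 mm voxels. A full synthetic study — 7 patients, 6 observers calibrated to
a mean pairwise DSC of 0.60 — runs in about a minute:

```r
res <- runPipeline(list(mode = "synthetic"), "demo_out", seed = 1)
res$anova
#>        metric         f df1 df2    p_value
#> 1         dsc 0.7209515   5 204 0.60839735
#> 2   precision 1.9885729   5 204 0.08174329
#> 3 sensitivity 2.1751614   5 204 0.05825953
#> 4 specificity 3.0335687   5 204 0.01154691
#> 5 mean_dta_cm 1.5171743   5 204 0.18585809
#> 6  max_dta_cm 1.2624207   5 204 0.28156423
head(res$volumes)
#>   source median_ccm min_ccm max_ccm
#> 1    RO1     30.384   8.475  56.742
#> 2    RO2     31.362   8.010  51.882
#> ...
```

`res$records` holds one row per ordered observer pair and patient (210 rows
here: 6 observers × 5 comparisons × 7 patients) with all six agreement
metrics; `res$volume_comparison` holds one Wilcoxon rank-sum result per
(observer, threshold) pair. The same run is available from the shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml --out demo_out
```

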