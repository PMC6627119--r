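# osteoquant

Adaptive CT-based skeletal segmentation and SPECT tumor-burden
quantification for bone-metastatic disease.

## The problem

In metastatic castration-resistant prostate cancer (CRPC), estimating the
skeletal tumor burden and the avidity of metastases for bone-seeking
tracers is central to staging and to predicting the benefit of
bone-targeted radionuclide therapy (e.g. ²²³RaCl₂). Hybrid SPECT/CT
provides both anatomy (CT density in Hounsfield units) and function
(tracer counts), but separating osteoblastic metastases from normal bone
by hand is impractical at whole-skeleton scale.

`osteoquant` implements an adaptive, CT-driven segmentation of the
skeleton into three compartments and reads the tracer signal of each
compartment on the co-registered SPECT volume:

- **C_Vol** — cortical bone: in every axial slice, the bone outer border
  is detected where the HU profile crosses a surface threshold (default
  150 HU), and a 2-pixel ring inward of the border is sampled as cortex;
- **B_Vol** — normal trabecular bone: interior voxels with
  30 ≤ HU < cutoff;
- **M_Vol** — osteoblastic metastases: interior voxels with
  HU ≥ cutoff, where the *cutoff is the mean HU of the structure's own
  cortical rim* (metastatic bone is assumed at least as dense as cortex);
- purely lytic areas (HU < 30), enclosed hypodense cavities (spinal
  canal, bone cysts) and operator-marked benign hyperdensities are
  excluded from every compartment.

Derived quantities follow the standard definitions:
S_Vol = C_Vol + B_Vol + M_Vol and INV% = 100 · M_Vol / B_Vol (percent
invasion of the trabecular space). Compartment masks are exported onto
the SPECT grid as fractional-occupancy maps and mean counts/voxel are
computed as Σ(occupancy·counts)/Σ(occupancy) on the native SPECT grid.

A seeded digital phantom generator (`phantomSpec()`,
`generatePhantom()`, `phantomSuite()`) produces co-registered CT/SPECT
pairs with ground-truth labels so that every stage is testable without
patient data, and a statistics layer (`rocAuc()`, `bestThreshold()`,
`pearsonR()`, `unpairedTTest()`, `chiSquared()`, `cohortSummary()`,
`classifyResponse()`, cohort simulators) reproduces the typical
response-analysis workflow (PD/SD/PR classification, ROC with
Youden-index threshold selection).

## Worked example

```r
library(osteoquant)

ph  <- generatePhantom(phantomSpec(seed = 42))   # CT + SPECT + truth
seg <- segmentSkeleton(ph$ct)                    # adaptive segmentation
seg
#> SegmentationResult
#>   background               4022806 voxels    13577.0 mL
#>   cortical                   42513 voxels      143.5 mL
#>   trabecular                 94247 voxels      318.1 mL
#>   metastasis                 32639 voxels      110.2 mL
#>   excluded_canal              2026 voxels        6.8 mL
#>   excluded_calcification        73 voxels        0.2 mL
#>   adaptive cutoffs: 200 structure-slices, median 474.2 HU

report <- regionalReport(seg, ph$ct, ph$spect, ph$regions)
#>        region compartment volume_ml mean_hu mean_counts_per_voxel
#>    whole_body    cortical    138.24   474.4                 279.7
#>    whole_body  trabecular    314.32   250.7                 459.8
#>    whole_body  metastasis    110.09   590.3                 899.8
#>         axial    cortical     95.15   474.3                 281.3
#>         axial  trabecular    268.31   250.6                 464.3
#>         axial  metastasis    110.09   590.3                 899.8
#>  appendicular    cortical     43.09   474.7                 276.3
#>  appendicular  trabecular     46.01   251.1                 433.8
#>  appendicular  metastasis      0.00      NA                    NA
#> whole-body S_Vol 562.6 mL, INV% 35.0
```

Reading the output: the phantom's metastatic inclusions (truth
110.3 mL) are recovered as M_Vol = 110.1 mL (Dice 0.999 against the
ground-truth mask); their mean density (590 HU) and uptake
(≈900 counts/voxel) sit well above trabecular bone (251 HU,
≈460 counts/voxel), reproducing the expected compartment ordering.
Volumes are additive (whole-body = axial + appendicular; the skull is
excluded from whole-body reports), and the per-structure adaptive
cutoffs are returned in `segCutoffs(seg)` for audit.

A command-line interface wraps the same functions
(`inst/exec/osteoquant`):

```sh
osteoquant phantom  --scenario clean --seed 42 --out work/
osteoquant segment  --ct work/clean_ct.nii.gz --out work/seg/
osteoquant quantify --ct work/clean_ct.nii.gz \
    --spect work/clean_spect.nii.gz --labels work/seg/labels.nii.gz \
    --region-map work/clean_regions.nii.gz --out work/report/
osteoquant stats --cohort inst/extdata/synthetic_cohort.csv \
    --group-by superscan --roc b_counts:progression --out work/stats/
```

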