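---
title: "Adaptive skeletal segmentation and SPECT quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive skeletal segmentation and SPECT quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoquant)
```

## The model

`osteoquant` segments the skeleton on CT by exploiting a single anatomical
assumption: compact (cortical) bone is the most X-ray-attenuating tissue
in the body, so a stark HU discontinuity separates soft tissue from the
bone surface. Each axial slice is processed independently:

1. **Border detection.** Supra-threshold voxels
   (HU ≥ `surfaceHuThreshold`) are grouped into connected structures;
   the outer contour of each structure is the bone border and the region
   it encloses (holes filled) is the bone cross-section. This is the
   contour-closure equivalent of scanning each image row and marking
   where the HU profile first crosses the threshold, and the two agree
   exactly on convex structures (the test suite checks this against a
   literal raster-scan oracle).
2. **Cortical rim.** A ring of `rimThicknessPx` pixels (default 2)
   sampled inward from the border is labelled cortical bone (C_Vol).
3. **Adaptive cutoff.** The arithmetic mean HU of that rim is the
   structure's cutoff. The biological premise is that osteoblastic
   metastases are at least as dense as cortex.
4. **Interior classification.** Interior voxels with HU ≥ cutoff are
   metastasis (M_Vol); voxels with 30 ≤ HU < cutoff are normal
   trabecular bone (B_Vol); voxels below 30 HU are purely lytic areas
   and are removed automatically.
5. **Cavity exclusion.** Connected hypodense cavities that are fully
   enclosed by bone in-plane — the spinal canal, bone cysts — are
   excluded from every compartment.
6. **Operator exclusions.** A manual mask removes benign hyperdensities
   (osteophytes, osteochondrosis, implants); voxels at or above
   `metalHuMin` are *flagged* as metal candidates but never removed
   automatically.

Derived outputs: S_Vol = C_Vol + B_Vol + M_Vol (exclusions count toward
nothing) and INV% = 100·M_Vol/B_Vol. Compartment masks are exported to
the co-registered SPECT grid as *fractional occupancies* (exact
axis-aligned box overlaps, conserving volume), and mean counts/voxel is
the occupancy-weighted mean on the native SPECT grid.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `surfaceHuThreshold` | 150 | HU | Above soft tissue (≈40 ± 15) and fat, below trabecular bone (≈250), so the threshold crossing sits on the soft-tissue/cortex edge. The source method specifies only "a sharp variation of HU"; a fixed crossing makes the border testable against a raster oracle. |
| `rimThicknessPx` | 2 | pixels | The cortical ring is specified in pixels, not millimetres; at a typical ~1 mm-class CT pixel this covers the cortical shell of most bones. |
| `lyticHuMax` | 30 | HU | Voxels *strictly below* 30 HU are removed; HU exactly 30 is retained as bone (the exclusion is "inferior to 30"). |
| `canalHuMax` | 100 | HU | Upper bound on the mean HU of an enclosed cavity (canal/cyst contents: water-to-soft-tissue range). |
| `minBoneComponentPx` | 20 | pixels | Per-slice area floor; together with the requirement of a non-empty interior this rejects vascular calcifications and isolated specks at the border-detection stage. |
| `metalHuMin` | 2500 | HU | Above any biological mineralisation; flag-only because implants are an operator decision. |
| `cutoffScope` | `per_component_slice` | — | The cutoff is computed per bone structure per slice (the method samples "this cortical volume" and classifies "the inside of this volume"); `global` pools all rims, and `globalCutoff` allows a fixed value (used for monotonicity analyses). |

## Numerical choices

- **Erosion metric.** The rim is defined by iterated 3×3 (Chebyshev)
  erosion: a pixel is rim iff its Chebyshev distance to the component's
  complement is < `rimThicknessPx`. Pixels outside the image count as
  background, so edge-touching structures still erode. The acceptance
  measurement peels with the same one-pixel erosion, so "2-pixel ring"
  is exact by construction, and a brute-force distance-transform oracle
  verifies the equivalence in the tests.
- **Connectivity.** 8-connectivity in-plane (structures), 26-connectivity
  in 3D (cavities, lesion components in response classification).
- **Boundary handling.** HU = 30 is trabecular; HU exactly equal to the
  cutoff is metastasis ("at least equal").
- **Cavity rule.** Candidates are 3D components of automatically removed
  hypodense voxels (HU < 30 core); a component is relabelled
  `excluded_canal` when its mean HU < `canalHuMax` and no voxel has an
  in-plane 4-neighbour outside the segmented bone region. Keying on the
  sub-30 core keeps trabecular voxels in the 30–100 HU range in B_Vol
  (otherwise low-density marrow would be silently dropped); hypodense
  areas breaching the cortex keep the lytic label.
- **Degenerate inputs.** An all-air or flat slice yields an empty
  segmentation without error; a structure whose rim mean does not exceed
  `lyticHuMax` raises a "degenerate cortex" error; an empty cortical
  mask is an error rather than a silent NaN cutoff.
- **Mean HU ordering.** On discretised circular bones the 2-pixel rim
  dips into trabecular voxels along diagonal directions, so measured
  cortical means (and hence cutoffs) sit somewhat below the nominal
  cortical HU (on the default phantom: ≈474 vs a cortical mean of 531).
  This is a faithful property of a pixel-ring cortex sample; it lowers
  the cutoff conservatively (metastases at ≈590 HU remain far above,
  trabecular bone at ≈250 far below).

## The phantom: what it emulates and what it does not

`phantomSpec()` describes a single synthetic SPECT/CT study on a
256×256×64 CT grid at 1.5 mm and a 128×128 SPECT matrix at 5×5 mm
in-plane: a bulky pelvis-like bone mass (hip region) carrying two
confluent metastatic inclusions (r = 26/22 mm; bulky confluent pelvic
disease is typical of the high tumour burdens seen in advanced CRPC,
where whole-skeleton M_Vol of hundreds of mL is common) and two lytic
holes, a vertebral-column surrogate with an enclosed hypodense canal and
a small metastasis, two appendicular shafts, a skull surrogate and
extra-skeletal calcification specks. Compartment means default to
cohort-typical values: HU 531/251/590 (cortical/trabecular/metastasis)
and counts/voxel 271/462/939, with extra-skeletal background at 50
counts. The resulting whole-body INV% (~35) sits inside the reported
27 ± 20 cohort range.

**Noise model.** Published compartment spreads (e.g. 590 ± 136 HU for
metastases) are *between-patient* standard deviations of per-patient
means, not voxel-level noise; a single study does not sample them. The
phantom therefore uses the published values as compartment means, adds
voxel-level Gaussian noise of 40 HU for bone compartments (typical
low-dose CT quantum noise), and leaves the between-patient spreads to
the cohort simulators (`simulateCohort()`, `simulateResponseCohort()`),
which use the published ± values verbatim. SPECT counts keep the
published per-compartment SDs as voxel noise (nothing classifies on
counts, and means over thousands of voxels are insensitive to it), with
optional Poisson resampling and an optional Gaussian PSF for the
limited resolution of the single-photon technique.

**What passing phantom tests do not show.** The phantom has piecewise-
constant compartments with sharp borders, no reconstruction artefacts,
no patient motion, no bone-marrow heterogeneity, no degenerative
sclerosis, and geometrically simple bones. Recovery of its parameters
demonstrates that the implementation embodies the stated rules and is
quantitatively self-consistent — not that the method achieves any
particular accuracy on clinical images.

**Skull caps.** In tangential slices through the top of a closed
calvarium-like shell the whole cross-section is cortical; the interior
classifier then sees cortical-density voxels above the cutoff and marks
a few false metastasis voxels. This is an inherent slice-wise property
(and one reason the skull is excluded from analysis); whole-body reports
exclude the skull via the region map, and hip bones are pooled with the
axial skeleton in the default grouping.

## Statistics layer

- **ROC/AUC** is computed from pairwise concordance (ties credited ½),
  so it is exactly the normalised Mann–Whitney statistic and exactly the
  trapezoidal area of the stored curve. `direction = "low"` covers
  scores where low values indicate the positive class — progressive
  disease shows *lower* counts/voxel than stable/responding disease.
- **Best threshold** maximises Youden's J, breaking ties toward higher
  specificity, and returns the midpoint of the separating score gap.
  The ROC positives are the PD patients, with SD and PR pooled as
  negatives.
- **Tests.** Classical unpaired Student's t (equal variances), Pearson's
  r with the t transform at n−2 df, Pearson chi-squared without
  continuity correction; all two-sided at α = 0.05 with no multiplicity
  correction — reproducing the conventional reporting style of the
  source analyses, not endorsing it.
- **Response classification.** PD iff any follow-up metastasis component
  has zero overlap with the baseline mask dilated by one SPECT voxel
  (tolerating registration jitter); otherwise PR iff whole-body M_Vol
  mean counts dropped by ≥ 25% (`uptakeDropFraction`, the operational
  stand-in for "visibly diminished uptake", which has no published
  number); otherwise SD.

## Design decisions on open points

- **Co-registration** is assumed (hybrid acquisition); only world-extent
  overlap is validated, and no registration is performed.
- **Counts grid.** Compartment counts are read on the native SPECT grid
  through fractional occupancy (interpolating counts to CT resolution
  would fabricate sub-resolution count statistics); `countsGrid = "ct"`
  is available for comparison.
- **Fused SPECT input.** Multi-bed SPECT acquisitions are expected as a
  single fused volume; seam blending is out of scope.
- **DICOM ingestion** is not implemented; volumes are exchanged as NIfTI
  with a JSON label-code sidecar.

## Problem sizes and runtime

The default phantom (256×256×64 CT) generates in ~4 s and segments in
~6 s on one CPU; the full test suite (≈1100 assertions, including two
full-size phantom analyses, 100-case ROC oracle sweeps and 200-replicate
cohort simulations) runs in under two minutes. Property tests use
compact single-bone phantoms (128×128×24) where full scale adds nothing
to the property under test.

## Known limitations

- Slice-wise processing: no through-plane rim, and tangential caps of
  closed shells are misread (see above).
- Purely lytic metastases are excluded, not counted as tumour — the
  method quantifies osteoblastic disease only.
- No partial-volume correction beyond fractional occupancy; thin rims on
  a 5 mm SPECT grid mix with neighbouring tissue, which is why cortical
  counts are reported low.
- No calibration of counts to activity concentration (SUV-style); counts
  are comparable within a study, not across scanners.
- Anatomical region labels are an input (or phantom output), not
  computed.
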