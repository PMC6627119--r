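Package: osteoquant
Title: Adaptive CT Skeletal Segmentation and SPECT Tumor-Burden Quantification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partitions the skeleton on X-ray CT into cortical bone, normal
    trabecular bone and osteoblastic metastases using adaptive
    Hounsfield-unit thresholding (per-structure mean cortical density as the
    metastasis cutoff), exports the resulting compartment masks onto
    co-registered SPECT volumes as fractional-occupancy maps, and reports
    compartment volumes (mL), mean HU, mean tracer counts/voxel and percent
    trabecular invasion per skeletal region. Includes a seeded digital
    SPECT/CT phantom generator with ground-truth labels, and a statistics
    layer (Pearson correlation, unpaired t, chi-squared, ROC/AUC with
    Youden-index threshold selection, PD/SD/PR response classification,
    cohort simulation) for response analyses in metastatic
    castration-resistant prostate cancer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Segmentation, Visualization
RoxygenNote: 7.3.3
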