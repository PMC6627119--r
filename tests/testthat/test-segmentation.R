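test_that("border detection matches the raster-scan oracle on convex shapes", {
    cfg <- segmentationConfig()
    shapes <- list(
        makeAnnulusSlice(64, rOut = 20, rIn = 16, huRing = 800),
        makeDiscSlice(64, r = 15, hu = 700),
        makeDiscSlice(48, r = 10, hu = 300),
        makeAnnulusSlice(80, rOut = 30, rIn = 25, huRing = 600, huIn = 250))
    for (sl in shapes) {
        det <- detectBoneBorder(sl, cfg)
        expect_length(det$components, 1)
        oracle <- rasterScanOracle(sl, cfg@surfaceHuThreshold)
        expect_equal(det$components[[1]]$filled, oracle$filled)
        expect_equal(det$components[[1]]$border, oracle$border)
    }
})

test_that("border detection ignores flat slices and small hyperdense specks", {
    cfg <- segmentationConfig()
    flat <- matrix(40, 32, 32)
    expect_length(detectBoneBorder(flat, cfg)$components, 0)

    speck <- matrix(0, 32, 32)
    speck[10:11, 10] <- 900; speck[10, 11] <- 900  # 3-px calcification
    det <- detectBoneBorder(speck, cfg)
    expect_length(det$components, 0)
    expect_equal(sum(det$discarded), 3)

    # a ring is kept even if a speck coexists in the slice
    both <- makeAnnulusSlice(64, rOut = 18, rIn = 15, huRing = 800)
    both[4:5, 4] <- 900
    expect_length(detectBoneBorder(both, cfg)$components, 1)
})

test_that("cortical rim equals the Chebyshev distance-transform layers", {
    disc <- makeDiscSlice(40, r = 10, hu = 1) >= 1
    parts <- extractCorticalRim(disc, 2L)
    dist <- chebyshevDistOracle(disc)
    expect_equal(parts$rim, disc & dist <= 2)
    expect_equal(parts$interior, dist > 2)
    expect_equal(sum(parts$rim), sum(disc) - sum(dist > 2))

    # 20 x 10 rectangle, thickness 2: interior is the inner 16 x 6 = 96 px
    rect <- matrix(FALSE, 30, 20); rect[6:25, 6:15] <- TRUE
    parts2 <- extractCorticalRim(rect, 2L)
    expect_equal(sum(parts2$interior), 96)
    inner <- matrix(FALSE, 30, 20); inner[8:23, 8:13] <- TRUE
    expect_equal(parts2$interior, inner)

    # component of radius <= rim thickness: all rim, empty interior
    small <- matrix(FALSE, 10, 10); small[4:6, 4:6] <- TRUE
    parts3 <- extractCorticalRim(small, 2L)
    expect_equal(parts3$rim, small)
    expect_false(any(parts3$interior))
})

test_that("adaptive cutoff is the mean cortical HU", {
    expect_equal(adaptiveCutoff(matrix(c(520, 542, 0, 0), 2),
                                matrix(c(TRUE, TRUE, FALSE, FALSE), 2)), 531)
    expect_equal(adaptiveCutoff(matrix(500, 5, 5),
                                matrix(TRUE, 5, 5)), 500)
    expect_error(adaptiveCutoff(matrix(1, 2, 2), matrix(FALSE, 2, 2)),
                 "empty cortical mask")
    # sampling distribution: rim ~ N(531, 92^2), n = 500
    set.seed(7)
    v <- matrix(rnorm(500, 531, 92), 20, 25)
    cut <- adaptiveCutoff(v, matrix(TRUE, 20, 25))
    expect_lt(abs(cut - 531), 3 * 92 / sqrt(500))
})

test_that("interior classification honours the HU boundaries", {
    cfg <- segmentationConfig()
    hu <- matrix(c(29, 30, 531, 530.999, 800, 10), 2, 3)
    lab <- classifyInterior(hu, matrix(TRUE, 2, 3), cutoff = 531, cfg)
    cls <- segClasses()
    expect_equal(as.vector(lab),
                 as.vector(cls[c("excluded_lytic", "trabecular",
                                 "metastasis", "trabecular", "metastasis",
                                 "excluded_lytic")]),
                 ignore_attr = TRUE)
    # all-trabecular interior below the cutoff gives zero metastasis
    lab2 <- classifyInterior(matrix(250, 4, 4), matrix(TRUE, 4, 4), 531, cfg)
    expect_equal(sum(lab2 == cls[["metastasis"]]), 0)
    expect_error(classifyInterior(hu, matrix(TRUE, 2, 3), cutoff = 25, cfg),
                 "degenerate cortex")
})

test_that("enclosed hypodense cavities are sorted out as canal/cyst", {
    # vertebra-like ring with an enclosed HU-20 cavity and a second cyst
    sl <- makeAnnulusSlice(64, rOut = 22, rIn = 19, huRing = 600, huIn = 250)
    cx <- 32.5
    r2a <- outer((seq_len(64) - cx + 8)^2, (seq_len(64) - cx)^2, "+")
    r2b <- outer((seq_len(64) - cx - 8)^2, (seq_len(64) - cx)^2, "+")
    sl[r2a <= 4^2] <- 20   # canal
    sl[r2b <= 3^2] <- 25   # cyst surrogate
    ct <- sliceToCT(sl, nz = 4)
    seg <- segmentSkeleton(ct)
    cls <- segClasses()
    labs <- volData(segLabels(seg))
    expect_gt(sum(labs == cls[["excluded_canal"]]), 0)
    expect_equal(sum(labs == cls[["excluded_lytic"]]), 0)
    # both cavities relabelled: no sub-30 voxel left in a bone compartment
    bone <- labs %in% cls[c("cortical", "trabecular", "metastasis")]
    expect_true(all(volData(ct)[bone & labs != cls[["cortical"]]] >= 30))

    # no hypodense component: labels unchanged by the canal pass
    sl2 <- makeAnnulusSlice(64, rOut = 22, rIn = 19, huRing = 600,
                            huIn = 250)
    seg2 <- segmentSkeleton(sliceToCT(sl2, nz = 2))
    seg2b <- excludeSpinalCanal(seg2, sliceToCT(sl2, nz = 2))
    expect_identical(volData(segLabels(seg2)), volData(segLabels(seg2b)))
})

test_that("manual exclusions relabel voxels and metal is flagged not removed", {
    ph <- generatePhantom(tinyPhantomSpec(seed = 31))
    seg <- segmentSkeleton(ph$ct)
    cls <- segClasses()

    empty <- array(0L, dim(volData(ph$ct)))
    seg0 <- applyManualExclusions(seg, empty)
    expect_identical(volData(segLabels(seg0)), volData(segLabels(seg)))

    # excluding the metastasis blob removes its volume from M_Vol exactly
    met <- volData(segLabels(seg)) == cls[["metastasis"]]
    segX <- applyManualExclusions(seg, array(as.integer(met), dim(met)))
    v0 <- compartmentVolumes(seg); v1 <- compartmentVolumes(segX)
    expect_equal(v1[["metastasis"]], 0)
    expect_equal(v1[["excluded_manual"]],
                 v0[["excluded_manual"]] + v0[["metastasis"]])
    expect_equal(v1[["trabecular"]], v0[["trabecular"]])

    expect_error(applyManualExclusions(seg, array(0L, c(2, 2, 2))),
                 "grid mismatch")

    # an HU-3000 implant appears in the metal-candidate list
    spec <- tinyPhantomSpec(seed = 32)
    spec@implants <- list(list(center = c(80, 96, 18), r = 5))
    ph2 <- generatePhantom(spec)
    seg2 <- segmentSkeleton(ph2$ct)
    expect_gt(nrow(metalCandidates(seg2)), 0)
    huMetal <- volData(ph2$ct)[metalCandidates(seg2)]
    expect_true(all(huMetal >= segConfig(seg2)@metalHuMin))
})

test_that("segmentation partitions the volume with the HU ordering built in", {
    ph <- generatePhantom(tinyPhantomSpec(seed = 41, lytic = list(
        list(center = c(110, 96, 12), r = 5))))
    seg <- segmentSkeleton(ph$ct)
    labs <- volData(segLabels(seg))
    cls <- segClasses()
    # exclusive and exhaustive by construction of a single label array
    expect_true(all(labs %in% cls))
    hu <- volData(ph$ct)
    # per-structure: min HU over metastasis >= cutoff > max trabecular HU
    cuts <- segCutoffs(seg)
    for (z in unique(cuts$slice)) {
        sl <- labs[, , z]; hz <- hu[, , z]
        cutz <- min(cuts$cutoff_hu[cuts$slice == z])
        if (any(sl == cls[["metastasis"]]))
            expect_gte(min(hz[sl == cls[["metastasis"]]]), cutz)
        if (any(sl == cls[["trabecular"]]))
            expect_lt(max(hz[sl == cls[["trabecular"]]]),
                      max(cuts$cutoff_hu[cuts$slice == z]))
    }
    # no bone-compartment voxel below the lytic limit
    bone <- labs %in% cls[c("trabecular", "metastasis")]
    expect_true(all(hu[bone] >= 30))
    # cutoff audit trail is populated
    expect_gt(nrow(cuts), 0)
    expect_true(all(cuts$n_cortical_px > 0))
})

test_that("raising a global cutoff never increases the metastasis volume", {
    ph <- generatePhantom(tinyPhantomSpec(seed = 51))
    sweep <- c(350, 420, 500, 580, 660)
    mv <- vapply(sweep, function(cut) {
        s <- segmentSkeleton(ph$ct, segmentationConfig(
            cutoffScope = "global", globalCutoff = cut))
        compartmentVolumes(s)[["metastasis"]]
    }, numeric(1))
    expect_true(all(diff(mv) <= 0))
    bPlusExcl <- vapply(sweep, function(cut) {
        s <- segmentSkeleton(ph$ct, segmentationConfig(
            cutoffScope = "global", globalCutoff = cut))
        v <- compartmentVolumes(s)
        v[["trabecular"]] + v[["excluded_lytic"]] + v[["excluded_canal"]]
    }, numeric(1))
    expect_true(all(diff(bPlusExcl) >= 0))
})

test_that("degenerate inputs segment cleanly", {
    air <- VolumeGrid(array(-1000, c(24, 24, 3)), c(1.5, 1.5, 1.5),
                      modality = "CT")
    seg <- segmentSkeleton(air)
    expect_equal(sum(volData(segLabels(seg)) != 0), 0)
    expect_error(segmentSkeleton(VolumeGrid(array(0, c(4, 4, 4)),
                                            c(1, 1, 1),
                                            modality = "SPECT")),
                 "expects a CT")
})
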