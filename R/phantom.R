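#' PhantomSpec: parameters of the synthetic SPECT/CT phantom
#'
#' Describes a seeded digital phantom: a co-registered CT/SPECT volume
#' pair with ground-truth label and region maps. The skeleton is a set of
#' simple bone shapes (cortical-shelled tubes and spheres) containing
#' trabecular interiors, osteoblastic metastatic inclusions, lytic holes,
#' an enclosed cortically lined canal, extra-skeletal calcification
#' specks and optionally a metal implant. Compartment mean HU and mean
#' counts/voxel default to values typical of metastatic CRPC SPECT/CT
#' cohorts (metastases 590 HU / 939 counts, trabecular 251 / 462,
#' cortical 531 / 271).
#'
#' Geometry lists use world mm coordinates. Tubes:
#' \code{list(type = "tube", center = c(x, y), outerR, shellMm, zRange =
#' c(z1, z2) (slices), canalR, canalWallMm, region)}. Spheres:
#' \code{list(type = "sphere", center = c(x, y, z), r, shellMm, region)}.
#' Inclusions (mets, lytic, calcifications, implants):
#' \code{list(center = c(x, y, z), r)}.
#'
#' @slot ctDim,ctSpacing CT grid shape and spacing (mm).
#' @slot spectDim,spectSpacing SPECT grid shape and spacing (mm); the
#'   SPECT grid is centred on the CT grid in-plane.
#' @slot bones,mets,lyticLesions,calcifications,implants Geometry lists.
#' @slot huMean,huSd Named per-class HU mean and voxel-level noise SD.
#' @slot countsMean,countsSd Named per-compartment counts/voxel mean and
#'   voxel-level SD (background = extra-skeletal).
#' @slot poissonNoise If TRUE, SPECT counts are Poisson-resampled from the
#'   fraction-weighted mean map instead of Gaussian-perturbed.
#' @slot psfFwhmMm If > 0, the SPECT mean map is blurred with an isotropic
#'   Gaussian PSF of this FWHM, emulating the limited resolution of the
#'   single-photon technique.
#' @slot seed Random seed fixing the full output bit-exactly.
#' @export
setClass("PhantomSpec",
    representation(ctDim = "integer", ctSpacing = "numeric",
                   spectDim = "integer", spectSpacing = "numeric",
                   bones = "list", mets = "list", lyticLesions = "list",
                   calcifications = "list", implants = "list",
                   huMean = "numeric", huSd = "numeric",
                   countsMean = "numeric", countsSd = "numeric",
                   poissonNoise = "logical", psfFwhmMm = "numeric",
                   seed = "numeric"),
    validity = function(object) {
        msg <- character()
        if (any(object@ctDim <= 0) || any(object@spectDim <= 0))
            msg <- c(msg, "grid dimensions must be positive")
        if (any(object@ctSpacing <= 0) || any(object@spectSpacing <= 0))
            msg <- c(msg, "grid spacings must be positive")
        if (any(object@huSd < 0) || any(object@countsSd < 0))
            msg <- c(msg, "noise SDs must be non-negative")
        need <- c("soft_tissue", "cortical", "trabecular", "metastasis",
                  "lytic", "canal", "calcification", "implant")
        if (!all(need %in% names(object@huMean)))
            msg <- c(msg, "huMean must name all tissue classes")
        if (!all(c("metastasis", "trabecular", "cortical", "background") %in%
                 names(object@countsMean)))
            msg <- c(msg, "countsMean must name all compartments")
        if (length(msg)) msg else TRUE
    })

.defaultBones <- function() {
    list(
        list(type = "tube", center = c(192, 230), outerR = 45, shellMm = 3,
             zRange = c(1, 40), canalR = 0, canalWallMm = 0, region = "hip"),
        list(type = "tube", center = c(192, 130), outerR = 21, shellMm = 3,
             zRange = c(1, 48), canalR = 5, canalWallMm = 0, region = "axial"),
        list(type = "tube", center = c(60, 130), outerR = 14, shellMm = 3,
             zRange = c(1, 48), canalR = 0, canalWallMm = 0,
             region = "appendicular"),
        list(type = "tube", center = c(324, 130), outerR = 14, shellMm = 3,
             zRange = c(1, 48), canalR = 0, canalWallMm = 0,
             region = "appendicular"),
        list(type = "sphere", center = c(100, 60, 80), r = 13,
             shellMm = 3, region = "skull"))
}

.defaultMets <- function() {
    list(list(center = c(178, 230, 27), r = 26),
         list(center = c(208, 238, 36), r = 22),
         list(center = c(205, 130, 36), r = 4))
}

#' Construct a PhantomSpec
#'
#' All arguments default to the standard single-study phantom: a 256 x
#' 256 x 64 CT at 1.5 mm, a 128 x 128 x 64 SPECT at 5 x 5 mm in-plane, a
#' pelvis-like bone mass carrying two bulky metastatic inclusions and two
#' lytic holes, a vertebral-column surrogate with an enclosed cortically
#' lined canal and a small metastasis, two appendicular shafts, a skull
#' surrogate, and three extra-skeletal calcification specks. Compartment
#' mean HU/counts follow the cohort-typical values above; voxel-level HU
#' noise defaults to 40 HU (low-dose CT quantum noise) for bone
#' compartments, while the larger between-patient spreads belong to the
#' cohort simulator, not to a single phantom study.
#'
#' @param ctDim,ctSpacing,spectDim,spectSpacing Grid geometry.
#' @param bones,mets,lyticLesions,calcifications,implants Geometry lists
#'   (see \linkS4class{PhantomSpec}).
#' @param huMean,huSd,countsMean,countsSd Named class parameters.
#' @param poissonNoise,psfFwhmMm,seed See \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(ctDim = c(256L, 256L, 64L),
                        ctSpacing = c(1.5, 1.5, 1.5),
                        spectDim = c(128L, 128L, 64L),
                        spectSpacing = c(5, 5, 1.5),
                        bones = .defaultBones(),
                        mets = .defaultMets(),
                        lyticLesions = list(
                            list(center = c(168, 252, 40), r = 6),
                            list(center = c(222, 212, 18), r = 6)),
                        calcifications = list(
                            list(center = c(120, 40, 30), r = 2.5),
                            list(center = c(250, 50, 45), r = 2.5),
                            list(center = c(80, 300, 20), r = 2.5)),
                        implants = list(),
                        huMean = c(soft_tissue = 40, cortical = 531,
                                   trabecular = 251, metastasis = 590,
                                   lytic = 15, canal = 20,
                                   calcification = 700, implant = 3000),
                        huSd = c(soft_tissue = 15, cortical = 40,
                                 trabecular = 40, metastasis = 40,
                                 lytic = 8, canal = 8, calcification = 50,
                                 implant = 100),
                        countsMean = c(metastasis = 939, trabecular = 462,
                                       cortical = 271, background = 50),
                        countsSd = c(metastasis = 279, trabecular = 196,
                                     cortical = 106, background = 20),
                        poissonNoise = FALSE, psfFwhmMm = 0, seed = 42) {
    new("PhantomSpec", ctDim = as.integer(ctDim),
        ctSpacing = as.numeric(ctSpacing), spectDim = as.integer(spectDim),
        spectSpacing = as.numeric(spectSpacing), bones = bones, mets = mets,
        lyticLesions = lyticLesions, calcifications = calcifications,
        implants = implants, huMean = huMean, huSd = huSd,
        countsMean = countsMean, countsSd = countsSd,
        poissonNoise = poissonNoise, psfFwhmMm = psfFwhmMm, seed = seed)
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.checkShapeInGrid <- function(lo, hi, ext, what) {
    if (any(lo < ext[, "min"]) || any(hi > ext[, "max"]))
        stop("geometry exceeds grid extent: ", what)
}

# Paint the phantom tissue-class map and region map on the CT grid.
# Class codes: 1 soft, 2 cortical, 3 trabecular, 4 metastasis, 5 lytic,
# 6 canal, 7 calcification, 8 implant.
.buildGeometry <- function(spec) {
    d <- spec@ctDim; sp <- spec@ctSpacing
    xs <- (seq_len(d[1]) - 1) * sp[1]
    ys <- (seq_len(d[2]) - 1) * sp[2]
    zs <- (seq_len(d[3]) - 1) * sp[3]
    cmap <- array(1L, d)
    rmap <- array(0L, d)
    rc <- regionCodes()
    ext <- worldExtent(VolumeGrid(array(0, d), sp, c(0, 0, 0), "CT"))

    for (b in spec@bones) {
        rcode <- rc[[b$region]]
        if (identical(b$type, "tube")) {
            .checkShapeInGrid(c(b$center - b$outerR, zs[b$zRange[1]]),
                              c(b$center + b$outerR, zs[b$zRange[2]]),
                              ext, paste("tube at", paste(b$center,
                                                          collapse = ",")))
            r2 <- outer((xs - b$center[1])^2, (ys - b$center[2])^2, "+")
            solid <- r2 <= b$outerR^2
            inner <- r2 <= (b$outerR - b$shellMm)^2
            canalAll <- if (b$canalR > 0)
                r2 <= (b$canalR + b$canalWallMm)^2 else
                matrix(FALSE, d[1], d[2])
            canalIn <- if (b$canalR > 0) r2 <= b$canalR^2 else canalAll
            sl <- array(1L, c(d[1], d[2]))
            sl[solid] <- 2L
            sl[inner] <- 3L
            sl[canalAll & !canalIn] <- 2L
            sl[canalIn] <- 6L
            for (z in b$zRange[1]:b$zRange[2]) {
                cur <- cmap[, , z]
                cur[solid] <- sl[solid]
                cmap[, , z] <- cur
                rr <- rmap[, , z]; rr[solid] <- rcode; rmap[, , z] <- rr
            }
        } else if (identical(b$type, "sphere")) {
            .checkShapeInGrid(b$center - b$r, b$center + b$r, ext,
                              paste("sphere at", paste(b$center,
                                                       collapse = ",")))
            for (z in seq_len(d[3])) {
                dz2 <- (zs[z] - b$center[3])^2
                if (dz2 > b$r^2) next
                r2 <- outer((xs - b$center[1])^2, (ys - b$center[2])^2, "+")
                solid <- r2 <= b$r^2 - dz2
                inner <- r2 <= max(0, (sqrt(max(b$r^2 - dz2, 0)) -
                                       b$shellMm))^2 &
                         (b$r - sqrt(dz2)) > b$shellMm
                cur <- cmap[, , z]
                cur[solid] <- 2L
                cur[inner] <- 3L
                cmap[, , z] <- cur
                rr <- rmap[, , z]; rr[solid] <- rcode; rmap[, , z] <- rr
            }
        } else stop("unknown bone type: ", b$type)
    }
    paintSpheres <- function(cmap, shapes, code, onto, what) {
        for (s in shapes) {
            .checkShapeInGrid(s$center - s$r, s$center + s$r, ext,
                              paste(what, "at", paste(s$center,
                                                      collapse = ",")))
            z1 <- max(1L, ceiling((s$center[3] - s$r) / sp[3]) + 1L)
            z2 <- min(d[3], floor((s$center[3] + s$r) / sp[3]) + 1L)
            for (z in z1:z2) {
                dz2 <- (zs[z] - s$center[3])^2
                if (dz2 > s$r^2) next
                r2 <- outer((xs - s$center[1])^2, (ys - s$center[2])^2, "+")
                disc <- r2 <= s$r^2 - dz2
                cur <- cmap[, , z]
                sel <- disc & cur %in% onto
                cur[sel] <- code
                cmap[, , z] <- cur
            }
        }
        cmap
    }
    # inclusions are clipped to the compartments they can occupy:
    # metastases and lytic holes replace trabecular bone only;
    # implants replace bone; calcifications sit in soft tissue
    cmap <- paintSpheres(cmap, spec@mets, 4L, 3L, "metastasis")
    cmap <- paintSpheres(cmap, spec@lyticLesions, 5L, 3L, "lytic lesion")
    cmap <- paintSpheres(cmap, spec@implants, 8L, c(3L, 4L), "implant")
    cmap <- paintSpheres(cmap, spec@calcifications, 7L, 1L, "calcification")
    list(classMap = cmap, regionMap = rmap)
}

.gaussBlurSeparable <- function(arr, sigmaVox) {
    d <- dim(arr)
    for (ax in 1:3) {
        s <- sigmaVox[ax]
        if (s <= 0) next
        half <- max(1L, ceiling(3 * s))
        k <- stats::dnorm(-half:half, sd = s)
        k <- k / sum(k)
        # convolve along axis with replicated-edge padding
        perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
        a <- aperm(arr, perm)
        da <- dim(a)
        m <- matrix(a, da[1], da[2] * da[3])
        idx <- pmin(pmax(outer(seq_len(da[1]), -half:half, "+"), 1L), da[1])
        out <- matrix(0, da[1], ncol(m))
        for (j in seq_along(-half:half))
            out <- out + k[j] * m[idx[, j], , drop = FALSE]
        arr <- aperm(array(out, da), order(perm))
    }
    arr
}

#' Generate a synthetic co-registered CT/SPECT study with ground truth
#'
#' CT voxels are drawn around the compartment mean of their truth label
#' with voxel-level Gaussian noise; the SPECT volume is synthesised at its
#' native resolution from fraction-weighted compartment mean counts
#' (occupancies obtained with \code{\link{resampleMaskToGrid}}), with
#' Gaussian or Poisson noise and an optional Gaussian PSF. The seed fixes
#' the full output bit-exactly; changing only the seed changes the noise
#' but never the geometry.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return List with CT, SPECT, truth-label and region-map
#'   \linkS4class{VolumeGrid}s (\code{ct}, \code{spect}, \code{truth},
#'   \code{regions}) plus \code{spec}.
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(ctDim = c(64, 64, 8),
#'     bones = list(list(type = "tube", center = c(48, 48), outerR = 30,
#'                       shellMm = 3, zRange = c(1, 8), canalR = 0,
#'                       canalWallMm = 0, region = "axial")),
#'     mets = list(), lyticLesions = list(), calcifications = list()))
#' compartmentVolumes(ph$truth)
generatePhantom <- function(spec) {
    validObject(spec)
    geo <- .buildGeometry(spec)
    cmap <- geo$classMap
    d <- spec@ctDim
    clsNames <- c("soft_tissue", "cortical", "trabecular", "metastasis",
                  "lytic", "canal", "calcification", "implant")
    segCls <- segClasses()
    truthCode <- c(segCls[["background"]], segCls[["cortical"]],
                   segCls[["trabecular"]], segCls[["metastasis"]],
                   segCls[["excluded_lytic"]], segCls[["excluded_canal"]],
                   segCls[["background"]], segCls[["excluded_manual"]])

    ctOrigin <- c(0, 0, 0)
    ctCenter <- (d - 1) * spec@ctSpacing / 2
    spOrigin <- ctCenter - (spec@spectDim - 1) * spec@spectSpacing / 2

    .withSeed(spec@seed, {
        mu <- spec@huMean[clsNames][cmap]
        sd <- spec@huSd[clsNames][cmap]
        ctData <- array(mu + sd * stats::rnorm(length(mu)), d)

        truth <- array(truthCode[cmap], d)
        truthGrid <- VolumeGrid(truth, spec@ctSpacing, ctOrigin, "LABEL")
        ct <- VolumeGrid(ctData, spec@ctSpacing, ctOrigin, "CT")
        regions <- VolumeGrid(geo$regionMap, spec@ctSpacing, ctOrigin,
                              "LABEL")

        spectTemplate <- VolumeGrid(array(0, spec@spectDim),
                                    spec@spectSpacing, spOrigin, "SPECT")
        occ <- resampleMaskToGrid(truthGrid, spectTemplate,
                                  classes = segCls[c("cortical",
                                                     "trabecular",
                                                     "metastasis")])
        oc <- occ[[1]]@data; ob <- occ[[2]]@data; om <- occ[[3]]@data
        obg <- pmax(0, 1 - oc - ob - om)
        cm <- spec@countsMean; cs <- spec@countsSd
        meanMap <- oc * cm[["cortical"]] + ob * cm[["trabecular"]] +
                   om * cm[["metastasis"]] + obg * cm[["background"]]
        if (spec@psfFwhmMm > 0)
            meanMap <- .gaussBlurSeparable(
                meanMap, (spec@psfFwhmMm / 2.3548) / spec@spectSpacing)
        spectData <- if (spec@poissonNoise) {
            array(stats::rpois(length(meanMap), pmax(meanMap, 0)),
                  spec@spectDim) * 1.0
        } else {
            varMap <- oc * cs[["cortical"]]^2 + ob * cs[["trabecular"]]^2 +
                      om * cs[["metastasis"]]^2 + obg * cs[["background"]]^2
            pmax(array(meanMap + sqrt(varMap) *
                       stats::rnorm(length(meanMap)), spec@spectDim), 0)
        }
        spect <- VolumeGrid(spectData, spec@spectSpacing, spOrigin, "SPECT")
        list(ct = ct, spect = spect, truth = truthGrid, regions = regions,
             spec = spec)
    })
}

.scenarioCatalogue <- c("clean", "noisy", "lytic", "canal", "calcified",
                        "implant", "superscan-like", "no-tumor")

#' Build a PhantomSpec for a named scenario
#'
#' Scenarios: \code{clean} (defaults), \code{noisy} (Poisson counts +
#' 10 mm PSF), \code{lytic} (additional lytic holes), \code{canal}
#' (widened canal), \code{calcified} (more extra-skeletal specks),
#' \code{implant} (a metal implant in the pelvic bone),
#' \code{superscan-like} (elevated trabecular/metastatic uptake and a
#' larger tumour burden, hence higher INV\%), \code{no-tumor} (no
#' metastatic inclusions).
#'
#' @param name Scenario name.
#' @param seed Random seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
scenarioSpec <- function(name, seed = 42) {
    if (!name %in% .scenarioCatalogue)
        stop("unknown scenario '", name, "'; choose one of: ",
             paste(.scenarioCatalogue, collapse = ", "))
    base <- phantomSpec(seed = seed)
    switch(name,
        clean = base,
        noisy = { base@poissonNoise <- TRUE; base@psfFwhmMm <- 10; base },
        lytic = {
            base@lyticLesions <- c(base@lyticLesions, list(
                list(center = c(192, 214, 52), r = 7),
                list(center = c(186, 245, 12), r = 5)))
            base
        },
        canal = {
            base@bones[[2]]$canalR <- 7
            base
        },
        calcified = {
            base@calcifications <- c(base@calcifications, list(
                list(center = c(300, 300, 35), r = 2.5),
                list(center = c(60, 60, 55), r = 3),
                list(center = c(150, 330, 25), r = 2.5)))
            base
        },
        implant = {
            base@implants <- list(list(center = c(192, 258, 15), r = 7))
            base
        },
        `superscan-like` = {
            base@countsMean[["trabecular"]] <- 565
            base@countsMean[["metastasis"]] <- 1104
            base@mets[[1]] <- list(center = c(178, 230, 29), r = 28)
            base@mets[[2]]$r <- 24
            base
        },
        `no-tumor` = { base@mets <- list(); base })
}

#' Write a set of phantom fixtures to disk
#'
#' For each named scenario, writes \code{<name>_ct.nii.gz},
#' \code{<name>_spect.nii.gz}, \code{<name>_truth.nii.gz},
#' \code{<name>_regions.nii.gz} and \code{<name>_spec.json} under
#' \code{dir}.
#'
#' @param names Scenario names (see \code{\link{scenarioSpec}}).
#' @param dir Output directory (created if absent).
#' @param seed Random seed shared by the scenarios.
#' @return Invisibly, a named list of the files written per scenario.
#' @export
phantomSuite <- function(names = "clean", dir = ".", seed = 42) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- list()
    for (nm in names) {
        spec <- scenarioSpec(nm, seed = seed)
        ph <- generatePhantom(spec)
        stem <- file.path(dir, gsub("[^a-z0-9]+", "_", nm))
        files <- c(ct = paste0(stem, "_ct.nii.gz"),
                   spect = paste0(stem, "_spect.nii.gz"),
                   truth = paste0(stem, "_truth.nii.gz"),
                   regions = paste0(stem, "_regions.nii.gz"),
                   spec = paste0(stem, "_spec.json"))
        writeVolume(ph$ct, files[["ct"]])
        writeVolume(ph$spect, files[["spect"]])
        writeVolume(ph$truth, files[["truth"]])
        writeVolume(ph$regions, files[["regions"]])
        jsonlite::write_json(list(
            scenario = nm, seed = seed, ct_dim = spec@ctDim,
            ct_spacing = spec@ctSpacing, spect_dim = spec@spectDim,
            spect_spacing = spec@spectSpacing,
            hu_mean = as.list(spec@huMean), hu_sd = as.list(spec@huSd),
            counts_mean = as.list(spec@countsMean),
            counts_sd = as.list(spec@countsSd),
            poisson_noise = spec@poissonNoise, psf_fwhm_mm = spec@psfFwhmMm,
            n_bones = length(spec@bones), n_mets = length(spec@mets),
            label_codes = as.list(segClasses())),
            files[["spec"]], auto_unbox = TRUE, pretty = TRUE)
        out[[nm]] <- files
    }
    invisible(out)
}
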