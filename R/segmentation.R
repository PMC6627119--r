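#' Detect bone outer borders in an axial CT slice
#'
#' Emulates the horizontal raster scan of the slice: reading HU values
#' along each row, the first crossing of \code{surfaceHuThreshold} marks
#' the bone outer border. Operationally the border is the outer contour of
#' each connected supra-threshold structure, and the region it encloses is
#' obtained by hole filling. Structures whose filled area is below
#' \code{minBoneComponentPx}, or that have no enclosed interior once the
#' cortical rim is removed (isolated specks, vascular calcifications),
#' are discarded.
#'
#' @param ctSlice 2D matrix of HU values (one axial slice).
#' @param config A \linkS4class{SegmentationConfig}.
#' @return List with \code{components}: a list, one element per kept
#'   structure, each holding logical matrices \code{filled} (the enclosed
#'   region including the border) and \code{border} (its outer 1-px
#'   contour); and \code{discarded}: logical matrix of supra-threshold
#'   pixels of rejected structures.
#' @export
detectBoneBorder <- function(ctSlice, config = segmentationConfig()) {
    stopifnot(is.matrix(ctSlice))
    bw <- is.finite(ctSlice) & ctSlice >= config@surfaceHuThreshold
    discarded <- matrix(FALSE, nrow(ctSlice), ncol(ctSlice))
    if (!any(bw)) return(list(components = list(), discarded = discarded))
    lab <- .label2d8(bw)
    comps <- list()
    for (k in seq_len(lab$n)) {
        compMask <- lab$labels == k
        filled <- EBImage::fillHull(compMask * 1) == 1
        if (sum(filled) < config@minBoneComponentPx ||
            !any(erodeMask(filled, config@rimThicknessPx))) {
            discarded <- discarded | compMask
            next
        }
        border <- filled & !erodeMask(filled, 1L)
        comps[[length(comps) + 1L]] <- list(filled = filled, border = border)
    }
    list(components = comps, discarded = discarded)
}

#' Extract the cortical rim of a filled bone component
#'
#' The rim is the set of pixels at in-plane Chebyshev distance
#' < \code{rimThicknessPx} from the complement: the component minus its
#' erosion by \code{rimThicknessPx}. With the default thickness of 2 this
#' is the 2-pixel ring sampled inward from the bone outer border; the
#' remainder is the structure interior. Components of radius at most the
#' rim thickness are all rim, with an empty interior.
#'
#' @param filled Logical matrix: a filled connected bone region.
#' @param rimThicknessPx Rim thickness in pixels.
#' @return List of logical matrices \code{rim} and \code{interior}.
#' @export
extractCorticalRim <- function(filled, rimThicknessPx = 2L) {
    filled <- filled != 0
    interior <- erodeMask(filled, as.integer(rimThicknessPx))
    list(rim = filled & !interior, interior = interior)
}

#' Compute the adaptive HU cutoff from the cortical rim
#'
#' The cutoff that separates osteoblastic metastases from normal
#' trabecular bone is the arithmetic mean HU of the cortical voxels,
#' assuming metastases have an average density at least equal to that of
#' cortical bone.
#'
#' @param hu Numeric array/matrix of HU values.
#' @param corticalMask Logical mask of cortical voxels (same shape).
#' @return Mean cortical HU (scalar).
#' @export
#' @examples
#' adaptiveCutoff(matrix(c(520, 542, 0, 0), 2), matrix(c(TRUE, TRUE,
#'                FALSE, FALSE), 2))  # 531
adaptiveCutoff <- function(hu, corticalMask) {
    if (!any(corticalMask)) stop("empty cortical mask")
    mean(hu[corticalMask])
}

#' Classify structure-interior voxels against the adaptive cutoff
#'
#' Voxels with HU at least equal to the cutoff are metastasis; voxels from
#' \code{lyticHuMax} (inclusive: HU exactly 30 is retained as bone) up to
#' the cutoff are trabecular; voxels strictly below \code{lyticHuMax} are
#' purely lytic areas, automatically removed.
#'
#' @param hu Numeric matrix/array of HU values.
#' @param interiorMask Logical mask of interior voxels.
#' @param cutoff Adaptive HU cutoff (mean cortical density).
#' @param config A \linkS4class{SegmentationConfig}.
#' @return Integer matrix/array of labels over the interior (0 elsewhere).
#' @export
classifyInterior <- function(hu, interiorMask, cutoff,
                             config = segmentationConfig()) {
    if (!is.finite(cutoff) || cutoff <= config@lyticHuMax)
        stop("degenerate cortex: cutoff (", format(cutoff),
             ") must exceed lyticHuMax (", config@lyticHuMax, ")")
    cls <- segClasses()
    out <- array(0L, dim(hu))
    v <- hu[interiorMask]
    lab <- ifelse(v >= cutoff, cls[["metastasis"]],
                  ifelse(v >= config@lyticHuMax, cls[["trabecular"]],
                         cls[["excluded_lytic"]]))
    out[interiorMask] <- as.integer(lab)
    out
}

#' Sort out the spinal canal and enclosed hypodense cavities
#'
#' Voxels belonging to the spinal canal and hypodense areas such as bone
#' cysts are excluded from every compartment. Candidates are the
#' 26-connected 3D components of automatically removed hypodense voxels
#' (HU below \code{lyticHuMax}); a component is relabelled
#' \code{excluded_canal} when its mean HU is below \code{canalHuMax} and
#' it is fully enclosed by the segmented bone region in-plane (no in-plane
#' 4-neighbour outside the filled region). Hypodense areas breaching the
#' bone surface keep the \code{excluded_lytic} label.
#'
#' @param seg A \linkS4class{SegmentationResult} (interior classification
#'   done).
#' @param ct The CT \linkS4class{VolumeGrid} the segmentation was made on.
#' @param config A \linkS4class{SegmentationConfig}; defaults to the one
#'   stored in \code{seg}.
#' @return The updated \linkS4class{SegmentationResult}.
#' @export
excludeSpinalCanal <- function(seg, ct, config = segConfig(seg)) {
    stopifnot(is(seg, "SegmentationResult"), is(ct, "VolumeGrid"))
    if (!sameGrid(segLabels(seg), ct)) stop("segmentation/CT grid mismatch")
    cls <- segClasses()
    labs <- seg@labels@data
    lytic <- labs == cls[["excluded_lytic"]]
    if (!any(lytic)) return(seg)
    filled <- labs != cls[["background"]] &
        labs != cls[["excluded_calcification"]]
    # in-plane 4-neighbour adjacency to outside the filled region
    openPix <- array(FALSE, dim(labs))
    for (z in seq_len(dim(labs)[3])) {
        f <- filled[, , z]
        notF <- !f
        touch <- .shiftMatrix(notF * 1L, 1, 0) | .shiftMatrix(notF * 1L, -1, 0) |
                 .shiftMatrix(notF * 1L, 0, 1) | .shiftMatrix(notF * 1L, 0, -1)
        # pixels on the image edge have implicit outside neighbours
        edge <- matrix(FALSE, nrow(f), ncol(f))
        edge[c(1, nrow(f)), ] <- TRUE; edge[, c(1, ncol(f))] <- TRUE
        openPix[, , z] <- (touch == 1 | edge) & f
    }
    comp <- .label3d26(lytic)
    hu <- ct@data
    for (k in seq_len(comp$n)) {
        idx <- comp$labels == k
        if (mean(hu[idx]) >= config@canalHuMax) next
        if (any(openPix[idx])) next     # breaches the bone surface
        labs[idx] <- cls[["excluded_canal"]]
    }
    seg@labels@data <- labs
    validObject(seg)
    seg
}

#' Apply operator-drawn manual exclusions
#'
#' Voxels under the exclusion mask are relabelled
#' \code{excluded_manual} regardless of their prior class, removing benign
#' hyperdensities (osteochondrosis, osteophytes, metal implants) from
#' every compartment. Metal candidates (HU at or above
#' \code{metalHuMin}) remain flagged in \code{\link{metalCandidates}}
#' for review but are never auto-excluded.
#'
#' @param seg A \linkS4class{SegmentationResult}.
#' @param exclusionMask A LABEL/MASK \linkS4class{VolumeGrid} (non-zero =
#'   exclude) on the same grid, or a logical/0-1 array.
#' @return The updated \linkS4class{SegmentationResult}.
#' @export
applyManualExclusions <- function(seg, exclusionMask) {
    stopifnot(is(seg, "SegmentationResult"))
    if (is(exclusionMask, "VolumeGrid")) {
        if (!sameGrid(segLabels(seg), exclusionMask))
            stop("exclusion mask grid mismatch")
        exclusionMask <- exclusionMask@data
    }
    if (!identical(dim(exclusionMask), dim(seg@labels@data)))
        stop("exclusion mask grid mismatch")
    sel <- exclusionMask != 0
    seg@labels@data[sel] <- segClasses()[["excluded_manual"]]
    seg
}

#' Segment the skeleton on a CT volume
#'
#' Orchestrates the adaptive bone segmentation slice by slice: bone-border
#' detection, 2-pixel cortical rim extraction, adaptive mean-cortical-HU
#' cutoff, interior classification into trabecular bone and osteoblastic
#' metastases, automatic removal of purely lytic areas (HU below 30),
#' spinal-canal/cyst exclusion, and optional manual exclusions. Compact
#' bone is assumed to be the most attenuating structure in the body, so
#' supra-threshold contours delimit the skeleton.
#'
#' @param ct A CT \linkS4class{VolumeGrid}.
#' @param config A \linkS4class{SegmentationConfig}.
#' @param manualMask Optional exclusion mask (see
#'   \code{\link{applyManualExclusions}}).
#' @return A \linkS4class{SegmentationResult}.
#' @export
segmentSkeleton <- function(ct, config = segmentationConfig(),
                            manualMask = NULL) {
    stopifnot(is(ct, "VolumeGrid"))
    if (ct@modality != "CT") stop("segmentSkeleton expects a CT volume")
    validObject(config)
    d <- dim(ct@data)
    cls <- segClasses()
    labs <- array(0L, d)
    cutRows <- list()
    # per-slice detection; store rim/interior as flat indices for the
    # second (classification) pass so a global cutoff can pool all rims
    store <- vector("list", d[3])
    for (z in seq_len(d[3])) {
        sl <- ct@data[, , z]
        det <- detectBoneBorder(sl, config)
        if (any(det$discarded)) {
            flat <- which(det$discarded) + (z - 1L) * d[1] * d[2]
            labs[flat] <- cls[["excluded_calcification"]]
        }
        if (!length(det$components)) next
        perComp <- lapply(seq_along(det$components), function(k) {
            comp <- det$components[[k]]
            parts <- extractCorticalRim(comp$filled, config@rimThicknessPx)
            list(rim = which(parts$rim), interior = which(parts$interior))
        })
        store[[z]] <- perComp
    }
    off <- function(z) (z - 1L) * d[1] * d[2]
    globalCut <- NA_real_
    if (config@cutoffScope == "global") {
        globalCut <- if (is.finite(config@globalCutoff)) config@globalCutoff
        else {
            rimAll <- unlist(lapply(seq_len(d[3]), function(z) {
                pc <- store[[z]]
                if (is.null(pc)) return(numeric())
                unlist(lapply(pc, function(p) ct@data[p$rim + off(z)]))
            }))
            if (!length(rimAll)) NA_real_ else mean(rimAll)
        }
    }
    for (z in seq_len(d[3])) {
        pc <- store[[z]]
        if (is.null(pc)) next
        sl <- ct@data[, , z]
        for (k in seq_along(pc)) {
            rimIdx <- pc[[k]]$rim; intIdx <- pc[[k]]$interior
            cut <- if (config@cutoffScope == "global") globalCut
                   else adaptiveCutoff(sl, rimIdx)
            if (!is.finite(cut) || cut <= config@lyticHuMax)
                stop("degenerate cortex in slice ", z, " component ", k,
                     ": cutoff ", format(cut))
            labs[rimIdx + off(z)] <- cls[["cortical"]]
            v <- sl[intIdx]
            lab <- ifelse(v >= cut, cls[["metastasis"]],
                          ifelse(v >= config@lyticHuMax, cls[["trabecular"]],
                                 cls[["excluded_lytic"]]))
            labs[intIdx + off(z)] <- as.integer(lab)
            cutRows[[length(cutRows) + 1L]] <-
                data.frame(slice = z, component = k, cutoff_hu = cut,
                           n_cortical_px = length(rimIdx))
        }
    }
    cutoffs <- if (length(cutRows)) do.call(rbind, cutRows) else
        data.frame(slice = integer(), component = integer(),
                   cutoff_hu = numeric(), n_cortical_px = integer())
    metal <- which(ct@data >= config@metalHuMin &
                   labs %in% cls[c("cortical", "trabecular", "metastasis")])
    metal <- if (length(metal)) arrayInd(metal, d) else
        matrix(integer(), 0, 3)
    colnames(metal) <- c("x", "y", "z")
    seg <- new("SegmentationResult",
               labels = VolumeGrid(labs, ct@spacing, ct@origin, "LABEL"),
               cutoffs = cutoffs, config = config, metalCandidates = metal)
    seg <- excludeSpinalCanal(seg, ct, config)
    if (!is.null(manualMask)) seg <- applyManualExclusions(seg, manualMask)
    seg
}
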