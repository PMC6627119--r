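#' @import methods
NULL

#' Segmentation label codes
#'
#' Integer codes used in segmentation label volumes. Compartment classes
#' (cortical, trabecular, metastasis) contribute to skeletal volume;
#' exclusion classes do not.
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' segClasses()
segClasses <- function() {
    c(background = 0L, cortical = 1L, trabecular = 2L, metastasis = 3L,
      excluded_lytic = 4L, excluded_canal = 5L, excluded_manual = 6L,
      excluded_calcification = 7L)
}

#' Skeletal region codes
#'
#' Integer codes for region label maps. The skull is excluded from
#' whole-body reports; hip bones are pooled with the axial skeleton in the
#' default regional grouping.
#'
#' @return Named integer vector of region codes.
#' @export
regionCodes <- function() {
    c(other = 0L, skull = 1L, axial = 2L, appendicular = 3L, hip = 4L)
}

#' VolumeGrid: a 3D scalar field with world geometry
#'
#' The common currency of CT (Hounsfield units), SPECT (tracer counts) and
#' label data. Voxel (0,0,0) is centred at \code{origin}; voxel centres are
#' spaced by \code{spacing} (mm) along x, y and z, with axial slices being
#' planes of constant z.
#'
#' @slot data 3D numeric array (HU, counts, fractional occupancy, or
#'   integer label codes).
#' @slot spacing Numeric length-3, voxel spacing in mm, all strictly
#'   positive.
#' @slot origin Numeric length-3, world coordinates (mm) of the centre of
#'   voxel (0,0,0).
#' @slot modality One of \code{"CT"}, \code{"SPECT"}, \code{"LABEL"},
#'   \code{"MASK"} (fractional occupancy in [0,1]).
#'
#' @export
setClass("VolumeGrid",
    representation(data = "array", spacing = "numeric", origin = "numeric",
                   modality = "character"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "expected 3 axes")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be three strictly positive values")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be three finite values")
        if (!object@modality %in% c("CT", "SPECT", "LABEL", "MASK"))
            msg <- c(msg, "modality must be one of CT, SPECT, LABEL, MASK")
        if (object@modality == "LABEL") {
            v <- object@data
            if (any(v != round(v), na.rm = TRUE))
                msg <- c(msg, "LABEL volumes carry only integer class codes")
        }
        if (length(msg)) msg else TRUE
    })

#' Construct a VolumeGrid
#'
#' @param data 3D array of voxel values.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param origin World coordinates of voxel (0,0,0), mm.
#' @param modality \code{"CT"}, \code{"SPECT"}, \code{"LABEL"} or
#'   \code{"MASK"}.
#' @return A \linkS4class{VolumeGrid}.
#' @export
#' @examples
#' vg <- VolumeGrid(array(0, c(4, 4, 2)), spacing = c(5, 5, 5),
#'                  modality = "SPECT")
#' voxelVolumeML(vg)
VolumeGrid <- function(data, spacing, origin = c(0, 0, 0),
                       modality = c("CT", "SPECT", "LABEL", "MASK")) {
    modality <- match.arg(modality)
    if (modality == "LABEL" && is.numeric(data)) storage.mode(data) <- "integer"
    new("VolumeGrid", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), modality = modality)
}

#' SegmentationConfig: tunable parameters of the adaptive bone segmentation
#'
#' @slot surfaceHuThreshold HU value whose crossing marks the bone outer
#'   border during the horizontal raster scan (default 150).
#' @slot rimThicknessPx In-plane thickness, in pixels, of the cortical rim
#'   sampled from the outer border (default 2).
#' @slot lyticHuMax Interior voxels strictly below this HU are removed as
#'   purely lytic areas (default 30); HU exactly equal is retained as bone.
#' @slot canalHuMax Enclosed hypodense cavities (spinal canal, bone cysts)
#'   with mean HU below this are sorted out (default 100).
#' @slot minBoneComponentPx Minimum per-slice component area in pixels; also
#'   requires a non-empty interior after rim removal, which rejects
#'   non-bone hyperdensities such as vascular calcification (default 20).
#' @slot metalHuMin Voxels at or above this HU are flagged as metal-implant
#'   candidates for operator review, never auto-excluded (default 2500).
#' @slot cutoffScope \code{"per_component_slice"} (the mean cortical HU of
#'   each bone structure in each slice classifies that structure's
#'   interior) or \code{"global"} (one pooled cortical mean).
#' @slot globalCutoff Optional fixed HU cutoff used when
#'   \code{cutoffScope == "global"}; \code{NA} (default) computes it from
#'   the pooled cortical rim.
#' @export
setClass("SegmentationConfig",
    representation(surfaceHuThreshold = "numeric", rimThicknessPx = "integer",
                   lyticHuMax = "numeric", canalHuMax = "numeric",
                   minBoneComponentPx = "integer", metalHuMin = "numeric",
                   cutoffScope = "character", globalCutoff = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!(object@lyticHuMax < object@canalHuMax &&
              object@canalHuMax < object@surfaceHuThreshold))
            msg <- c(msg, "require lyticHuMax < canalHuMax < surfaceHuThreshold")
        if (object@rimThicknessPx < 1L)
            msg <- c(msg, "rimThicknessPx must be >= 1")
        if (object@minBoneComponentPx < 1L)
            msg <- c(msg, "minBoneComponentPx must be >= 1")
        if (!object@cutoffScope %in% c("per_component_slice", "global"))
            msg <- c(msg, "cutoffScope must be per_component_slice or global")
        if (length(msg)) msg else TRUE
    })

#' Construct a SegmentationConfig
#'
#' @param surfaceHuThreshold,rimThicknessPx,lyticHuMax,canalHuMax
#'   See \linkS4class{SegmentationConfig}.
#' @param minBoneComponentPx,metalHuMin,cutoffScope,globalCutoff
#'   See \linkS4class{SegmentationConfig}.
#' @return A \linkS4class{SegmentationConfig}.
#' @export
#' @examples
#' segmentationConfig(cutoffScope = "global")
segmentationConfig <- function(surfaceHuThreshold = 150, rimThicknessPx = 2L,
                               lyticHuMax = 30, canalHuMax = 100,
                               minBoneComponentPx = 20L, metalHuMin = 2500,
                               cutoffScope = c("per_component_slice", "global"),
                               globalCutoff = NA_real_) {
    cutoffScope <- match.arg(cutoffScope)
    new("SegmentationConfig",
        surfaceHuThreshold = surfaceHuThreshold,
        rimThicknessPx = as.integer(rimThicknessPx),
        lyticHuMax = lyticHuMax, canalHuMax = canalHuMax,
        minBoneComponentPx = as.integer(minBoneComponentPx),
        metalHuMin = metalHuMin, cutoffScope = cutoffScope,
        globalCutoff = as.numeric(globalCutoff))
}

#' Read a SegmentationConfig from a JSON or YAML file
#'
#' Field names follow the snake_case external convention
#' (\code{surface_hu_threshold}, \code{rim_thickness_px},
#' \code{lytic_hu_max}, \code{canal_hu_max}, \code{min_bone_component_px},
#' \code{metal_hu_min}, \code{cutoff_scope}, \code{global_cutoff}).
#' Unspecified fields take their defaults.
#'
#' @param path Path to a .json, .yaml or .yml file.
#' @return A \linkS4class{SegmentationConfig}.
#' @export
readSegmentationConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    lst <- if (ext %in% c("yaml", "yml")) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the 'yaml' package is required to read YAML configs")
        yaml::read_yaml(path)
    } else {
        jsonlite::read_json(path, simplifyVector = TRUE)
    }
    map <- c(surface_hu_threshold = "surfaceHuThreshold",
             rim_thickness_px = "rimThicknessPx",
             lytic_hu_max = "lyticHuMax", canal_hu_max = "canalHuMax",
             min_bone_component_px = "minBoneComponentPx",
             metal_hu_min = "metalHuMin", cutoff_scope = "cutoffScope",
             global_cutoff = "globalCutoff")
    unknown <- setdiff(names(lst), names(map))
    if (length(unknown))
        stop("unknown config fields: ", paste(unknown, collapse = ", "))
    args <- stats::setNames(lst, map[names(lst)])
    do.call(segmentationConfig, args)
}

#' SegmentationResult: labelled skeleton plus the cutoffs that produced it
#'
#' @slot labels A LABEL \linkS4class{VolumeGrid} on the CT grid using the
#'   codes of \code{\link{segClasses}}.
#' @slot cutoffs data.frame with columns \code{slice}, \code{component},
#'   \code{cutoff_hu}, \code{n_cortical_px}: the adaptive mean-cortical-HU
#'   cutoff applied to each bone structure.
#' @slot config The \linkS4class{SegmentationConfig} applied.
#' @slot metalCandidates Integer matrix (one row per voxel, columns x/y/z,
#'   1-based) of voxels at or above \code{metalHuMin}, flagged for operator
#'   review.
#' @export
setClass("SegmentationResult",
    representation(labels = "VolumeGrid", cutoffs = "data.frame",
                   config = "SegmentationConfig", metalCandidates = "matrix"),
    validity = function(object) {
        msg <- character()
        if (object@labels@modality != "LABEL")
            msg <- c(msg, "labels must be a LABEL VolumeGrid")
        if (!all(unique(as.vector(object@labels@data)) %in% segClasses()))
            msg <- c(msg, "labels contain codes outside the class catalogue")
        if (length(msg)) msg else TRUE
    })

#' ROCResult: receiver-operating-characteristic analysis of a score
#'
#' @slot auc Area under the curve, ties credited 1/2 (equals the normalised
#'   Mann-Whitney statistic).
#' @slot curve data.frame of \code{threshold}, \code{sensitivity},
#'   \code{specificity}, ordered by decreasing stringency.
#' @slot direction \code{"high"} if high scores indicate the positive
#'   class, \code{"low"} otherwise.
#' @slot nPos,nNeg Group sizes.
#' @export
setClass("ROCResult",
    representation(auc = "numeric", curve = "data.frame",
                   direction = "character", nPos = "integer", nNeg = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@auc < 0 || object@auc > 1)
            msg <- c(msg, "AUC must lie in [0, 1]")
        if (!all(c("threshold", "sensitivity", "specificity") %in%
                 names(object@curve)))
            msg <- c(msg, "curve must have threshold/sensitivity/specificity")
        fpr <- 1 - object@curve$specificity
        if (is.unsorted(fpr, strictly = FALSE))
            msg <- c(msg, "curve must be monotone in false-positive rate")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "VolumeGrid", function(object) {
    d <- dim(object@data)
    cat(sprintf("VolumeGrid [%s] %d x %d x %d @ (%g, %g, %g) mm\n",
                object@modality, d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  origin (%g, %g, %g) mm; voxel volume %.4g mL\n",
                object@origin[1], object@origin[2], object@origin[3],
                voxelVolumeML(object)))
    invisible(NULL)
})

setMethod("show", "SegmentationResult", function(object) {
    tab <- table(factor(as.vector(object@labels@data), levels = segClasses(),
                        labels = names(segClasses())))
    cat("SegmentationResult\n")
    vx <- voxelVolumeML(object@labels)
    for (nm in names(tab))
        if (tab[[nm]] > 0)
            cat(sprintf("  %-22s %9d voxels  %9.1f mL\n", nm, tab[[nm]],
                        tab[[nm]] * vx))
    cat(sprintf("  adaptive cutoffs: %d structure-slices, median %.1f HU\n",
                nrow(object@cutoffs),
                if (nrow(object@cutoffs)) stats::median(object@cutoffs$cutoff_hu)
                else NA_real_))
    invisible(NULL)
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: AUC = %.4f (%d positives, %d negatives, %s scores indicate positives)\n",
                object@auc, object@nPos, object@nNeg,
                object@direction))
    invisible(NULL)
})
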