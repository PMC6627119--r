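#' @rdname VolumeGrid-accessors
#' @name VolumeGrid-accessors
#' @title Accessors for VolumeGrid and SegmentationResult
#' @param x A \linkS4class{VolumeGrid} or \linkS4class{SegmentationResult}.
#' @return \code{volData}: the 3D array; \code{voxelSpacing},
#'   \code{voxelOrigin}: numeric length-3 (mm); \code{modality}: character;
#'   \code{voxelVolumeML}: voxel volume in mL; \code{worldExtent}: 3 x 2
#'   matrix of voxel-cell bounds (mm); \code{segLabels}: the LABEL
#'   VolumeGrid; \code{segCutoffs}: the cutoff data.frame;
#'   \code{metalCandidates}: integer voxel-index matrix.
NULL

#' @rdname VolumeGrid-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("worldExtent", function(x) standardGeneric("worldExtent"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("segCutoffs", function(x) standardGeneric("segCutoffs"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("segConfig", function(x) standardGeneric("segConfig"))
#' @rdname VolumeGrid-accessors
#' @export
setGeneric("metalCandidates", function(x) standardGeneric("metalCandidates"))

#' @rdname VolumeGrid-accessors
setMethod("volData", "VolumeGrid", function(x) x@data)
#' @rdname VolumeGrid-accessors
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname VolumeGrid-accessors
setMethod("voxelOrigin", "VolumeGrid", function(x) x@origin)
#' @rdname VolumeGrid-accessors
setMethod("modality", "VolumeGrid", function(x) x@modality)
#' @rdname VolumeGrid-accessors
setMethod("voxelVolumeML", "VolumeGrid", function(x) prod(x@spacing) / 1000)

#' @rdname VolumeGrid-accessors
setMethod("worldExtent", "VolumeGrid", function(x) {
    n <- dim(x@data)
    lo <- x@origin - x@spacing / 2
    hi <- x@origin + (n - 1) * x@spacing + x@spacing / 2
    m <- cbind(lo, hi)
    dimnames(m) <- list(c("x", "y", "z"), c("min", "max"))
    m
})

#' @rdname VolumeGrid-accessors
setMethod("segLabels", "SegmentationResult", function(x) x@labels)
#' @rdname VolumeGrid-accessors
setMethod("segCutoffs", "SegmentationResult", function(x) x@cutoffs)
#' @rdname VolumeGrid-accessors
setMethod("segConfig", "SegmentationResult", function(x) x@config)
#' @rdname VolumeGrid-accessors
setMethod("metalCandidates", "SegmentationResult", function(x) x@metalCandidates)

#' Check that two volumes share an identical grid
#'
#' @param a,b \linkS4class{VolumeGrid} objects.
#' @param tol Tolerance (mm) on spacing and origin agreement.
#' @return Logical scalar.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
    identical(dim(a@data), dim(b@data)) &&
        all(abs(a@spacing - b@spacing) < tol) &&
        all(abs(a@origin - b@origin) < tol)
}
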