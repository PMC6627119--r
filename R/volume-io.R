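#' Read a CT, SPECT or label volume from a NIfTI file
#'
#' Voxel spacing and origin are taken from the file header (pixdim and the
#' sform/qform translation); data are returned in (x, y, z-axial) order as
#' stored by NIfTI. Label volumes are checked to carry only integer class
#' codes.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param modality \code{"CT"}, \code{"SPECT"}, \code{"LABEL"} or
#'   \code{"MASK"}.
#' @return A \linkS4class{VolumeGrid}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' vg <- VolumeGrid(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(1.5, 1.5, 1.5),
#'                  modality = "CT")
#' writeVolume(vg, f)
#' vg2 <- readVolume(f, "CT")
#' stopifnot(all(volData(vg) == volData(vg2)))
readVolume <- function(path, modality = c("CT", "SPECT", "LABEL", "MASK")) {
    modality <- match.arg(modality)
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected 3 axes in '", path, "' (header field dim reports ",
             length(d), ")")
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
        stop("non-positive voxel spacing in '", path,
             "' (header field pixdim = ", paste(sp, collapse = " x "), ")")
    xf <- RNifti::xform(img)
    org <- as.numeric(xf[1:3, 4])
    dat <- array(as.vector(img), d)
    VolumeGrid(dat, spacing = sp, origin = org, modality = modality)
}

#' Write a VolumeGrid to a NIfTI file
#'
#' Round-trips are lossless for integer label maps (written with an
#' integer datatype) and for CT/SPECT data (written as float64).
#'
#' @param vol A \linkS4class{VolumeGrid}.
#' @param path Output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "VolumeGrid"))
    dat <- vol@data
    dtype <- if (vol@modality == "LABEL") "int16" else "double"
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(c(vol@spacing, 1))
    m[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = dtype)
    invisible(path)
}

#' Write the label-class catalogue as a JSON sidecar
#'
#' @param path Output .json path.
#' @return \code{path}, invisibly.
#' @export
writeLabelSidecar <- function(path) {
    jsonlite::write_json(as.list(segClasses()), path, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

# per-axis overlap-length matrix between source cells (columns) and target
# cells (rows); cell i (0-based) spans origin + (i -/+ 0.5) * spacing
.overlapWeights <- function(nS, sS, oS, nT, sT, oT) {
    sLo <- oS + (seq_len(nS) - 1.5) * sS
    sHi <- sLo + sS
    tLo <- oT + (seq_len(nT) - 1.5) * sT
    tHi <- tLo + sT
    w <- outer(tHi, sHi, pmin) - outer(tLo, sLo, pmax)
    w[w < 0] <- 0
    w
}

#' Resample a label mask onto another grid as fractional occupancy
#'
#' For each requested class, every target voxel receives the fraction of
#' its volume covered by the class, computed from exact axis-aligned
#' box overlaps (so total occupied volume is conserved wherever the source
#' lies inside the target extent). This is how CT-grid compartment masks
#' are exported onto the co-registered SPECT grid; counts are then read on
#' the native SPECT grid rather than interpolated.
#'
#' @param mask A LABEL (or MASK) \linkS4class{VolumeGrid}.
#' @param target A \linkS4class{VolumeGrid} defining the output grid.
#' @param classes Integer class codes to resample; default all non-zero
#'   codes present. For a MASK input the (fractional) values themselves are
#'   spread, and a single map is returned under class code 1.
#' @return Named list of MASK \linkS4class{VolumeGrid}s (names are the
#'   class codes), each with values in [0, 1].
#' @export
resampleMaskToGrid <- function(mask, target, classes = NULL) {
    stopifnot(is(mask, "VolumeGrid"), is(target, "VolumeGrid"))
    em <- worldExtent(mask); et <- worldExtent(target)
    if (any(em[, "min"] >= et[, "max"] | em[, "max"] <= et[, "min"]))
        stop("no spatial overlap between mask and target grids")
    dS <- dim(mask@data); dT <- dim(target@data)
    W <- lapply(1:3, function(ax)
        .overlapWeights(dS[ax], mask@spacing[ax], mask@origin[ax],
                        dT[ax], target@spacing[ax], target@origin[ax]))
    vt <- prod(target@spacing)
    if (is.null(classes)) {
        classes <- if (mask@modality == "MASK") 1L else
            sort(setdiff(unique(as.vector(mask@data)), 0))
    }
    contract <- function(a) {
        # apply Wx, Wy, Wz along the three axes by matrix multiplication
        d <- dim(a)
        a <- W[[1]] %*% matrix(a, d[1], d[2] * d[3])
        a <- array(a, c(dT[1], d[2], d[3]))
        a <- aperm(a, c(2, 1, 3))
        a <- W[[2]] %*% matrix(a, d[2], dT[1] * d[3])
        a <- aperm(array(a, c(dT[2], dT[1], d[3])), c(2, 1, 3))
        a <- matrix(a, dT[1] * dT[2], d[3]) %*% t(W[[3]])
        array(a, dT)
    }
    out <- lapply(classes, function(cl) {
        src <- if (mask@modality == "MASK") mask@data else
            (mask@data == cl) * 1
        occ <- contract(src) / vt
        occ[occ < 0] <- 0; occ[occ > 1] <- 1
        VolumeGrid(occ, spacing = target@spacing, origin = target@origin,
                   modality = "MASK")
    })
    names(out) <- as.character(classes)
    out
}
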