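#' Compartment volumes of a segmentation, in mL
#'
#' \code{volume_ml(class) = voxel_count(class) * voxel_volume_ml}. The
#' skeletal volume S_Vol is the sum of the cortical (C_Vol), trabecular
#' (B_Vol) and metastasis (M_Vol) compartments; exclusion classes
#' contribute to no compartment.
#'
#' @param seg A \linkS4class{SegmentationResult} or LABEL
#'   \linkS4class{VolumeGrid}.
#' @return Named numeric vector of mL per class, plus \code{skeletal}.
#' @export
compartmentVolumes <- function(seg) {
    labs <- if (is(seg, "SegmentationResult")) segLabels(seg) else seg
    stopifnot(is(labs, "VolumeGrid"))
    vx <- voxelVolumeML(labs)
    cls <- segClasses()
    counts <- vapply(cls, function(code) sum(labs@data == code), numeric(1))
    vols <- counts * vx
    c(vols, skeletal = sum(vols[c("cortical", "trabecular", "metastasis")]))
}

#' Percent of trabecular invasion by metastases
#'
#' \code{INV\% = 100 * M_Vol / B_Vol}, the fraction of the trabecular bone
#' space replaced by osteoblastic metastases.
#'
#' @param mVolMl Metastasis volume, mL.
#' @param bVolMl Trabecular volume, mL.
#' @return INV\% (scalar).
#' @export
#' @examples
#' invPercent(27, 100)  # 27
invPercent <- function(mVolMl, bVolMl) {
    if (bVolMl <= 0) stop("INV% undefined: trabecular volume is zero")
    100 * mVolMl / bVolMl
}

#' Occupancy-weighted mean counts/voxel on the SPECT grid
#'
#' Mean radioactivity concentration of a compartment:
#' \code{sum(occupancy * counts) / sum(occupancy)} over the native SPECT
#' grid, with the fractional occupancy produced by
#' \code{\link{resampleMaskToGrid}}. On a binary mask this reduces to the
#' plain average over masked voxels.
#'
#' @param spect A SPECT \linkS4class{VolumeGrid}.
#' @param occupancy A MASK \linkS4class{VolumeGrid} on the SPECT grid.
#' @return Mean counts/voxel (scalar).
#' @export
meanCounts <- function(spect, occupancy) {
    stopifnot(is(spect, "VolumeGrid"), is(occupancy, "VolumeGrid"))
    if (!sameGrid(spect, occupancy))
        stop("occupancy must live on the SPECT grid")
    w <- occupancy@data
    tot <- sum(w)
    if (tot <= 0) stop("empty compartment on SPECT grid")
    sum(w * spect@data) / tot
}

.regionMask <- function(regionMap, region, dims) {
    rc <- regionCodes()
    if (is.null(regionMap)) {
        if (region == "whole_body") return(array(TRUE, dims))
        return(NULL)
    }
    rm <- regionMap@data
    switch(region,
        whole_body   = rm != rc[["skull"]],
        axial        = rm %in% rc[c("axial", "hip")],
        appendicular = rm == rc[["appendicular"]],
        hip          = rm == rc[["hip"]],
        skull        = rm == rc[["skull"]],
        custom       = rm != rc[["skull"]],
        stop("unknown region: ", region))
}

#' Per-region compartment report: volumes, mean HU, mean counts, INV%
#'
#' One block of rows per requested region: the cortical, trabecular and
#' metastasis compartments plus a \code{skeletal} summary row
#' (S_Vol = C_Vol + B_Vol + M_Vol, INV\% = 100 M_Vol/B_Vol). The
#' whole-body region excludes the skull; hip bones are pooled with the
#' axial skeleton. Counts are read on the native SPECT grid through
#' fractional-occupancy masks by default (\code{countsGrid = "spect"});
#' \code{countsGrid = "ct"} averages nearest-voxel SPECT values on the CT
#' grid instead.
#'
#' @param seg A \linkS4class{SegmentationResult}.
#' @param ct The CT \linkS4class{VolumeGrid} (for mean HU).
#' @param spect The co-registered SPECT \linkS4class{VolumeGrid}, or NULL
#'   to skip counts.
#' @param regionMap Optional LABEL \linkS4class{VolumeGrid} of
#'   \code{\link{regionCodes}} on the CT grid.
#' @param regions Character vector of regions to report.
#' @param countsGrid \code{"spect"} or \code{"ct"}.
#' @return data.frame with columns region, compartment, volume_ml,
#'   mean_hu, mean_counts_per_voxel, inv_percent, region_missing.
#' @export
regionalReport <- function(seg, ct, spect = NULL, regionMap = NULL,
                           regions = c("whole_body", "axial", "appendicular"),
                           countsGrid = c("spect", "ct")) {
    stopifnot(is(seg, "SegmentationResult"), is(ct, "VolumeGrid"))
    countsGrid <- match.arg(countsGrid)
    labs <- segLabels(seg)
    if (!sameGrid(labs, ct)) stop("segmentation/CT grid mismatch")
    if (!is.null(regionMap) && !sameGrid(labs, regionMap))
        stop("region map must live on the CT grid")
    if (!is.null(spect) && countsGrid == "ct" && !sameGrid(labs, spect))
        stop("countsGrid = 'ct' requires SPECT on the CT grid")
    cls <- segClasses()
    vx <- voxelVolumeML(labs)
    dims <- dim(labs@data)
    comp3 <- c("cortical", "trabecular", "metastasis")

    ctNearest <- NULL
    if (!is.null(spect) && countsGrid == "ct" ) ctNearest <- spect@data

    rows <- list()
    for (rg in regions) {
        rmask <- .regionMask(regionMap, rg, dims)
        missing <- is.null(rmask) || !any(rmask)
        if (missing) rmask <- array(FALSE, dims)
        compMasks <- lapply(comp3, function(cp)
            labs@data == cls[[cp]] & rmask)
        names(compMasks) <- comp3
        vols <- vapply(compMasks, sum, numeric(1)) * vx
        meanHu <- vapply(compMasks, function(m)
            if (any(m)) mean(ct@data[m]) else NA_real_, numeric(1))
        cnts <- rep(NA_real_, 3); names(cnts) <- comp3
        unionMask <- compMasks[[1]] | compMasks[[2]] | compMasks[[3]]
        cntSkel <- NA_real_
        if (!is.null(spect) && !missing) {
            if (countsGrid == "ct") {
                cnts <- vapply(compMasks, function(m)
                    if (any(m)) mean(ctNearest[m]) else NA_real_, numeric(1))
                if (any(unionMask)) cntSkel <- mean(ctNearest[unionMask])
            } else {
                maskGrid <- VolumeGrid(array(as.integer(unionMask +
                    (compMasks$trabecular | compMasks$metastasis) +
                    compMasks$metastasis), dims),
                    labs@spacing, labs@origin, "LABEL")
                # codes: 1 = cortical, 2 = trabecular, 3 = metastasis
                occ <- resampleMaskToGrid(maskGrid, spect, classes = 1:3)
                for (i in 1:3) {
                    if (sum(occ[[i]]@data) > 0)
                        cnts[comp3[i]] <- meanCounts(spect, occ[[i]])
                }
                wAll <- occ[[1]]@data + occ[[2]]@data + occ[[3]]@data
                if (sum(wAll) > 0)
                    cntSkel <- sum(wAll * spect@data) / sum(wAll)
            }
        }
        sVol <- sum(vols)
        inv <- if (vols[["trabecular"]] > 0)
            100 * vols[["metastasis"]] / vols[["trabecular"]] else NA_real_
        huSkel <- if (any(unionMask)) mean(ct@data[unionMask]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
            region = rg,
            compartment = c(comp3, "skeletal"),
            volume_ml = c(unname(vols), sVol),
            mean_hu = c(unname(meanHu), huSkel),
            mean_counts_per_voxel = c(unname(cnts), cntSkel),
            inv_percent = c(rep(NA_real_, 3), inv),
            region_missing = missing,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Write a regional report as CSV and JSON
#'
#' @param report data.frame from \code{\link{regionalReport}}.
#' @param stem Output path stem; writes \code{<stem>.csv} and
#'   \code{<stem>.json}.
#' @return Character vector of the two paths, invisibly.
#' @export
writeQuantReport <- function(report, stem) {
    csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
    utils::write.csv(report, csv, row.names = FALSE)
    jsonlite::write_json(report, js, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
    invisible(c(csv, js))
}
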