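# Binary morphology helpers. Implemented with explicit shifts so that
# pixels outside the image count as background (an edge-touching mask must
# still erode at the image border), and with union-find merging to obtain
# 8-connectivity in-plane and 26-connectivity through-plane on top of
# EBImage's 4-connected labelling.

.shiftMatrix <- function(m, dx, dy) {
    # shift by (dx, dy), filling vacated cells with 0
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
}

#' Erode a binary mask in-plane
#'
#' One erosion step removes every pixel with any background pixel in its
#' 3 x 3 (Chebyshev) neighbourhood; pixels outside the image count as
#' background. Applied \code{k} times. With \code{k} equal to the rim
#' thickness, \code{mask & !erodeMask(mask, k)} is exactly the set of
#' pixels at Chebyshev distance < k from the complement.
#'
#' @param mask Logical or 0/1 integer matrix.
#' @param k Number of one-pixel erosion layers to remove.
#' @return Logical matrix.
#' @export
#' @examples
#' disc <- outer(-10:10, -10:10, function(x, y) x^2 + y^2 <= 64)
#' sum(disc) - sum(erodeMask(disc, 2))  # pixel count of a 2-px rim
erodeMask <- function(mask, k = 1L) {
    m <- mask != 0
    storage.mode(m) <- "integer"
    for (i in seq_len(k)) {
        acc <- m
        for (dx in -1:1) for (dy in -1:1) {
            if (dx == 0 && dy == 0) next
            acc <- acc & .shiftMatrix(m, dx, dy)
        }
        m <- acc
        storage.mode(m) <- "integer"
        if (!any(m == 1L)) break
    }
    m == 1L
}

.dilateMask2d <- function(mask, k = 1L) {
    m <- mask != 0
    storage.mode(m) <- "integer"
    for (i in seq_len(k)) {
        acc <- m
        for (dx in -1:1) for (dy in -1:1) {
            if (dx == 0 && dy == 0) next
            acc <- acc | .shiftMatrix(m, dx, dy)
        }
        m <- acc
        storage.mode(m) <- "integer"
    }
    m == 1L
}

# union-find with path halving
.ufFind <- function(parent, i) {
    while (parent[i] != i) {
        parent[i] <- parent[parent[i]]
        i <- parent[i]
    }
    i
}

.mergePairs <- function(nlab, pairs) {
    parent <- seq_len(nlab)
    if (nrow(pairs)) {
        for (r in seq_len(nrow(pairs))) {
            a <- .ufFind(parent, pairs[r, 1]); b <- .ufFind(parent, pairs[r, 2])
            if (a != b) parent[max(a, b)] <- min(a, b)
        }
    }
    roots <- vapply(seq_len(nlab), function(i) .ufFind(parent, i), integer(1))
    match(roots, sort(unique(roots)))
}

# 8-connected 2D labelling: EBImage 4-connected labels merged across
# diagonal adjacencies
.label2d8 <- function(mask) {
    m <- mask != 0
    storage.mode(m) <- "double"
    lab <- EBImage::bwlabel(m)
    nlab <- max(lab)
    if (nlab <= 1L) return(list(labels = lab, n = nlab))
    pairs <- NULL
    for (sh in list(c(1, 1), c(1, -1))) {
        a <- lab
        b <- .shiftMatrix(lab, sh[1], sh[2])
        sel <- a > 0 & b > 0 & a != b
        if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
    }
    if (is.null(pairs)) return(list(labels = lab, n = nlab))
    remap <- .mergePairs(nlab, unique(pairs))
    lab[lab > 0] <- remap[lab[lab > 0]]
    list(labels = lab, n = max(remap))
}

# 26-connected 3D labelling: per-slice 8-connected labels merged across
# slices wherever a voxel in slice z+1 has any of the 9 in-plane
# neighbours labelled in slice z
.label3d26 <- function(arr) {
    d <- dim(arr)
    labs <- array(0L, d)
    offset <- 0L
    nper <- integer(d[3])
    for (z in seq_len(d[3])) {
        l2 <- .label2d8(arr[, , z] != 0)
        sl <- l2$labels
        sl[sl > 0] <- sl[sl > 0] + offset
        labs[, , z] <- sl
        nper[z] <- l2$n
        offset <- offset + l2$n
    }
    nlab <- offset
    if (nlab <= 1L) return(list(labels = labs, n = nlab))
    pairs <- NULL
    for (z in seq_len(d[3] - 1L)) {
        a <- labs[, , z]; b <- labs[, , z + 1L]
        if (!any(a > 0) || !any(b > 0)) next
        for (dx in -1:1) for (dy in -1:1) {
            as <- if (dx == 0 && dy == 0) a else .shiftMatrix(a, dx, dy)
            sel <- as > 0 & b > 0
            if (any(sel)) pairs <- rbind(pairs, unique(cbind(as[sel], b[sel])))
        }
    }
    if (is.null(pairs)) return(list(labels = labs, n = nlab))
    remap <- .mergePairs(nlab, unique(pairs))
    labs[labs > 0] <- remap[labs[labs > 0]]
    list(labels = labs, n = max(remap))
}

# 3D binary dilation by an axis-aligned box of half-widths r = c(rx, ry, rz)
# voxels (separable OR of shifts)
.dilate3dBox <- function(arr, r) {
    a <- arr != 0
    d <- dim(a)
    for (ax in 1:3) {
        if (r[ax] < 1) next
        acc <- a
        for (s in seq_len(r[ax])) {
            idx <- seq_len(d[ax])
            lo <- pmin(pmax(idx - s, 1L), d[ax])
            hi <- pmin(pmax(idx + s, 1L), d[ax])
            lo[idx - s < 1] <- NA; hi[idx + s > d[ax]] <- NA
            shL <- array(FALSE, d); shR <- array(FALSE, d)
            if (ax == 1) {
                ok <- !is.na(lo); shL[idx[ok], , ] <- a[lo[ok], , ]
                ok <- !is.na(hi); shR[idx[ok], , ] <- a[hi[ok], , ]
            } else if (ax == 2) {
                ok <- !is.na(lo); shL[, idx[ok], ] <- a[, lo[ok], ]
                ok <- !is.na(hi); shR[, idx[ok], ] <- a[, hi[ok], ]
            } else {
                ok <- !is.na(lo); shL[, , idx[ok]] <- a[, , lo[ok]]
                ok <- !is.na(hi); shR[, , idx[ok]] <- a[, , hi[ok]]
            }
            acc <- acc | shL | shR
        }
        a <- acc
    }
    a
}
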