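# Independent brute-force oracles and small geometry builders used across
# the suite. These deliberately avoid the package's own code paths.

# Raster-scan border oracle: walk each row, mark the span between the
# first and last crossing of `thr` as inside (valid for convex
# structures); border = inside pixels with an outside 8-neighbour.
rasterScanOracle <- function(slice, thr) {
    filled <- matrix(FALSE, nrow(slice), ncol(slice))
    for (i in seq_len(nrow(slice))) {
        hit <- which(slice[i, ] >= thr)
        if (length(hit)) filled[i, min(hit):max(hit)] <- TRUE
    }
    border <- matrix(FALSE, nrow(slice), ncol(slice))
    nr <- nrow(slice); nc <- ncol(slice)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!filled[i, j]) next
        for (dx in -1:1) for (dy in -1:1) {
            ii <- i + dx; jj <- j + dy
            if (ii < 1 || ii > nr || jj < 1 || jj > nc || !filled[ii, jj])
                border[i, j] <- TRUE
        }
    }
    list(filled = filled, border = border)
}

# Chebyshev distance to the mask complement, by brute force
chebyshevDistOracle <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    out <- matrix(0L, nr, nc)
    comp <- which(!mask, arr.ind = TRUE)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!mask[i, j]) next
        dEdge <- min(i, j, nr - i + 1, nc - j + 1)  # implicit outside
        d <- if (nrow(comp)) min(pmax(abs(comp[, 1] - i), abs(comp[, 2] - j)))
             else Inf
        out[i, j] <- min(d, dEdge)
    }
    out
}

# Pairwise-concordance AUC oracle (ties credited 1/2)
bruteForceAuc <- function(scores, positives) {
    pos <- scores[positives]; neg <- scores[!positives]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Closed-form reference statistics
refPearson <- function(x, y) {
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    df <- length(x) - 2
    t <- r * sqrt(df / (1 - r^2))
    list(r = r, t = t, p = 2 * stats::pt(-abs(t), df))
}
refTTest <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
        (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
refChisq <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - e)^2 / e)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    list(chisq = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# 2D slice builders (HU matrices)
makeAnnulusSlice <- function(n = 64, cx = NULL, rOut = 20, rIn = 16,
                             huRing = 800, huBg = 0, huIn = huBg) {
    if (is.null(cx)) cx <- (n + 1) / 2
    r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
    sl <- matrix(huBg, n, n)
    sl[r2 <= rOut^2] <- huRing
    sl[r2 <= rIn^2] <- huIn
    sl
}
makeDiscSlice <- function(n = 64, r = 20, hu = 600, huBg = 0) {
    cx <- (n + 1) / 2
    r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
    sl <- matrix(huBg, n, n)
    sl[r2 <= r^2] <- hu
    sl
}
sliceToCT <- function(sl, nz = 1, spacing = c(1.5, 1.5, 1.5)) {
    VolumeGrid(array(rep(sl, nz), c(nrow(sl), ncol(sl), nz)), spacing,
               modality = "CT")
}

# A compact single-bone phantom spec for fast tests
tinyPhantomSpec <- function(seed = 11, mets = list(
                                list(center = c(96, 96, 18), r = 14)),
                            lytic = list(), ...) {
    phantomSpec(ctDim = c(128L, 128L, 24L),
                spectDim = c(64L, 64L, 24L), spectSpacing = c(5, 5, 1.5),
                bones = list(list(type = "tube", center = c(96, 96),
                                  outerR = 40, shellMm = 3,
                                  zRange = c(1, 24), canalR = 0,
                                  canalWallMm = 0, region = "hip")),
                mets = mets, lyticLesions = lytic,
                calcifications = list(), seed = seed, ...)
}
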