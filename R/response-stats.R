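#' ROC analysis of a per-subject score
#'
#' Builds the full ROC curve and the area under it, with ties credited
#' 1/2, so the AUC equals the normalised pairwise concordance
#' (Mann-Whitney U / (n1 * n0)). \code{direction = "low"} handles scores
#' where low values indicate the positive class (as for tracer counts in
#' progressive disease).
#'
#' @param scores Numeric per-subject values.
#' @param positives Logical labels (TRUE = positive class).
#' @param direction \code{"high"} or \code{"low"}: which end of the score
#'   scale indicates the positive class.
#' @return An \linkS4class{ROCResult}.
#' @export
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))@auc  # 1
rocAuc <- function(scores, positives, direction = c("high", "low")) {
    direction <- match.arg(direction)
    stopifnot(length(scores) == length(positives), is.logical(positives))
    ok <- is.finite(scores) & !is.na(positives)
    scores <- scores[ok]; positives <- positives[ok]
    n1 <- sum(positives); n0 <- sum(!positives)
    if (n1 == 0 || n0 == 0)
        stop("ROC requires at least one positive and one negative")
    s <- if (direction == "low") -scores else scores
    r <- rank(s, ties.method = "average")
    auc <- (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # curve: rule 'oriented score >= t -> positive' at each observed value
    thr <- sort(unique(s), decreasing = TRUE)
    sens <- vapply(thr, function(t) mean(s[positives] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(s[!positives] < t), numeric(1))
    curve <- data.frame(
        threshold = c(Inf, if (direction == "low") -thr else thr, -Inf),
        sensitivity = c(0, sens, 1),
        specificity = c(1, spec, 0))
    new("ROCResult", auc = auc, curve = curve, direction = direction,
        nPos = as.integer(n1), nNeg = as.integer(n0))
}

#' Best ROC operating threshold by the Youden index
#'
#' Selects the threshold maximising J = sensitivity + specificity - 1,
#' breaking ties toward higher specificity. The returned threshold is the
#' midpoint of the gap between adjacent observed scores (for fully
#' separated groups, the midpoint of the separating gap), to be applied
#' as "score >= threshold is positive" (\code{direction = "high"}) or
#' "score <= threshold is positive" (\code{direction = "low"}).
#'
#' @param roc An \linkS4class{ROCResult}.
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{youden}.
#' @export
bestThreshold <- function(roc) {
    stopifnot(is(roc, "ROCResult"))
    cv <- roc@curve
    inner <- cv[is.finite(cv$threshold), , drop = FALSE]
    if (!nrow(inner)) stop("degenerate ROC curve")
    j <- inner$sensitivity + inner$specificity - 1
    best <- which(j == max(j))
    if (length(best) > 1)
        best <- best[which.max(inner$specificity[best])]
    tBest <- inner$threshold[best]
    # midpoint of the gap below (direction high) / above (direction low)
    # the selected observed score, in original score units
    obs <- sort(inner$threshold)
    pos <- match(tBest, obs)
    tMid <- if (roc@direction == "high") {
        if (pos > 1) (obs[pos - 1] + tBest) / 2 else tBest - 1
    } else {
        if (pos < length(obs)) (obs[pos + 1] + tBest) / 2 else tBest + 1
    }
    list(threshold = tMid, sensitivity = inner$sensitivity[best],
         specificity = inner$specificity[best], youden = j[best])
}

#' Pearson product-moment correlation with p-value
#'
#' Standard bivariate correlation; the p-value comes from the t transform
#' with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with \code{r}, \code{p}, \code{t}, \code{df}, \code{n}.
#' @export
pearsonR <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value,
         t = unname(ct$statistic), df = unname(ct$parameter),
         n = length(x))
}

#' Unpaired two-sample t-test (classical, equal variances)
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}, group means.
#' @export
unpairedTTest <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 observations")
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson chi-squared test on a 2 x k contingency table
#'
#' No continuity correction (matching conventional reporting of the
#' Pearson statistic).
#'
#' @param tab Matrix of non-negative integer counts.
#' @return List with \code{chisq}, \code{df}, \code{p}.
#' @export
chiSquared <- function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chisq = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Classify therapy response from baseline and follow-up studies
#'
#' Progressive disease (PD) if any follow-up metastasis component is a new
#' lesion — zero voxel overlap with the baseline metastasis mask dilated
#' by one SPECT voxel (tolerating registration jitter). Otherwise partial
#' response (PR) if whole-body metastasis mean counts/voxel dropped by at
#' least \code{uptakeDropFraction} (visibly diminished uptake); otherwise
#' stable disease (SD).
#'
#' @param baseline,followup Lists with elements \code{seg}
#'   (\linkS4class{SegmentationResult}) and \code{spect}
#'   (\linkS4class{VolumeGrid}), on co-registered grids.
#' @param uptakeDropFraction Relative drop in metastasis mean counts that
#'   qualifies as PR (default 0.25).
#' @return \code{"PD"}, \code{"SD"} or \code{"PR"}.
#' @export
classifyResponse <- function(baseline, followup, uptakeDropFraction = 0.25) {
    segB <- baseline$seg; segF <- followup$seg
    stopifnot(is(segB, "SegmentationResult"), is(segF, "SegmentationResult"))
    if (!sameGrid(segLabels(segB), segLabels(segF)))
        stop("baseline/follow-up grid mismatch")
    cls <- segClasses()
    metB <- segLabels(segB)@data == cls[["metastasis"]]
    metF <- segLabels(segF)@data == cls[["metastasis"]]
    ctSp <- voxelSpacing(segLabels(segB))
    spSp <- if (!is.null(baseline$spect)) voxelSpacing(baseline$spect) else
        rep(max(ctSp), 3)
    rad <- pmax(1L, as.integer(ceiling(spSp / ctSp)))
    metBdil <- if (any(metB)) .dilate3dBox(metB, rad) else metB
    if (any(metF)) {
        compF <- .label3d26(metF)
        for (k in seq_len(compF$n)) {
            if (!any(metBdil[compF$labels == k])) return("PD")
        }
    }
    uptake <- function(st) {
        seg <- st$seg; spect <- st$spect
        if (is.null(spect)) return(NA_real_)
        met <- segLabels(seg)@data == cls[["metastasis"]]
        if (!any(met)) return(NA_real_)
        if (sameGrid(segLabels(seg), spect))
            return(mean(spect@data[met]))
        mg <- VolumeGrid(array(as.integer(met), dim(met)),
                         voxelSpacing(segLabels(seg)),
                         voxelOrigin(segLabels(seg)), "LABEL")
        occ <- resampleMaskToGrid(mg, spect, classes = 1L)[[1]]
        meanCounts(spect, occ)
    }
    ub <- uptake(baseline); uf <- uptake(followup)
    if (is.finite(ub) && is.finite(uf) && ub > 0 &&
        (ub - uf) / ub >= uptakeDropFraction) "PR" else "SD"
}

#' Grouped mean +/- SD cohort summary with pairwise tests
#'
#' Summarises every numeric column of a cohort table as group mean and SD,
#' with pairwise unpaired t-tests between groups; logical columns (for
#' example a superscan flag) are summarised as prevalences and compared
#' with a chi-squared test across groups.
#'
#' @param records data.frame of per-patient rows.
#' @param groupBy Name of the grouping column.
#' @return List with \code{table} (one row per variable) and \code{tests}
#'   (one row per variable x group pair; NULL for a single group).
#' @export
cohortSummary <- function(records, groupBy) {
    stopifnot(is.data.frame(records), groupBy %in% names(records))
    g <- factor(records[[groupBy]])
    lv <- levels(g)
    if (any(table(g) < 2)) stop("each group needs at least 2 records")
    numCols <- names(records)[vapply(records, is.numeric, logical(1))]
    logCols <- names(records)[vapply(records, is.logical, logical(1))]
    fmtRows <- lapply(numCols, function(cn) {
        v <- records[[cn]]
        row <- data.frame(variable = cn, stringsAsFactors = FALSE)
        for (l in lv) {
            row[[paste0("mean_", l)]] <- mean(v[g == l], na.rm = TRUE)
            row[[paste0("sd_", l)]] <- stats::sd(v[g == l], na.rm = TRUE)
        }
        row
    })
    for (cn in logCols) {
        row <- data.frame(variable = cn, stringsAsFactors = FALSE)
        for (l in lv) {
            row[[paste0("mean_", l)]] <- mean(records[[cn]][g == l])
            row[[paste0("sd_", l)]] <- NA_real_
        }
        fmtRows[[length(fmtRows) + 1L]] <- row
    }
    tabOut <- do.call(rbind, fmtRows)
    tests <- NULL
    if (length(lv) > 1) {
        testRows <- list()
        for (cn in numCols) {
            v <- records[[cn]]
            for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
                tt <- unpairedTTest(v[g == lv[i]], v[g == lv[j]])
                testRows[[length(testRows) + 1L]] <- data.frame(
                    variable = cn, group_a = lv[i], group_b = lv[j],
                    statistic = tt$t, p = tt$p, test = "t",
                    stringsAsFactors = FALSE)
            }
        }
        for (cn in logCols) {
            tab <- table(records[[cn]], g)
            cs <- chiSquared(tab)
            testRows[[length(testRows) + 1L]] <- data.frame(
                variable = cn, group_a = "all", group_b = "all",
                statistic = cs$chisq, p = cs$p, test = "chisq",
                stringsAsFactors = FALSE)
        }
        tests <- do.call(rbind, testRows)
    }
    list(table = tabOut, tests = tests)
}

.rtruncnorm0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Simulate a superscan-stratified cohort
#'
#' Draws per-patient records from group-wise normal distributions
#' (truncated at zero) whose default means and SDs follow published
#' superscan vs non-superscan cohort statistics in metastatic CRPC
#' (for example INV\% 40 +/- 23 vs 21 +/- 16, metastasis mean HU
#' 693 +/- 132 vs 549 +/- 115, n = 12 vs 64).
#'
#' @param n Named integer vector \code{c(superscan = ..., non = ...)}.
#' @param params Named list: for each variable, a list of
#'   \code{c(mean, sd)} per group (\code{superscan}, \code{non}).
#' @param seed Optional seed.
#' @return data.frame with one row per patient.
#' @export
simulateCohort <- function(n = c(superscan = 12L, non = 64L),
                           params = list(
                               m_vol_ml = list(superscan = c(527, 304),
                                               non = c(245, 187)),
                               lesion_count = list(superscan = c(106, 22),
                                                   non = c(61, 23)),
                               inv_percent = list(superscan = c(40, 23),
                                                  non = c(21, 16)),
                               psa_ng_ml = list(superscan = c(1235, 959),
                                                non = c(257, 407)),
                               b_counts = list(superscan = c(565, 243),
                                               non = c(428, 164)),
                               m_counts = list(superscan = c(1104, 291),
                                               non = c(886, 251)),
                               b_hu = list(superscan = c(319, 78),
                                           non = c(223, 59)),
                               m_hu = list(superscan = c(693, 132),
                                           non = c(549, 115))),
                           seed = NULL) {
    draw <- function() {
        rows <- lapply(names(n), function(grp) {
            df <- data.frame(patient = paste0(grp, "_", seq_len(n[[grp]])),
                             superscan = grp == "superscan",
                             stringsAsFactors = FALSE)
            for (v in names(params))
                df[[v]] <- .rtruncnorm0(n[[grp]], params[[v]][[grp]][1],
                                        params[[v]][[grp]][2])
            df
        })
        do.call(rbind, rows)
    }
    if (is.null(seed)) draw() else .withSeed(seed, draw())
}

#' Simulate a therapy-response cohort (PD/SD/PR)
#'
#' Default parameters follow published response-stratified counts/voxel
#' statistics (PD markedly lower than SD/PR in both the metastasis and
#' trabecular compartments, n = 21/35/20).
#'
#' @param n Named integer vector over \code{PD}, \code{SD}, \code{PR}.
#' @param params Named list of per-group \code{c(mean, sd)} as in
#'   \code{\link{simulateCohort}}.
#' @param seed Optional seed.
#' @return data.frame with one row per patient; \code{response} column.
#' @export
simulateResponseCohort <- function(n = c(PD = 21L, SD = 35L, PR = 20L),
                                   params = list(
                                       m_vol_ml = list(PD = c(245, 312),
                                                       SD = c(342, 203),
                                                       PR = c(373, 254)),
                                       b_counts = list(PD = c(275, 60),
                                                       SD = c(528, 162),
                                                       PR = c(515, 188)),
                                       m_counts = list(PD = c(715, 190),
                                                       SD = c(1058, 255),
                                                       PR = c(975, 219)),
                                       b_hu = list(PD = c(232, 81),
                                                   SD = c(253, 68),
                                                   PR = c(264, 82)),
                                       m_hu = list(PD = c(545, 157),
                                                   SD = c(605, 120),
                                                   PR = c(610, 127))),
                                   seed = NULL) {
    draw <- function() {
        rows <- lapply(names(n), function(grp) {
            df <- data.frame(patient = paste0(grp, "_", seq_len(n[[grp]])),
                             response = grp, stringsAsFactors = FALSE)
            for (v in names(params))
                df[[v]] <- .rtruncnorm0(n[[grp]], params[[v]][[grp]][1],
                                        params[[v]][[grp]][2])
            df
        })
        do.call(rbind, rows)
    }
    if (is.null(seed)) draw() else .withSeed(seed, draw())
}
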