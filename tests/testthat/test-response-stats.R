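test_that("AUC equals brute-force pairwise concordance on random instances", {
    set.seed(303)
    for (i in 1:100) {
        n <- sample(4:30, 1)
        sc <- sample(seq_len(8), n, replace = TRUE) + rnorm(n, 0, 0.01)
        lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(lb) || all(lb)) lb[c(1, n)] <- c(TRUE, FALSE)
        roc <- rocAuc(sc, lb)
        expect_identical(roc@auc, bruteForceAuc(sc, lb))
        # AUC equals the trapezoidal area of the stored curve
        fpr <- 1 - roc@curve$specificity; tpr <- roc@curve$sensitivity
        trap <- sum(diff(fpr) * (utils::head(tpr, -1) +
                                 utils::tail(tpr, -1)) / 2)
        expect_equal(trap, roc@auc, tolerance = 1e-12)
    }
})

test_that("AUC is invariant under increasing transforms and flips with sign", {
    set.seed(404)
    sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
    a <- rocAuc(sc, lb)@auc
    expect_equal(rocAuc(exp(sc / 3), lb)@auc, a)
    expect_equal(rocAuc(rank(sc) * 1.0, lb)@auc, a)
    expect_equal(rocAuc(-sc, lb)@auc + a, 1)  # tie-free data
    expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))@auc, 1)
    expect_equal(rocAuc(rep(2, 6), rep(c(TRUE, FALSE), 3))@auc, 0.5)
    expect_error(rocAuc(1:4, rep(TRUE, 4)), "at least one")
})

test_that("AUC agrees with an independent ROC implementation", {
    set.seed(505)
    for (i in 1:10) {
        sc <- rnorm(30) + rep(c(0.8, 0), 15)
        lb <- rep(c(TRUE, FALSE), 15)
        ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<")))
        expect_equal(rocAuc(sc, lb)@auc, ref, tolerance = 1e-12)
    }
})

test_that("Youden threshold lands in the separating gap with the right J", {
    r <- rocAuc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                direction = "low")
    bt <- bestThreshold(r)
    expect_equal(bt$threshold, 2.5)
    expect_equal(bt$youden, 1)
    expect_equal(bt$sensitivity, 1); expect_equal(bt$specificity, 1)

    r2 <- rocAuc(c(10, 11, 30, 31), c(FALSE, FALSE, TRUE, TRUE))
    expect_equal(bestThreshold(r2)$threshold, 20.5)  # midpoint of the gap

    # exhaustive-scan cross-check on a tied, imperfect instance
    sc <- c(1, 2, 2, 3, 4, 5, 6, 6); lb <- c(T, T, F, T, F, F, T, F)
    bt3 <- bestThreshold(rocAuc(sc, lb))
    jScan <- max(vapply(sort(unique(sc)), function(t)
        mean(sc[lb] >= t) + mean(sc[!lb] < t) - 1, numeric(1)))
    expect_equal(bt3$youden, jScan)
})

test_that("low-uptake progression cohorts recover the optimal operating point", {
    # PD counts ~ N(275, 60), non-PD ~ N(520, 170), n = 21/55. The
    # population Youden-optimal point (closed-form grid oracle) is
    # t* = 375.5 with sens* = 0.953, spec* = 0.802, J* = 0.755; the
    # sample-recovered threshold should sit at that point on average,
    # with the usual small finite-sample optimism in J.
    tg <- seq(200, 700, 0.1)
    Jg <- stats::pnorm((tg - 275) / 60) - stats::pnorm((tg - 520) / 170)
    tStar <- tg[which.max(Jg)]; jStar <- max(Jg)
    sensStar <- stats::pnorm((tStar - 275) / 60)
    specStar <- 1 - stats::pnorm((tStar - 520) / 170)
    set.seed(606)
    res <- t(replicate(200, {
        sc <- c(rnorm(21, 275, 60), rnorm(55, 520, 170))
        lb <- rep(c(TRUE, FALSE), c(21, 55))
        bt <- bestThreshold(rocAuc(sc, lb, direction = "low"))
        c(bt$threshold, bt$sensitivity, bt$specificity, bt$youden)
    }))
    expect_lt(abs(mean(res[, 1]) - tStar), 20)
    expect_lt(abs(mean(res[, 2]) - sensStar), 0.05)
    expect_lt(abs(mean(res[, 3]) - specStar), 0.05)
    expect_gte(mean(res[, 4]), jStar)          # optimism, never pessimism
    expect_lt(mean(res[, 4]), jStar + 0.1)
})

test_that("correlation and group tests match closed-form references to 1e-10", {
    set.seed(707)
    for (i in 1:50) {
        n <- sample(5:40, 1)
        x <- rnorm(n); y <- 0.5 * x + rnorm(n)
        pr <- pearsonR(x, y); ref <- refPearson(x, y)
        expect_equal(pr$r, ref$r, tolerance = 1e-10)
        expect_equal(pr$p, ref$p, tolerance = 1e-10)
        a <- rnorm(sample(4:20, 1), 1); b <- rnorm(sample(4:20, 1))
        tt <- unpairedTTest(a, b); rt <- refTTest(a, b)
        expect_equal(tt$t, rt$t, tolerance = 1e-10)
        expect_equal(tt$df, rt$df)
        expect_equal(tt$p, rt$p, tolerance = 1e-10)
        tab <- matrix(sample(5:40, 4), 2)
        cs <- chiSquared(tab); rc <- refChisq(tab)
        expect_equal(cs$chisq, rc$chisq, tolerance = 1e-10)
        expect_equal(cs$p, rc$p, tolerance = 1e-10)
    }
    expect_equal(pearsonR(1:10, 2 * (1:10) + 1)$r, 1)
    expect_equal(pearsonR(1:10, -(1:10))$r, -1)
    expect_error(pearsonR(rep(1, 5), 1:5), "zero variance")
    expect_equal(unpairedTTest(c(1, 2, 3), c(1, 2, 3))$t, 0)
    expect_equal(chiSquared(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
})

test_that("response classification follows the new-lesion and uptake rules", {
    ph <- generatePhantom(tinyPhantomSpec(seed = 808))
    seg <- segmentSkeleton(ph$ct)
    base <- list(seg = seg, spect = ph$spect)

    # identical studies: stable disease
    expect_equal(classifyResponse(base, base), "SD")

    # uptake halved with identical lesions: partial response
    sp2 <- ph$spect; sp2@data <- sp2@data * 0.5
    expect_equal(classifyResponse(base, list(seg = seg, spect = sp2)), "PR")
    # a sub-threshold drop stays SD
    sp3 <- ph$spect; sp3@data <- sp3@data * 0.9
    expect_equal(classifyResponse(base, list(seg = seg, spect = sp3)), "SD")

    # one added disjoint lesion: progressive disease, whatever the uptake
    spec2 <- tinyPhantomSpec(seed = 808, mets = list(
        list(center = c(96, 96, 18), r = 14),
        list(center = c(70, 70, 8), r = 6)))
    ph2 <- generatePhantom(spec2)
    seg2 <- segmentSkeleton(ph2$ct)
    fup <- list(seg = seg2, spect = sp2)
    expect_equal(classifyResponse(base, fup), "PD")
    expect_error(classifyResponse(base, list(
        seg = segmentSkeleton(VolumeGrid(array(40, c(8, 8, 4)),
                                         c(1.5, 1.5, 1.5),
                                         modality = "CT")))),
        "grid mismatch")
})

test_that("cohort summaries report group means, SDs and pairwise tests", {
    df <- simulateCohort(seed = 99)
    sm <- cohortSummary(df, "superscan")
    expect_true(all(c("mean_TRUE", "mean_FALSE") %in% names(sm$table)))
    inv <- sm$table[sm$table$variable == "inv_percent", ]
    expect_gt(inv$mean_TRUE, inv$mean_FALSE)  # superscan INV% higher
    expect_true(all(sm$tests$p >= 0 & sm$tests$p <= 1))

    # identical groups: all t-test p-values are 1
    same <- data.frame(g = rep(c("a", "b"), each = 4),
                       v = rep(c(1, 2, 3, 4), 2))
    sm2 <- cohortSummary(same, "g")
    expect_equal(sm2$tests$p[sm2$tests$variable == "v"], 1)

    # single group: summary without tests
    one <- data.frame(g = rep("a", 5), v = rnorm(5))
    expect_null(cohortSummary(one, "g")$tests)
    expect_error(cohortSummary(data.frame(g = c("a", "b"), v = 1:2), "g"),
                 "at least 2")
})

test_that("simulated response cohorts show the PD low-uptake pattern", {
    df <- simulateResponseCohort(seed = 101)
    m <- tapply(df$b_counts, df$response, mean)
    expect_lt(m[["PD"]], m[["SD"]])
    expect_lt(m[["PD"]], m[["PR"]])
    expect_equal(unname(table(df$response)[c("PD", "SD", "PR")]),
                 c(21L, 35L, 20L), ignore_attr = TRUE)
})
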