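test_that("extractVoiHU returns the region's voxels and errors on unknowns", {
    tv <- tinyVolumeAndMask(c(42, 42, 42, 42, 42))
    hu <- extractVoiHU(tv$ct, tv$mask, "bm")
    expect_identical(hu, rep(42, 5))
    expect_error(extractVoiHU(tv$ct, tv$mask, "sternum"),
                 regexp = "sternum", class = "bmq_lookup_error")
})

test_that("histograms count in-range values per 1-HU bin and track overflow", {
    h <- buildHistogram(c(-10, -10, 20), range = c(-50, 50))
    expect_equal(h@counts[h@binCenters == -10], 2)
    expect_equal(h@counts[h@binCenters == 20], 1)
    expect_equal(h@totalVoxels, 3)
    expect_equal(h@outOfRange, 0)

    h2 <- buildHistogram(c(0, 2000), range = c(-500, 1500))
    expect_equal(sum(h2@counts), 1)
    expect_equal(h2@outOfRange, 1)
    expect_error(buildHistogram(numeric(0)), class = "bmq_config_error")

    s <- sampleVoxelClasses(100000, 1, c(42, 30), c(0, 1), seed = 31)
    h3 <- buildHistogram(s$positive)
    expect_lt(abs(h3@binCenters[which.max(h3@counts)] - 42), 2.5)
})

test_that("cohort summary averages per-subject proportions with SEM", {
    h1 <- buildHistogram(rep(10, 10), range = c(0, 20))
    s0 <- summarizeCohort(list(h1, h1))
    expect_true(all(s0@semProportion == 0))

    # proportions 0.2 vs 0.4 in bin 10 -> mean 0.3, SEM = sd/sqrt(2) = 0.1
    a <- buildHistogram(c(rep(10, 2), rep(15, 8)), range = c(0, 20))
    b <- buildHistogram(c(rep(10, 4), rep(15, 6)), range = c(0, 20))
    s <- summarizeCohort(list(a, b))
    i <- which(s@binCenters == 10)
    expect_equal(s@meanProportion[i], 0.3)
    expect_equal(s@semProportion[i], 0.1)

    expect_error(summarizeCohort(list(a)), class = "bmq_config_error")
    cOther <- buildHistogram(rep(10, 3), range = c(0, 25))
    expect_error(summarizeCohort(list(a, cOther)), class = "bmq_config_error")
})

test_that("ROC and optimal threshold match brute-force enumeration exactly", {
    set.seed(77)
    for (rep in 1:20) {
        nP <- sample(2:50, 1); nN <- sample(2:50, 1)
        pos <- round(rnorm(nP, 50, 40))
        neg <- round(rnorm(nN, 150, 40))
        roc <- computeROC(pos, neg)
        oracle <- bruteForceRoc(pos, neg)
        shared <- intersect(thresholds(roc), oracle$t)
        io <- match(shared, oracle$t); ir <- match(shared, thresholds(roc))
        expect_equal(sensitivity(roc)[ir], oracle$sens[io])
        expect_equal(specificity(roc)[ir], oracle$spec[io])
        expect_identical(optimalThreshold(roc), bruteForceOptimum(pos, neg))
        expect_equal(auc(roc), mannWhitneyAuc(pos, neg), tolerance = 1e-9)
    }
})

test_that("toy separable classes give a perfect operating point at t = 121", {
    roc <- computeROC(c(10, 50, 120), c(130, 200, 250))
    t <- optimalThreshold(roc)
    expect_identical(t, 121)
    i <- which(thresholds(roc) == t)
    expect_equal(sensitivity(roc)[i], 1)
    expect_equal(specificity(roc)[i], 1)
    expect_equal(auc(roc), 1)
})

test_that("identical class samples give AUC one half", {
    x <- c(10, 20, 30, 40)
    expect_equal(auc(computeROC(x, x)), 0.5)
})

test_that("ROC curves agree with pROC on random samples", {
    skip_if_not_installed("pROC")
    set.seed(101)
    pos <- round(rnorm(300, 60, 35)); neg <- round(rnorm(250, 170, 35))
    roc <- computeROC(pos, neg)
    ref <- pROC::roc(response = c(rep(1, length(pos)), rep(0, length(neg))),
                     predictor = c(pos, neg), direction = ">",
                     quiet = TRUE)
    expect_equal(auc(roc), as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("sensitivity is non-decreasing and specificity non-increasing in t", {
    set.seed(55)
    for (rep in 1:5) {
        s <- sampleVoxelClasses(500, 500, c(40, 35), c(180, 40), seed = rep)
        roc <- computeROC(s$positive, s$negative)
        expect_true(all(diff(sensitivity(roc)) >= 0))
        expect_true(all(diff(specificity(roc)) <= 0))
        expect_true(all(sensitivity(roc) >= 0 & sensitivity(roc) <= 1))
    }
})

test_that("equal-variance Gaussian classes recover the mean midpoint", {
    for (seed in 1:5) {
        s <- sampleVoxelClasses(100000, 100000, c(42, 30), c(188, 30),
                                seed = seed)
        t <- optimalThreshold(computeROC(s$positive, s$negative))
        expect_lte(abs(t - 115), 2)
    }
})

test_that("threshold-scheme derivation wires both cutpoints", {
    bmat <- sampleVoxelClasses(50000, 1, c(42, 30), c(0, 1), seed = 1)$positive
    rm_ <- sampleVoxelClasses(50000, 1, c(188, 30), c(0, 1), seed = 2)$positive
    bone <- sampleVoxelClasses(50000, 1, c(412, 55), c(0, 1), seed = 3)$positive
    der <- deriveThresholdScheme(bmat, rm_, bone)
    th <- thresholds(der$scheme)
    expect_equal(th[["yellow_low"]], -200)
    # equal-variance pair: analytic optimum is the mean midpoint, 115
    expect_lte(abs(th[["bmat_rm"]] - 115), 3)
    # RM(188,30) vs bone(412,55): analytic Youden optimum ~271.5 HU
    # (root of the density cross-over, computed by numeric root-finding)
    expect_lte(abs(th[["rm_bone"]] - 271), 4)

    # without a bone sample the RM/bone cutpoint keeps its fallback
    der2 <- deriveThresholdScheme(bmat, rm_)
    expect_equal(thresholds(der2$scheme)[["rm_bone"]], 300)
})
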