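test_that("classifyHU places boundary values per the scheme's intervals", {
    sch <- thresholdScheme()
    expect_identical(classifyHU(c(114, 115, 300, 301, -200, -201), sch),
                     c("BMAT", "RM", "RM", "BONE", "BMAT", "OUT_OF_RANGE"))
})

test_that("classifyHU agrees with a 4-way interval lookup on random HU", {
    sch <- thresholdScheme()
    oracle <- function(h) {
        if (h < -200) "OUT_OF_RANGE"
        else if (h < 115) "BMAT"
        else if (h <= 300) "RM"
        else "BONE"
    }
    set.seed(3)
    hu <- sample(-1200:1500, 500)
    expect_identical(classifyHU(hu, sch),
                     vapply(hu, oracle, character(1)))
})

test_that("segmentation counts each class and conserves the VOI size", {
    hu <- c(-250, -100, 0, 114, 115, 250, 300, 301)
    tv <- tinyVolumeAndMask(hu, shape = c(2, 2, 2))
    seg <- segmentBM(tv$ct, tv$mask, "bm")
    expect_equal(classCounts(seg)[["BMAT"]], 3)
    expect_equal(classCounts(seg)[["RM"]], 3)
    expect_equal(classCounts(seg)[["BONE"]], 1)
    expect_equal(classCounts(seg)[["OUT_OF_RANGE"]], 1)
    expect_equal(sum(classCounts(seg)), 8)

    # permuting voxel order leaves counts unchanged
    tv2 <- tinyVolumeAndMask(rev(hu), shape = c(2, 2, 2))
    expect_identical(classCounts(segmentBM(tv2$ct, tv2$mask, "bm")),
                     classCounts(seg))
})

test_that("class counts sum to the VOI size for random volumes", {
    set.seed(13)
    for (rep in 1:10) {
        n <- sample(10:300, 1)
        hu <- round(runif(n, -1500, 2000))
        tv <- tinyVolumeAndMask(hu, shape = c(7, 7, 7))
        seg <- segmentBM(tv$ct, tv$mask, "bm")
        expect_equal(sum(classCounts(seg)), n)
    }
})

test_that("Ad.V/Ma.V is the BMAT percentage and scales with voxel volume", {
    hu <- c(-250, -100, 0, 114, 115, 250, 300, 301)
    tv <- tinyVolumeAndMask(hu, shape = c(2, 2, 2))
    adv <- adiposityFraction(segmentBM(tv$ct, tv$mask, "bm"))
    expect_equal(adv$ad_v_over_ma_v, 37.5)  # 3 of 8 voxels
    expect_equal(adv$volumes_mL[["total"]], 8 / 1000)

    # rescaling the voxel spacing leaves the ratio invariant and scales
    # absolute volumes by the spacing product
    tv2 <- tinyVolumeAndMask(hu, shape = c(2, 2, 2), spacing = c(2, 2, 5))
    adv2 <- adiposityFraction(segmentBM(tv2$ct, tv2$mask, "bm"))
    expect_equal(adv2$ad_v_over_ma_v, adv$ad_v_over_ma_v)
    expect_equal(adv2$volumes_mL[["total"]], 8 * 20 / 1000)

    allFat <- tinyVolumeAndMask(rep(50, 8), shape = c(2, 2, 2))
    expect_equal(adiposityFraction(segmentBM(allFat$ct, allFat$mask,
                                             "bm"))$ad_v_over_ma_v, 100)

    # soft-tissue denominator drops bone and out-of-range voxels
    advST <- adiposityFraction(segmentBM(tv$ct, tv$mask, "bm"),
                               denominator = "soft_tissue")
    expect_equal(advST$ad_v_over_ma_v, 100 * 3 / 6)
})

test_that("phantoms recover Ad.V/Ma.V within 1.5 points across fractions", {
    for (seed in 1:3) {
        for (frac in c(0.1, 0.5, 0.9)) {
            ph <- generateHumanPhantom(phantomConfig(
                gridShape = c(64, 64, 40),
                bmRegions = data.frame(name = "bm", n_voxels = 100000L,
                                       bmat_fraction = frac),
                seed = seed))
            adv <- adiposityFraction(segmentBM(ph$ct, ph$masks, "bm"))
            expect_lt(abs(adv$ad_v_over_ma_v - 100 * frac), 1.5)
        }
    }
})

test_that("decay correction doubles activity per elapsed half-life", {
    expect_equal(decayCorrect(0.5, 109.77), 1.0)
    expect_equal(decayCorrect(3.2, 0), 3.2)
    expect_equal(decayCorrect(1.0, 219.54, 109.77), 4.0)
    expect_error(decayCorrect(1.0, -10), class = "bmq_config_error")
})

test_that("%ID/g normalizes decay-corrected activity by dose and mass", {
    # activity 0.02 MBq already at injection time (elapsed ~ 0)
    s <- gammaSample(countsPerMinute = 2000, counterConversion = 1e-5,
                     tissueMass = 0.1, elapsedSinceInjection = 1e-9)
    expect_equal(percentIdPerG(s, dose = 10), 2.0, tolerance = 1e-6)

    # whole dose in 1 g, one half-life elapsed: decay correction restores 100
    s2 <- gammaSample(countsPerMinute = 5e5, counterConversion = 1e-5,
                      tissueMass = 1, elapsedSinceInjection = 109.77)
    expect_equal(percentIdPerG(s2, dose = 10), 100)

    # doubling tissue mass halves %ID/g
    s3 <- gammaSample(2000, 1e-5, 0.2, 1e-9)
    expect_equal(percentIdPerG(s3, 10), 1.0, tolerance = 1e-6)
    expect_error(gammaSample(2000, 1e-5, 0, 10), class = "bmq_config_error")
})

test_that("SUV has its normalization fixed point and skips empty classes", {
    params <- suvParams(injectedDose = 185, bodyMass = 60000)
    # uniform concentration equal to dose/bodyMass (kBq/g) -> SUV 1 everywhere
    conc <- 185 * 1000 / 60000
    n <- 27
    vals <- rep(conc, n)
    pet <- voxelVolume(array(vals, c(3, 3, 3)), modality = "PET")
    mask <- voiMask(array(1L, c(3, 3, 3)), c("1" = "bm"))
    ctv <- voxelVolume(array(50, c(3, 3, 3)), modality = "CT")
    seg <- segmentBM(ctv, mask, "bm")
    suv <- compartmentSUV(pet, mask, "bm", seg, params)
    expect_equal(unname(suv[["BMAT"]]), 1)
    expect_false("BONE" %in% names(suv))  # no bone voxels -> absent, not 0
    expect_equal(unname(regionSUV(pet, mask, "bm", params)), 1)

    # concentration 5 kBq/mL, 185 MBq, 60 kg -> SUV ~ 1.62
    pet5 <- voxelVolume(array(5, c(3, 3, 3)), modality = "PET")
    expect_equal(unname(regionSUV(pet5, mask, "bm", params)),
                 5 / (185000 / 60000))
    expect_error(suvParams(0, 60000), class = "bmq_config_error")
})

test_that("morphometry computes density, area fraction and locularity", {
    ann <- adipocyteAnnotationSet(2, data.frame(
        area_mm2 = rep(0.05, 10),
        small_droplet_count = c(rep(0L, 7), 3L, 4L, 2L)))
    m <- morphometry(ann)
    expect_equal(m$n_ad_per_marrow_area, 5)          # 10 cells / 2 mm^2
    expect_equal(m$ad_area_fraction, 25)             # 0.5 / 2 mm^2
    expect_equal(m$multilocular_count, 2L)           # droplet counts 3 and 4
    expect_equal(m$multilocular_fraction, 0.2)

    empty <- adipocyteAnnotationSet(1.5)
    expect_equal(morphometry(empty)$n_ad_per_marrow_area, 0)
    expect_true(is.na(morphometry(empty)$multilocular_fraction))
})
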