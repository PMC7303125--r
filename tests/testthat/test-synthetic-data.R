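test_that("phantom truth records the exact generated BMAT split", {
    cfg <- phantomConfig(gridShape = c(64, 64, 40),
                         bmRegions = data.frame(name = "bm",
                                                n_voxels = 100000L,
                                                bmat_fraction = 0.70),
                         seed = 11)
    ph <- generateHumanPhantom(cfg)
    expect_identical(ph$truth$true_bmat_fraction[["bm"]], 0.70)
    # recomputing the fraction from the per-voxel truth classes agrees exactly
    cls <- ph$truth$region_class[["bm"]]
    expect_identical(mean(cls == "BMAT"), 0.70)
    expect_identical(dim(ph$truth$label_grid), dim(voxelData(ph$ct)))
})

test_that("phantom generation is bit-identical under a repeated seed", {
    cfg <- phantomConfig(seed = 42)
    a <- generateHumanPhantom(cfg)
    b <- generateHumanPhantom(cfg)
    expect_identical(voxelData(a$ct), voxelData(b$ct))
    expect_identical(voxelData(a$pet), voxelData(b$pet))
    expect_identical(a$truth, b$truth)
})

test_that("compartment HU distributions match their configured parameters", {
    cfg <- phantomConfig(gridShape = c(64, 64, 40),
                         bmRegions = data.frame(name = "bm",
                                                n_voxels = 100000L,
                                                bmat_fraction = 1.0),
                         seed = 5)
    ph <- generateHumanPhantom(cfg)
    hu <- extractVoiHU(ph$ct, ph$masks, "bm")
    # SE of the mean = 30 / sqrt(1e5) ~ 0.095; 0.5 HU is > 5 SE
    expect_lt(abs(mean(hu) - 42), 0.5)
    expect_lt(abs(sd(hu) - 30), 0.5)
})

test_that("per-compartment means and SDs stay within 5 standard errors", {
    ph <- generateHumanPhantom(phantomConfig(gridShape = c(48, 48, 48),
                                             seed = 9))
    comp <- defaultCompartments()
    for (nm in c("scWAT", "muscle", "trabecular_bone")) {
        hu <- extractVoiHU(ph$ct, ph$masks, nm)
        row <- comp[comp$name == nm, ]
        se <- row$hu_sd / sqrt(length(hu))
        # integer-HU rounding adds variance 1/12, allow 0.3 HU on top of 5 SE
        expect_lt(abs(mean(hu) - row$hu_mean), 5 * se + 0.3)
    }
})

test_that("voxel-class sampling honours degenerate SDs, tails and seeds", {
    s <- sampleVoxelClasses(3, 3, c(10, 0), c(200, 0), seed = 1)
    expect_identical(s$positive, c(10, 10, 10))
    expect_identical(s$negative, c(200, 200, 200))

    s2 <- sampleVoxelClasses(100000, 1, c(42, 30), c(188, 30), seed = 2)
    # P(HU < 115) = pnorm((115 - 42)/30) = pnorm(2.4333) ~ 0.99252
    expect_lt(abs(mean(s2$positive < 115) - pnorm((115 - 42) / 30)), 0.005)

    expect_identical(sampleVoxelClasses(50, 50, c(0, 1), c(5, 1), seed = 7),
                     sampleVoxelClasses(50, 50, c(0, 1), c(5, 1), seed = 7))
    expect_error(sampleVoxelClasses(0, 3, c(0, 1), c(5, 1), seed = 1),
                 class = "bmq_config_error")
})

test_that("TEM phantom rods land on the configured linear HU map", {
    tem <- generateTemPhantom(densities = c(1.08, 1.57), slope = 1000,
                              intercept = -800, noiseSD = 0,
                              voxelsPerRod = 50, seed = 3)
    rods <- measureRods(tem$ct, tem$rodMasks, tem$truth$density)
    expect_equal(rods$mean_hu, c(280, 770))
    expect_equal(tem$truth$noiseless_hu, c(280, 770))

    noisy <- generateTemPhantom(densities = c(1.08, 1.57), noiseSD = 10,
                                voxelsPerRod = 500, seed = 4)
    rodsN <- measureRods(noisy$ct, noisy$rodMasks, noisy$truth$density)
    expect_lt(max(abs(rodsN$mean_hu - noisy$truth$noiseless_hu)), 1.5)

    one <- generateTemPhantom(densities = 1.2, noiseSD = 0,
                              voxelsPerRod = 10, seed = 5)
    rods1 <- measureRods(one$ct, one$rodMasks, one$truth$density)
    expect_error(fitCalibration(rods1), class = "bmq_config_error")
    expect_error(generateTemPhantom(densities = c(1.5, 1.2)),
                 class = "bmq_config_error")
})

test_that("cohort generation matches its spec and reproduces under seed", {
    one <- generateCohort(nSubjects = 1, ageSD = 0, heightSD = 0,
                          massMean = 60, massSD = 0, seed = 1)
    expect_equal(one$mass_kg, 60)
    expect_equal(nrow(one), 1L)

    big <- generateCohort(nSubjects = 10000, massMean = 59.7, massSD = 8,
                          seed = 2)
    expect_lt(abs(mean(big$mass_kg) - 59.7), 0.25)
    expect_true(all(big$mass_kg > 0) && all(big$height_m > 0))

    expect_identical(generateCohort(seed = 9), generateCohort(seed = 9))
    expect_error(generateCohort(nSubjects = 0), class = "bmq_config_error")
})

test_that("adipocyte annotations encode the multilocular rule by construction", {
    ann <- generateAdipocyteAnnotations(2, 1, marrowArea = 2, seed = 1)
    droplets <- ann@adipocytes$small_droplet_count
    expect_identical(sum(droplets >= 3L), 1L)
    expect_identical(sum(droplets <= 2L), 2L)
    expect_lte(sum(ann@adipocytes$area_mm2), 2)

    empty <- generateAdipocyteAnnotations(0, 0, marrowArea = 3.5, seed = 1)
    expect_identical(nrow(empty@adipocytes), 0L)
    expect_equal(empty@marrowArea, 3.5)

    ten <- generateAdipocyteAnnotations(6, 4, marrowArea = 2, seed = 2)
    expect_equal(morphometry(ten)$n_ad_per_marrow_area, 5)
})

test_that("invalid generator configurations are rejected", {
    expect_error(phantomConfig(bmRegions = data.frame(name = "x",
                                                      n_voxels = 10L,
                                                      bmat_fraction = 1.2)),
                 class = "bmq_config_error")
    comp <- defaultCompartments()
    comp$hu_sd[1] <- -1
    expect_error(phantomConfig(compartments = comp),
                 class = "bmq_config_error")
    expect_error(generateAdipocyteAnnotations(-1, 0, 1),
                 class = "bmq_config_error")
})
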