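test_that("mass-mode marrow volumes reproduce both reported cohort means", {
    v <- bmVolumes(59.67)
    expect_equal(round(v[["BMAT"]], 2), 2.27)
    expect_equal(round(v[["RM"]], 2), 0.84)

    # unit construction: M such that BM mass * share = 0.92 kg -> 1 L fat
    m1 <- 0.92 / 0.05 / 0.7
    expect_equal(bmVolumes(m1)[["BMAT"]], 1)
})

test_that("volume mode pins the BMAT/RM volume ratio at 7/3", {
    pv <- compositionParams(splitMode = "volume")
    v <- bmVolumes(59.67, pv)
    expect_equal(v[["BMAT"]] / v[["RM"]], 7 / 3)
    expect_equal(v[["BMAT"]],
                 0.7 * 0.05 * 59.67 / (0.7 * 0.92 + 0.3 * 1.06))
    # mass mode cannot be swapped silently: its ratio is 7/3 * 1.06/0.92
    vm <- bmVolumes(59.67)
    expect_equal(vm[["BMAT"]] / vm[["RM"]], 7 / 3 * 1.06 / 0.92)
    expect_gt(abs(vm[["BMAT"]] / vm[["RM"]] - v[["BMAT"]] / v[["RM"]]), 0.3)
})

test_that("volumes are homogeneous degree 1 in body mass", {
    v1 <- bmVolumes(50)
    v2 <- bmVolumes(100)
    expect_equal(v2[["BMAT"]], 2 * v1[["BMAT"]])
    expect_equal(v2[["RM"]], 2 * v1[["RM"]])
    expect_error(bmVolumes(0), class = "bmq_config_error")
})

test_that("bone volume divides the modelled bone mass by bone density", {
    expect_equal(round(boneVolume(1.7, function(h) 9.35), 2), 7.51)
    expect_equal(boneVolume(1.7, function(h) 1.245), 1)
    expect_error(boneVolume(1.7), class = "bmq_config_error")
    expect_error(boneVolume(1.7, function(h) 0), class = "bmq_config_error")
    # the shipped placeholder is labelled as such
    expect_true(attr(placeholderBoneMassModel(), "placeholder"))
})

test_that("muscle volume uses the sex/age percentage table", {
    tab <- data.frame(sex = "female", age_min = 18, age_max = 120,
                      muscle_pct = 31.7)
    subj <- list(sex = "female", age = 52, mass_kg = 59.67)
    expect_equal(round(muscleVolume(subj, tab), 2), 17.93)

    tab100 <- data.frame(sex = "female", age_min = 18, age_max = 120,
                         muscle_pct = 99.9999)
    expect_equal(muscleVolume(list(sex = "female", age = 52,
                                   mass_kg = 1.055), tab100), 1,
                 tolerance = 1e-4)
    expect_error(muscleVolume(list(sex = "male", age = 52, mass_kg = 60),
                              tab), regexp = "male",
                 class = "bmq_lookup_error")
    expect_error(muscleVolume(subj), class = "bmq_config_error")
})

test_that("capacity indices are volume x SUV relative to muscle", {
    cap <- capacity(c(BMAT = 2.27, muscle = 17.93),
                    c(BMAT = 2.0, muscle = 0.85))
    bmatRow <- cap[cap$tissue == "BMAT", ]
    expect_equal(bmatRow$percent_of_muscle,
                 (2.27 * 2.0) / (17.93 * 0.85) * 100)
    expect_equal(cap$percent_of_muscle[cap$tissue == "muscle"], 100)

    # equal SUVs: percent_of_muscle reduces to the volume ratio
    capEq <- capacity(c(BMAT = 3, muscle = 12), c(BMAT = 1.4, muscle = 1.4))
    expect_equal(capEq$percent_of_muscle[capEq$tissue == "BMAT"], 25)

    # common rescaling of all SUVs leaves percent_of_muscle unchanged
    cap2 <- capacity(c(BMAT = 2.27, muscle = 17.93),
                     c(BMAT = 2.0, muscle = 0.85) * 3.7)
    expect_equal(cap2$percent_of_muscle, cap$percent_of_muscle)
    expect_error(capacity(c(BMAT = 2), c(BMAT = 1)),
                 class = "bmq_config_error")
})

test_that("cohort volume statistics follow the analytic mass transform", {
    coh <- generateCohort(nSubjects = 5000, massMean = 59.7, massSD = 8,
                          seed = 4)
    v <- vapply(coh$mass_kg, function(m) bmVolumes(m)[["BMAT"]], numeric(1))
    k <- 0.05 * 0.7 / 0.92  # litres per kg body mass
    expect_equal(mean(v), k * mean(coh$mass_kg), tolerance = 1e-12)
    expect_lt(abs(mean(v) - k * 59.7), 4 * k * 8 / sqrt(5000))
    expect_lt(abs(sd(v) - k * 8), 0.03)
})

test_that("body-mass inversion is consistent with the forward model", {
    m <- solveBodyMassForBmat(2.27)
    expect_equal(bmVolumes(m)[["BMAT"]], 2.27, tolerance = 1e-8)
    expect_equal(m, 2.27 * 0.92 / (0.05 * 0.7), tolerance = 1e-6)
})
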