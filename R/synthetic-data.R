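## Synthetic phantom generation.
##
## Every input the pipeline consumes can be generated here with known ground
## truth: paired CT/PET phantoms with per-compartment Gaussian HU and uptake,
## labelled voxel-class samples for ROC work, tissue-equivalent rod phantoms
## for density calibration, anthropometric cohorts, and 2-D adipocyte
## annotations for histomorphometry. One integer seed determines everything;
## each compartment draws from its own derived substream so output does not
## depend on generation order.

#' Default compartment HU and uptake parameters
#'
#' Per-compartment Gaussian HU parameters chosen so that the midpoint of the
#' BMAT and red-marrow means falls at 115 HU and the red-marrow/trabecular
#' midpoint (at the wider bone SD) falls at 300 HU — i.e. default phantoms
#' reproduce the diagnostic cutpoints. Uptake values are nominal activity
#' concentrations (kBq/mL) with BMAT set higher than subcutaneous WAT, as
#' observed for basal marrow fat glucose uptake.
#'
#' @return data.frame with columns \code{name, hu_mean, hu_sd, uptake,
#'   uptake_sd}.
#' @export
defaultCompartments <- function() {
    data.frame(
        name      = c("scWAT", "BMAT", "RM", "trabecular_bone",
                      "cortical_bone", "muscle"),
        hu_mean   = c(-100, 42, 188, 412, 1000, 55),
        hu_sd     = c(20, 30, 30, 55, 100, 10),
        uptake    = c(1.2, 4.0, 2.5, 1.5, 0.8, 2.6),
        uptake_sd = c(0.1, 0.3, 0.2, 0.15, 0.1, 0.2),
        stringsAsFactors = FALSE)
}

#' Phantom configuration
#'
#' @param gridShape voxels per axis, 3 integers.
#' @param voxelSpacing mm per axis (length 1 or 3).
#' @param compartments data.frame like [defaultCompartments()].
#' @param bmRegions data.frame with columns \code{name}, \code{n_voxels},
#'   \code{bmat_fraction} (proportion of the region's voxels drawn from the
#'   BMAT HU distribution; the rest are red marrow).
#' @param seed master integer seed.
#' @return A validated list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(gridShape = c(64, 64, 48), voxelSpacing = c(1, 1, 1),
                          compartments = defaultCompartments(),
                          bmRegions = data.frame(
                              name = c("sternum_BM", "vertebrae_BM"),
                              n_voxels = c(20000L, 20000L),
                              bmat_fraction = c(0.7, 0.05)),
                          seed = 1L) {
    if (length(voxelSpacing) == 1L) voxelSpacing <- rep(voxelSpacing, 3L)
    if (any(voxelSpacing <= 0)) configError("voxelSpacing must be positive")
    if (any(compartments$hu_sd < 0) || any(compartments$uptake_sd < 0))
        configError("compartment standard deviations must be non-negative")
    if (any(bmRegions$bmat_fraction < 0 | bmRegions$bmat_fraction > 1))
        configError("bmat_fraction must lie in [0, 1]")
    if (any(bmRegions$n_voxels < 1))
        configError("each BM region needs at least one voxel")
    if (!all(c("BMAT", "RM") %in% compartments$name))
        configError("compartments must include BMAT and RM")
    needed <- sum(bmRegions$n_voxels) +
        sum(!compartments$name %in% c("BMAT", "RM"))
    if (needed > prod(gridShape))
        configError(sprintf("grid too small: at least %d voxels needed, %d available",
                            needed, prod(gridShape)))
    structure(list(gridShape = as.integer(gridShape),
                   voxelSpacing = as.numeric(voxelSpacing),
                   compartments = compartments, bmRegions = bmRegions,
                   seed = as.integer(seed)),
              class = "PhantomConfig")
}

compartmentRow <- function(compartments, name) {
    i <- match(name, compartments$name)
    if (is.na(i)) configError(sprintf("compartment '%s' not configured", name))
    compartments[i, ]
}

#' Generate a paired CT/PET human phantom with ground truth
#'
#' Lays out each configured bone-marrow region and one block of 1000 voxels
#' per non-marrow compartment on the voxel grid. Within each BM region,
#' exactly \code{floor(bmat_fraction * n)} voxels take BMAT-distributed HU
#' and uptake and the remainder red-marrow values, so the recorded truth
#' fraction is exact. All remaining grid voxels are background (-1000 HU CT,
#' zero PET, label 0).
#'
#' @param config a [phantomConfig()].
#' @return list with elements \code{ct}, \code{pet} (both
#'   \linkS4class{VoxelVolume}), \code{masks} (\linkS4class{VOIMask} covering
#'   each BM region and compartment block), and \code{truth} (list with
#'   \code{label_grid}, \code{true_bmat_fraction}, \code{true_uptake},
#'   \code{region_class}: per-voxel "BMAT"/"RM" class for each BM region).
#' @examples
#' ph <- generateHumanPhantom(phantomConfig(seed = 7))
#' ph$truth$true_bmat_fraction
#' @export
generateHumanPhantom <- function(config) {
    if (!inherits(config, "PhantomConfig"))
        config <- do.call(phantomConfig, config)
    gs <- config$gridShape
    nTot <- prod(gs)
    comp <- config$compartments
    bmr <- config$bmRegions

    ct <- rep(-1000, nTot)
    pet <- rep(0, nTot)
    labels <- integer(nTot)
    labelGrid <- integer(nTot)

    regionNames <- character()
    trueFrac <- numeric()
    regionClass <- list()
    cursor <- 1L
    labelId <- 0L
    bmatRow <- compartmentRow(comp, "BMAT")
    rmRow <- compartmentRow(comp, "RM")

    takeVoxels <- function(n) {
        if (cursor + n - 1L > nTot)
            configError("grid too small for configured regions")
        idx <- cursor:(cursor + n - 1L)
        cursor <<- cursor + n
        idx
    }

    for (i in seq_len(nrow(bmr))) {
        labelId <- labelId + 1L
        n <- as.integer(bmr$n_voxels[i])
        nBmat <- as.integer(floor(bmr$bmat_fraction[i] * n))
        idx <- takeVoxels(n)
        cls <- rep("RM", n)
        if (nBmat > 0) cls[seq_len(nBmat)] <- "BMAT"
        s <- subSeed(config$seed, 100L + i)
        draws <- withSeed(s, {
            list(ctB = rnorm(nBmat, bmatRow$hu_mean, bmatRow$hu_sd),
                 ctR = rnorm(n - nBmat, rmRow$hu_mean, rmRow$hu_sd),
                 petB = rnorm(nBmat, bmatRow$uptake, bmatRow$uptake_sd),
                 petR = rnorm(n - nBmat, rmRow$uptake, rmRow$uptake_sd))
        })
        ct[idx] <- c(draws$ctB, draws$ctR)
        pet[idx] <- pmax(c(draws$petB, draws$petR), 0)
        labels[idx] <- labelId
        labelGrid[idx] <- labelId
        regionNames[as.character(labelId)] <- bmr$name[i]
        trueFrac[bmr$name[i]] <- nBmat / n
        regionClass[[bmr$name[i]]] <- cls
    }

    otherComp <- comp[!comp$name %in% c("BMAT", "RM"), , drop = FALSE]
    trueUptake <- c(BMAT = bmatRow$uptake, RM = rmRow$uptake)
    # reference blocks of up to 1000 voxels per non-marrow compartment,
    # shrunk to fit whatever grid space the BM regions leave over
    nOther <- nrow(otherComp)
    blockSize <- if (nOther) max(1L, min(1000L, (nTot - cursor + 1L) %/% nOther))
                 else 0L
    for (j in seq_len(nOther)) {
        labelId <- labelId + 1L
        row <- otherComp[j, ]
        n <- blockSize
        idx <- takeVoxels(n)
        s <- subSeed(config$seed, 200L + j)
        draws <- withSeed(s, list(ct = rnorm(n, row$hu_mean, row$hu_sd),
                                  pet = rnorm(n, row$uptake, row$uptake_sd)))
        ct[idx] <- draws$ct
        pet[idx] <- pmax(draws$pet, 0)
        labels[idx] <- labelId
        labelGrid[idx] <- labelId
        regionNames[as.character(labelId)] <- row$name
        trueUptake[row$name] <- row$uptake
    }

    ctVol <- voxelVolume(array(roundHalfAwayFromZero(ct), dim = gs),
                         spacing = config$voxelSpacing, modality = "CT")
    petVol <- voxelVolume(array(pet, dim = gs),
                          spacing = config$voxelSpacing, modality = "PET")
    mask <- voiMask(array(labels, dim = gs), regionNames = regionNames,
                    spacing = config$voxelSpacing)
    list(ct = ctVol, pet = petVol, masks = mask,
         truth = list(label_grid = array(labelGrid, dim = gs),
                      true_bmat_fraction = trueFrac,
                      true_uptake = trueUptake,
                      region_class = regionClass))
}

#' Sample labelled voxel HU classes
#'
#' Draws a positive (e.g. BMAT-rich marrow) and a negative (e.g. red marrow)
#' Gaussian HU sample for ROC analysis. Values are rounded to integer HU,
#' matching CT storage.
#'
#' @param nPos,nNeg class sizes (>= 1).
#' @param posDist,negDist numeric(2): mean and SD.
#' @param seed integer seed.
#' @param integerHU round draws to integer HU (default TRUE).
#' @return list with numeric vectors \code{positive} and \code{negative}.
#' @export
sampleVoxelClasses <- function(nPos, nNeg, posDist, negDist, seed,
                               integerHU = TRUE) {
    if (nPos < 1 || nNeg < 1) configError("class sizes must be >= 1")
    if (posDist[2] < 0 || negDist[2] < 0)
        configError("standard deviations must be non-negative")
    pos <- withSeed(subSeed(seed, 1L), rnorm(nPos, posDist[1], posDist[2]))
    neg <- withSeed(subSeed(seed, 2L), rnorm(nNeg, negDist[1], negDist[2]))
    if (integerHU) {
        pos <- roundHalfAwayFromZero(pos)
        neg <- roundHalfAwayFromZero(neg)
    }
    list(positive = pos, negative = neg)
}

#' Generate a tissue-equivalent-material (TEM) rod phantom
#'
#' Emulates a CT density-calibration phantom: rods of known mass density on a
#' linear HU map, with Gaussian voxel noise. Rod voxels are laid out in
#' disjoint blocks; everything else is background.
#'
#' @param densities strictly increasing rod densities, g/mL.
#' @param slope,intercept the generating linear HU map (HU per g/mL, HU).
#' @param noiseSD Gaussian voxel noise, HU.
#' @param voxelsPerRod voxels per rod (>= 1).
#' @param seed integer seed.
#' @param integerHU round CT values to integer HU (default TRUE).
#' @return list with \code{ct} (\linkS4class{VoxelVolume}, modality UCT),
#'   \code{rodMasks} (\linkS4class{VOIMask}, regions \code{rod_1} ...),
#'   \code{truth} (data.frame rod, density, noiseless_hu).
#' @export
generateTemPhantom <- function(densities = seq(1.08, 1.57, length.out = 5),
                               slope = 1000, intercept = -800, noiseSD = 10,
                               voxelsPerRod = 500L, seed = 1L,
                               integerHU = TRUE) {
    if (length(densities) < 1L || is.unsorted(densities, strictly = TRUE))
        configError("rod densities must be strictly increasing")
    if (voxelsPerRod < 1L) configError("voxelsPerRod must be >= 1")
    if (noiseSD < 0) configError("noiseSD must be non-negative")
    nRods <- length(densities)
    side <- ceiling((nRods * voxelsPerRod * 2)^(1 / 3))
    gs <- c(side, side, side)
    nTot <- prod(gs)
    ct <- rep(-1000, nTot)
    labels <- integer(nTot)
    regionNames <- character()
    for (i in seq_len(nRods)) {
        idx <- ((i - 1L) * voxelsPerRod + 1L):(i * voxelsPerRod)
        mu <- slope * densities[i] + intercept
        ct[idx] <- withSeed(subSeed(seed, 300L + i),
                            rnorm(voxelsPerRod, mu, noiseSD))
        labels[idx] <- i
        regionNames[as.character(i)] <- paste0("rod_", i)
    }
    if (integerHU) ct <- roundHalfAwayFromZero(ct)
    list(ct = voxelVolume(array(ct, dim = gs), modality = "UCT"),
         rodMasks = voiMask(array(labels, dim = gs), regionNames = regionNames),
         truth = data.frame(rod = paste0("rod_", seq_len(nRods)),
                            density = densities,
                            noiseless_hu = slope * densities + intercept))
}

#' Generate a synthetic subject cohort
#'
#' Samples anthropometrics from Gaussian marginals. Non-positive height or
#' mass draws are resampled. Defaults emulate a retrospectively identified
#' room-temperature clinical cohort (n = 10, age 51.5 +/- 19.6 y, 20\% male);
#' height and mass defaults (1.68 +/- 0.09 m, 59.7 +/- 8 kg) are chosen to
#' give BMI near the reported 20.7 +/- 2.4 kg/m^2.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param ageMean,ageSD years.
#' @param sexRatio proportion male in [0, 1].
#' @param heightMean,heightSD m.
#' @param massMean,massSD kg.
#' @param seed integer seed.
#' @return data.frame (id, age, sex, height_m, mass_kg).
#' @export
generateCohort <- function(nSubjects = 10L, ageMean = 51.5, ageSD = 19.6,
                           sexRatio = 0.2, heightMean = 1.68, heightSD = 0.09,
                           massMean = 59.7, massSD = 8, seed = 1L) {
    if (nSubjects < 1) configError("nSubjects must be >= 1")
    if (any(c(ageSD, heightSD, massSD) < 0))
        configError("standard deviations must be non-negative")
    if (sexRatio < 0 || sexRatio > 1)
        configError("sexRatio must lie in [0, 1]")
    positiveNormal <- function(k, n, mean, sd) {
        withSeed(subSeed(seed, k), {
            x <- rnorm(n, mean, sd)
            while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
            x
        })
    }
    age <- withSeed(subSeed(seed, 401L), pmax(rnorm(nSubjects, ageMean, ageSD), 18))
    sex <- withSeed(subSeed(seed, 402L),
                    ifelse(runif(nSubjects) < sexRatio, "male", "female"))
    height <- positiveNormal(403L, nSubjects, heightMean, heightSD)
    mass <- positiveNormal(404L, nSubjects, massMean, massSD)
    data.frame(id = sprintf("S%03d", seq_len(nSubjects)), age = age, sex = sex,
               height_m = height, mass_kg = mass, stringsAsFactors = FALSE)
}

#' Generate synthetic adipocyte annotations
#'
#' Constructs a 2-D annotation set with the requested numbers of unilocular
#' (at most 2 small satellite droplets) and multilocular (3 or more) cells.
#' Cell areas are drawn log-normally around a typical marrow-adipocyte size
#' and rescaled if their sum would exceed half the marrow area.
#'
#' @param nUnilocular,nMultilocular cell counts (>= 0).
#' @param marrowArea total marrow section area, mm^2 (> 0).
#' @param meanCellArea typical adipocyte area, mm^2 (default 0.002,
#'   i.e. ~50 um diameter).
#' @param seed integer seed.
#' @return An \linkS4class{AdipocyteAnnotationSet}.
#' @export
generateAdipocyteAnnotations <- function(nUnilocular, nMultilocular,
                                         marrowArea, meanCellArea = 0.002,
                                         seed = 1L) {
    if (nUnilocular < 0 || nMultilocular < 0)
        configError("cell counts must be non-negative")
    if (marrowArea <= 0) configError("marrowArea must be positive")
    n <- nUnilocular + nMultilocular
    if (n == 0L)
        return(adipocyteAnnotationSet(marrowArea))
    areas <- withSeed(subSeed(seed, 501L),
                      exp(rnorm(n, log(meanCellArea), 0.3)))
    if (sum(areas) > marrowArea / 2)
        areas <- areas * (marrowArea / 2) / sum(areas)
    if (sum(areas) > marrowArea)
        configError("adipocyte area exceeds marrow area")
    droplets <- c(withSeed(subSeed(seed, 502L),
                           sample(0:2, nUnilocular, replace = TRUE)),
                  withSeed(subSeed(seed, 503L),
                           sample(3:8, nMultilocular, replace = TRUE)))
    adipocyteAnnotationSet(marrowArea,
        data.frame(area_mm2 = areas,
                   small_droplet_count = as.integer(droplets)))
}
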