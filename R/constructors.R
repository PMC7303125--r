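#' Construct a VoxelVolume
#'
#' @param values 3-D numeric array of voxel values, indexed (x, y, z).
#' @param spacing voxel spacing in mm per axis (length 1 or 3).
#' @param origin world-space origin in mm (length 3).
#' @param modality \code{"CT"}, \code{"PET"} or \code{"UCT"}.
#' @param units unit string; defaults to \code{"HU"} for CT/UCT and
#'   \code{"kBq/mL"} for PET.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- voxelVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2.5), modality = "CT")
#' spacing(v)
#' @export
voxelVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        modality = c("CT", "PET", "UCT"), units = NULL) {
    modality <- match.arg(modality)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    if (is.null(units))
        units <- if (modality == "PET") "kBq/mL" else "HU"
    new("VoxelVolume", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin), modality = modality, units = units)
}

#' Construct a VOIMask
#'
#' @param labels 3-D integer array; 0 = background.
#' @param regionNames named character vector mapping label id (as the name)
#'   to region name, e.g. \code{c("1" = "sternum_BM")}.
#' @param spacing,origin grid geometry in mm, matching the companion volume.
#' @return A \linkS4class{VOIMask}.
#' @export
voiMask <- function(labels, regionNames, spacing = c(1, 1, 1),
                    origin = c(0, 0, 0)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(labels) <- "integer"
    new("VOIMask", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin),
        regionNames = structure(as.character(regionNames),
                                names = names(regionNames)))
}

#' Construct a ThresholdScheme
#'
#' Defaults are the diagnostic cutpoints for human marrow: BMAT in
#' [-200, 115) HU, red marrow in [115, 300] HU, bone above 300 HU.
#'
#' @param yellowLow lower HU bound of the BMAT window (default -200).
#' @param bmatRM BMAT / red-marrow cutpoint (default 115).
#' @param rmBone red-marrow / bone cutpoint (default 300).
#' @return A \linkS4class{ThresholdScheme}.
#' @examples
#' thresholdScheme()
#' @export
thresholdScheme <- function(yellowLow = -200, bmatRM = 115, rmBone = 300) {
    new("ThresholdScheme", yellowLow = as.numeric(yellowLow),
        bmatRM = as.numeric(bmatRM), rmBone = as.numeric(rmBone))
}

#' Construct an AdipocyteAnnotationSet
#'
#' @param marrowArea total marrow section area, mm^2.
#' @param adipocytes data.frame with columns \code{area_mm2} and
#'   \code{small_droplet_count}.
#' @return An \linkS4class{AdipocyteAnnotationSet}.
#' @export
adipocyteAnnotationSet <- function(marrowArea,
                                   adipocytes = data.frame(
                                       area_mm2 = numeric(),
                                       small_droplet_count = integer())) {
    new("AdipocyteAnnotationSet", marrowArea = as.numeric(marrowArea),
        adipocytes = adipocytes)
}

#' Construct CompositionParams
#'
#' @param bmMassFraction marrow proportion of body mass (default 0.05).
#' @param bmatShare,rmShare BMAT / red-marrow partition (defaults 0.70, 0.30).
#' @param densityFat,densityHaem,densityBone,densityMuscle tissue mass
#'   densities in g/mL (defaults 0.92, 1.06, 1.245, 1.055).
#' @param splitMode apply the 70/30 partition to marrow \code{"mass"}
#'   (default) or marrow \code{"volume"}.
#' @return A \linkS4class{CompositionParams}.
#' @examples
#' compositionParams()
#' @export
compositionParams <- function(bmMassFraction = 0.05, bmatShare = 0.70,
                              rmShare = 0.30, densityFat = 0.92,
                              densityHaem = 1.06, densityBone = 1.245,
                              densityMuscle = 1.055,
                              splitMode = c("mass", "volume")) {
    splitMode <- match.arg(splitMode)
    new("CompositionParams", bmMassFraction = bmMassFraction,
        bmatShare = bmatShare, rmShare = rmShare, densityFat = densityFat,
        densityHaem = densityHaem, densityBone = densityBone,
        densityMuscle = densityMuscle, splitMode = splitMode)
}

#' SUV normalization parameters
#'
#' Bundles the injected dose, body mass and timing needed to convert PET
#' activity concentration to body-weight-normalized SUV. The default
#' half-life is the physical half-life of fluorine-18 (109.77 min).
#'
#' @param injectedDose injected activity, MBq.
#' @param bodyMass subject body mass, g.
#' @param injectionTime,measurementTime minutes; measurement must not precede
#'   injection.
#' @param halfLife radionuclide half-life in minutes.
#' @return A validated list of class \code{"SUVParams"}.
#' @export
suvParams <- function(injectedDose, bodyMass, injectionTime = 0,
                      measurementTime = injectionTime, halfLife = 109.77) {
    if (injectedDose <= 0) configError("injectedDose must be positive (MBq)")
    if (bodyMass <= 0) configError("bodyMass must be positive (g)")
    if (halfLife <= 0) configError("halfLife must be positive (minutes)")
    if (measurementTime < injectionTime)
        configError("measurementTime must not precede injectionTime")
    structure(list(injectedDose = injectedDose, bodyMass = bodyMass,
                   injectionTime = injectionTime,
                   measurementTime = measurementTime, halfLife = halfLife),
              class = "SUVParams")
}

#' Gamma-counter sample
#'
#' One ex vivo tissue measurement from a calibrated gamma counter.
#'
#' @param countsPerMinute raw counts per minute.
#' @param counterConversion calibration factor, MBq per cpm.
#' @param tissueMass tissue mass in g.
#' @param elapsedSinceInjection minutes from tracer injection to counting.
#' @return A validated list of class \code{"GammaSample"}.
#' @export
gammaSample <- function(countsPerMinute, counterConversion, tissueMass,
                        elapsedSinceInjection) {
    vals <- c(countsPerMinute, counterConversion, tissueMass,
              elapsedSinceInjection)
    if (any(vals <= 0))
        configError("all gamma-sample fields must be positive")
    structure(list(countsPerMinute = countsPerMinute,
                   counterConversion = counterConversion,
                   tissueMass = tissueMass,
                   elapsedSinceInjection = elapsedSinceInjection),
              class = "GammaSample")
}
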