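## Compartment segmentation, adipose volumetrics, SUV and gamma-count
## quantification, and adipocyte histomorphometry.

#' Classify an HU value into a marrow compartment
#'
#' Applies the diagnostic scheme: BMAT (yellow marrow) in
#' \code{[yellowLow, bmatRM)}, red marrow in \code{[bmatRM, rmBone]}, bone
#' above \code{rmBone}; values below \code{yellowLow} are OUT_OF_RANGE
#' (air/artefact). With the default scheme: 114 HU is BMAT, 115 RM, 300 RM,
#' 301 BONE, -201 OUT_OF_RANGE.
#'
#' @param hu numeric HU value(s); rounded to integer HU.
#' @param scheme a \linkS4class{ThresholdScheme}.
#' @return character vector of class labels.
#' @export
classifyHU <- function(hu, scheme = thresholdScheme()) {
    stopifnot(is(scheme, "ThresholdScheme"))
    h <- roundHalfAwayFromZero(hu)
    out <- rep("OUT_OF_RANGE", length(h))
    out[h >= scheme@yellowLow & h < scheme@bmatRM] <- "BMAT"
    out[h >= scheme@bmatRM & h <= scheme@rmBone] <- "RM"
    out[h > scheme@rmBone] <- "BONE"
    out
}

#' Segment a bone-marrow VOI into compartments
#'
#' Every voxel of the named BM region is classified by [classifyHU()];
#' counts are conserved (they always sum to the VOI voxel count).
#'
#' @param ct a CT \linkS4class{VoxelVolume}.
#' @param bmMask a \linkS4class{VOIMask} on the same grid.
#' @param region BM region name within the mask.
#' @param scheme a \linkS4class{ThresholdScheme}.
#' @return A \linkS4class{CompartmentSegmentation}.
#' @export
segmentBM <- function(ct, bmMask, region, scheme = thresholdScheme()) {
    hu <- extractVoiHU(ct, bmMask, region)
    classes <- classifyHU(hu, scheme)
    counts <- vapply(c("BMAT", "RM", "BONE", "OUT_OF_RANGE"),
                     function(cl) sum(classes == cl), numeric(1))
    new("CompartmentSegmentation", classes = classes, counts = counts,
        voxelVolumeML = prod(spacing(ct)) / 1000)
}

#' Adipose volumetrics from a compartment segmentation
#'
#' Ad.V/Ma.V is the BMAT voxel count as a percentage of the marrow-cavity
#' voxel count. By default all classified voxels — including bone intrusions
#' and out-of-range voxels — remain in the denominator (total BM volume);
#' set \code{denominator = "soft_tissue"} to restrict it to BMAT + RM.
#'
#' @param seg a \linkS4class{CompartmentSegmentation}.
#' @param denominator \code{"total"} (default) or \code{"soft_tissue"}.
#' @return list with \code{ad_v_over_ma_v} (percent) and \code{volumes_mL}
#'   (named: per class plus \code{total}).
#' @export
adiposityFraction <- function(seg, denominator = c("total", "soft_tissue")) {
    denominator <- match.arg(denominator)
    counts <- classCounts(seg)
    total <- sum(counts)
    if (total == 0) configError("segmentation covers zero voxels")
    denom <- if (denominator == "total") total
             else counts[["BMAT"]] + counts[["RM"]]
    if (denom == 0) configError("empty Ad.V/Ma.V denominator")
    volumes <- counts * voxelVolumeML(seg)
    list(ad_v_over_ma_v = 100 * counts[["BMAT"]] / denom,
         volumes_mL = c(volumes, total = total * voxelVolumeML(seg)))
}

#' Correct a measured activity for radioactive decay
#'
#' Back-corrects an activity measured \code{elapsed} minutes after tracer
#' injection to the injection time: A0 = A * 2^(elapsed / halfLife).
#'
#' @param activity measured activity, MBq.
#' @param elapsed minutes since injection (>= 0; correction is
#'   one-directional).
#' @param halfLife radionuclide half-life, minutes (default 109.77 for
#'   fluorine-18).
#' @return Activity at injection time, MBq.
#' @examples
#' decayCorrect(0.5, 109.77)  # one half-life -> 1.0
#' @export
decayCorrect <- function(activity, elapsed, halfLife = 109.77) {
    if (halfLife <= 0) configError("halfLife must be positive")
    if (any(elapsed < 0))
        configError("elapsed must be non-negative: decay correction is one-directional")
    activity * 2^(elapsed / halfLife)
}

#' Percent injected dose per gram from a gamma-counter sample
#'
#' Counts per minute are converted to MBq with the counter calibration
#' factor, decay-corrected back to injection time, and normalized by the
#' injected dose and tissue mass:
#' \%ID/g = 100 * A0 / dose / mass.
#'
#' @param sample a [gammaSample()].
#' @param dose injected dose, MBq (> 0).
#' @param halfLife radionuclide half-life, minutes.
#' @return \%ID/g (percent per gram).
#' @export
percentIdPerG <- function(sample, dose, halfLife = 109.77) {
    stopifnot(inherits(sample, "GammaSample"))
    if (dose <= 0) configError("injected dose must be positive")
    activity <- sample$countsPerMinute * sample$counterConversion
    a0 <- decayCorrect(activity, sample$elapsedSinceInjection, halfLife)
    100 * a0 / dose / sample$tissueMass
}

#' Mean SUV per marrow compartment
#'
#' Converts PET activity concentration (kBq/mL, assumed already
#' decay-corrected by the scanner to injection time) to body-weight SUV,
#' SUV = C / (dose / bodyMass), and averages over each compartment's voxels.
#' Classes with no voxels are absent from the result, not reported as zero.
#'
#' @param pet a PET \linkS4class{VoxelVolume} in kBq/mL.
#' @param bmMask a \linkS4class{VOIMask} on the same grid.
#' @param region BM region name.
#' @param seg the \linkS4class{CompartmentSegmentation} of that region.
#' @param params an [suvParams()] (dose in MBq, body mass in g).
#' @return named numeric: mean SUV per non-empty class.
#' @export
compartmentSUV <- function(pet, bmMask, region, seg, params) {
    stopifnot(inherits(params, "SUVParams"))
    validateAlignment(pet, bmMask)
    ids <- names(regionNames(bmMask))[regionNames(bmMask) == region]
    if (!length(ids))
        lookupError(sprintf("region '%s' not present in mask", region))
    conc <- voxelData(pet)[voxelData(bmMask) == as.integer(ids[[1]])]
    if (length(conc) != length(voxelClasses(seg)))
        configError("segmentation does not match the region's voxel count")
    # dose MBq -> kBq so that kBq/mL / (kBq/g) is dimensionless (1 mL ~ 1 g)
    normalizer <- params$injectedDose * 1000 / params$bodyMass
    suv <- conc / normalizer
    present <- unique(voxelClasses(seg))
    vapply(present, function(cl) mean(suv[voxelClasses(seg) == cl]),
           numeric(1))
}

#' Mean SUV of a whole named region
#'
#' Body-weight SUV averaged over every voxel of one VOI (e.g. muscle or
#' subcutaneous WAT), without compartment segmentation.
#'
#' @inheritParams compartmentSUV
#' @return mean SUV (single value).
#' @export
regionSUV <- function(pet, bmMask, region, params) {
    stopifnot(inherits(params, "SUVParams"))
    validateAlignment(pet, bmMask)
    ids <- names(regionNames(bmMask))[regionNames(bmMask) == region]
    if (!length(ids))
        lookupError(sprintf("region '%s' not present in mask", region))
    conc <- voxelData(pet)[voxelData(bmMask) == as.integer(ids[[1]])]
    if (!length(conc)) lookupError(sprintf("region '%s' has no voxels", region))
    mean(conc) / (params$injectedDose * 1000 / params$bodyMass)
}

#' Adipocyte histomorphometry metrics
#'
#' Computes adipocyte density (N.Ad/Ma.Ar, cells per mm^2), adipocyte area
#' fraction (Ad.Ar/Ma.Ar, percent) and the multilocular count/fraction. A
#' cell is multilocular iff it has 3 or more small lipid droplets associated
#' with its main droplet.
#'
#' @param annotations an \linkS4class{AdipocyteAnnotationSet}.
#' @return list: \code{n_ad_per_marrow_area} (mm^-2), \code{ad_area_fraction}
#'   (percent), \code{multilocular_count}, \code{multilocular_fraction}.
#' @export
morphometry <- function(annotations) {
    stopifnot(is(annotations, "AdipocyteAnnotationSet"))
    ma <- annotations@marrowArea
    if (ma <= 0) configError("marrow area must be positive")
    ad <- annotations@adipocytes
    n <- nrow(ad)
    nMulti <- if (n) sum(ad$small_droplet_count >= 3L) else 0L
    list(n_ad_per_marrow_area = n / ma,
         ad_area_fraction = 100 * (if (n) sum(ad$area_mm2) else 0) / ma,
         multilocular_count = nMulti,
         multilocular_fraction = if (n) nMulti / n else NA_real_)
}
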