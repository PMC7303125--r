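## Linear HU <-> mass-density calibration from a tissue-equivalent rod
## phantom, and the derived bone / bone-marrow HU threshold for small-animal
## CT analysis.

#' Measure mean HU of each calibration rod
#'
#' @param ct a (micro-)CT \linkS4class{VoxelVolume}.
#' @param rodMasks a \linkS4class{VOIMask} with one region per rod.
#' @param densities known rod mass densities (g/mL), one per mask region, in
#'   mask label order.
#' @return data.frame (rod, density, mean_hu, n_voxels).
#' @export
measureRods <- function(ct, rodMasks, densities) {
    validateAlignment(ct, rodMasks)
    rn <- regionNames(rodMasks)
    if (length(rn) != length(densities))
        configError(sprintf("%d rod masks but %d densities supplied",
                            length(rn), length(densities)))
    labels <- voxelData(rodMasks)
    vals <- voxelData(ct)
    res <- lapply(seq_along(rn), function(i) {
        id <- as.integer(names(rn)[i])
        sel <- labels == id
        if (!any(sel))
            lookupError(sprintf("rod region '%s' has no voxels", rn[[i]]))
        data.frame(rod = rn[[i]], density = densities[i],
                   mean_hu = mean(vals[sel]), n_voxels = sum(sel))
    })
    do.call(rbind, res)
}

#' Fit the linear HU ~ density calibration
#'
#' Ordinary least squares of rod mean HU on known density, optionally
#' weighted by rod voxel count. Requires at least two rods with distinct
#' densities.
#'
#' @param rods data.frame from [measureRods()] (columns \code{density},
#'   \code{mean_hu}; optional \code{n_voxels}).
#' @param weightByVoxels weight each rod by its voxel count (default FALSE,
#'   mirroring a fixed VOI template per rod).
#' @return A \linkS4class{CalibrationModel}.
#' @examples
#' rods <- data.frame(density = c(1.08, 1.57), mean_hu = c(280, 770))
#' fitCalibration(rods)
#' @export
fitCalibration <- function(rods, weightByVoxels = FALSE) {
    if (nrow(rods) < 2L)
        configError("calibration needs at least 2 rods")
    if (length(unique(rods$density)) < 2L)
        configError("calibration needs at least 2 distinct rod densities")
    w <- if (weightByVoxels && "n_voxels" %in% names(rods)) rods$n_voxels
         else NULL
    fit <- stats::lm(mean_hu ~ density, data = rods, weights = w)
    cf <- stats::coef(fit)
    # r^2 computed directly; summary.lm warns on exact fits
    tss <- sum((rods$mean_hu - mean(rods$mean_hu))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
    new("CalibrationModel", slope = unname(cf[["density"]]),
        intercept = unname(cf[["(Intercept)"]]),
        rSquared = min(max(r2, 0), 1),
        densityRange = range(rods$density))
}

#' Invert the calibration: density at a given HU
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param hu HU value(s).
#' @return numeric density (g/mL) with attribute \code{extrapolated}: logical,
#'   TRUE where the predicted density falls outside the rod density range.
#' @export
densityAt <- function(model, hu) {
    stopifnot(is(model, "CalibrationModel"))
    dens <- (hu - model@intercept) / model@slope
    structure(dens,
              extrapolated = dens < model@densityRange[1] - 1e-12 |
                             dens > model@densityRange[2] + 1e-12)
}

#' Predicted HU at a given density
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param density g/mL.
#' @return predicted HU.
#' @export
huAt <- function(model, density) {
    stopifnot(is(model, "CalibrationModel"))
    model@slope * density + model@intercept
}

#' Bone / bone-marrow HU threshold from a density cutoff
#'
#' Maps an explicit mass-density cutoff through the calibration to an integer
#' HU threshold separating bone from marrow in small-animal CT. No default
#' cutoff is provided: it must be chosen and logged by the analyst.
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param densityCutoff bone/marrow density cutoff, g/mL (required).
#' @return integer HU threshold.
#' @export
boneBmThreshold <- function(model, densityCutoff = NULL) {
    stopifnot(is(model, "CalibrationModel"))
    if (is.null(densityCutoff))
        configError(paste("no bone/BM density cutoff supplied;",
                          "choose one explicitly (g/mL), e.g.",
                          "boneBmThreshold(model, densityCutoff = 1.2)"))
    as.integer(roundHalfAwayFromZero(huAt(model, densityCutoff)))
}
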