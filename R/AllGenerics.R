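#' @name accessors
#' @title Accessors for bmatquant S4 classes
#' @description Slot accessors for the imaging and model classes. Use these
#'   rather than \code{@} access.
#' @param x an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("voxelUnits", function(x) standardGeneric("voxelUnits"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname accessors
#' @export
setGeneric("youdenJ", function(x) standardGeneric("youdenJ"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setGeneric("voxelClasses", function(x) standardGeneric("voxelClasses"))
#' @rdname accessors
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))
#' @rdname accessors
#' @export
setGeneric("calibrationSlope", function(x) standardGeneric("calibrationSlope"))
#' @rdname accessors
#' @export
setGeneric("calibrationIntercept",
           function(x) standardGeneric("calibrationIntercept"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("densityRange", function(x) standardGeneric("densityRange"))

#' @rdname accessors
setMethod("voxelData", "VoxelVolume", function(x) x@values)
#' @rdname accessors
setMethod("voxelData", "VOIMask", function(x) x@labels)
#' @rdname accessors
setMethod("spacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "VOIMask", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "VoxelVolume", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "VOIMask", function(x) x@origin)
#' @rdname accessors
setMethod("modality", "VoxelVolume", function(x) x@modality)
#' @rdname accessors
setMethod("voxelUnits", "VoxelVolume", function(x) x@units)
#' @rdname accessors
setMethod("regionNames", "VOIMask", function(x) x@regionNames)
#' @rdname accessors
setMethod("thresholds", "ROCCurve", function(x) x@thresholds)
#' @rdname accessors
setMethod("thresholds", "ThresholdScheme",
          function(x) c(yellow_low = x@yellowLow, bmat_rm = x@bmatRM,
                        rm_bone = x@rmBone))
#' @rdname accessors
setMethod("sensitivity", "ROCCurve", function(x) x@sensitivity)
#' @rdname accessors
setMethod("specificity", "ROCCurve", function(x) x@specificity)
#' @rdname accessors
setMethod("youdenJ", "ROCCurve", function(x) x@youdenJ)
#' @rdname accessors
setMethod("auc", "ROCCurve", function(x) x@auc)
#' @rdname accessors
setMethod("classCounts", "CompartmentSegmentation", function(x) x@counts)
#' @rdname accessors
setMethod("voxelClasses", "CompartmentSegmentation", function(x) x@classes)
#' @rdname accessors
setMethod("voxelVolumeML", "CompartmentSegmentation", function(x) x@voxelVolumeML)
#' @rdname accessors
setMethod("calibrationSlope", "CalibrationModel", function(x) x@slope)
#' @rdname accessors
setMethod("calibrationIntercept", "CalibrationModel", function(x) x@intercept)
#' @rdname accessors
setMethod("rSquared", "CalibrationModel", function(x) x@rSquared)
#' @rdname accessors
setMethod("densityRange", "CalibrationModel", function(x) x@densityRange)

setMethod("show", "VoxelVolume", function(object) {
    d <- dim(object@values)
    cat(sprintf("VoxelVolume [%s] %d x %d x %d voxels, spacing %s mm, units %s\n",
                object@modality, d[1], d[2], d[3],
                paste(format(object@spacing, trim = TRUE), collapse = " x "),
                object@units))
    v <- range(object@values)
    cat(sprintf("  value range: [%.6g, %.6g]\n", v[1], v[2]))
})

setMethod("show", "VOIMask", function(object) {
    d <- dim(object@labels)
    cat(sprintf("VOIMask %d x %d x %d voxels, %d regions\n",
                d[1], d[2], d[3], length(object@regionNames)))
    for (id in names(object@regionNames)) {
        cat(sprintf("  [%s] %s: %d voxels\n", id, object@regionNames[[id]],
                    sum(object@labels == as.integer(id))))
    }
})

setMethod("show", "ThresholdScheme", function(object) {
    cat(sprintf(paste0("ThresholdScheme: BMAT [%g, %g) HU | RM [%g, %g] HU | ",
                       "bone > %g HU | out-of-range < %g HU\n"),
                object@yellowLow, object@bmatRM, object@bmatRM, object@rmBone,
                object@rmBone, object@yellowLow))
})

setMethod("show", "ROCCurve", function(object) {
    i <- which.max(object@youdenJ)
    cat(sprintf("ROCCurve over %d integer HU thresholds [%g, %g]\n",
                length(object@thresholds), min(object@thresholds),
                max(object@thresholds)))
    cat(sprintf("  AUC = %.4f; max Youden J = %.4f at t = %g HU\n",
                object@auc, object@youdenJ[i], object@thresholds[i]))
})

setMethod("show", "CompartmentSegmentation", function(object) {
    cat(sprintf("CompartmentSegmentation of %d voxels (%.6g mL each)\n",
                length(object@classes), object@voxelVolumeML))
    for (cl in c("BMAT", "RM", "BONE", "OUT_OF_RANGE"))
        cat(sprintf("  %-13s %d\n", cl, object@counts[[cl]]))
})

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf("CalibrationModel: HU = %.4g * density + %.4g (r^2 = %.4f)\n",
                object@slope, object@intercept, object@rSquared))
    cat(sprintf("  calibrated over %.3g-%.3g g/mL\n",
                object@densityRange[1], object@densityRange[2]))
})

setMethod("show", "HUHistogram", function(object) {
    cat(sprintf("HUHistogram '%s': %d bins [%g, %g] HU, %g voxels (%g out of range)\n",
                object@region, length(object@binCenters),
                min(object@binCenters), max(object@binCenters),
                object@totalVoxels, object@outOfRange))
})

setMethod("show", "CohortHistogramSummary", function(object) {
    cat(sprintf("CohortHistogramSummary: %d subjects, %d bins [%g, %g] HU\n",
                object@nSubjects, length(object@binCenters),
                min(object@binCenters), max(object@binCenters)))
})

setMethod("show", "AdipocyteAnnotationSet", function(object) {
    n <- nrow(object@adipocytes)
    nMulti <- if (n) sum(object@adipocytes$small_droplet_count >= 3L) else 0L
    cat(sprintf("AdipocyteAnnotationSet: %d adipocytes (%d multilocular) in %.4g mm^2 marrow\n",
                n, nMulti, object@marrowArea))
})

setMethod("show", "CompositionParams", function(object) {
    cat(sprintf(paste0("CompositionParams: BM = %.3g of body mass, ",
                       "BMAT/RM split %.2g/%.2g (%s mode)\n"),
                object@bmMassFraction, object@bmatShare, object@rmShare,
                object@splitMode))
    cat(sprintf("  densities (g/mL): fat %.3g, haematopoietic %.3g, bone %.4g, muscle %.4g\n",
                object@densityFat, object@densityHaem, object@densityBone,
                object@densityMuscle))
})
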