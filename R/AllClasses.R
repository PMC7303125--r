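#' @import methods
NULL

#' VoxelVolume: a 3-D scalar image grid
#'
#' The substrate of all imaging operations: a 3-D array of voxel values with
#' physical spacing (mm per axis), a world-space origin (mm) and a modality
#' tag. CT and micro-CT volumes hold Hounsfield units (HU); PET volumes hold
#' activity concentration (kBq/mL) or SUV.
#'
#' @slot values 3-D numeric array of voxel values, indexed (x, y, z).
#' @slot spacing numeric(3), voxel edge lengths in mm; all > 0.
#' @slot origin numeric(3), world-space position of voxel (1,1,1) in mm.
#' @slot modality one of \code{"CT"}, \code{"PET"}, \code{"UCT"}.
#' @slot units unit string: \code{"HU"} for CT/UCT, \code{"kBq/mL"} or
#'   \code{"SUV"} for PET.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
    representation(values = "array", spacing = "numeric",
                   origin = "numeric", modality = "character",
                   units = "character"),
    validity = function(object) {
        msgs <- character()
        if (length(dim(object@values)) != 3L)
            msgs <- c(msgs, sprintf("'values' must be a 3-D array, got %d dimensions",
                                    length(dim(object@values))))
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msgs <- c(msgs, "'spacing' must be 3 positive finite values (mm)")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msgs <- c(msgs, "'origin' must be 3 finite values (mm)")
        if (!object@modality %in% c("CT", "PET", "UCT"))
            msgs <- c(msgs, "'modality' must be one of CT, PET, UCT")
        if (any(!is.finite(object@values)))
            msgs <- c(msgs, "'values' must be finite")
        if (object@modality %in% c("CT", "UCT") && object@units != "HU")
            msgs <- c(msgs, "CT/UCT volumes must carry units 'HU'")
        if (object@modality == "PET" && !object@units %in% c("kBq/mL", "SUV"))
            msgs <- c(msgs, "PET volumes must carry units 'kBq/mL' or 'SUV'")
        if (length(msgs)) msgs else TRUE
    })

#' VOIMask: named volumes of interest on a voxel grid
#'
#' An integer label image aligned to a \linkS4class{VoxelVolume}, with a map
#' from label id to region name. Label 0 is reserved for background.
#'
#' @slot labels 3-D integer array of label ids; 0 = background.
#' @slot spacing numeric(3) mm, must match the companion volume.
#' @slot origin numeric(3) mm.
#' @slot regionNames named character vector; names are label ids as strings,
#'   values are region names (e.g. \code{"sternum_BM"}).
#' @exportClass VOIMask
setClass("VOIMask",
    representation(labels = "array", spacing = "numeric",
                   origin = "numeric", regionNames = "character"),
    validity = function(object) {
        msgs <- character()
        if (length(dim(object@labels)) != 3L)
            msgs <- c(msgs, "'labels' must be a 3-D array")
        if (any(object@labels != floor(object@labels)) || any(object@labels < 0))
            msgs <- c(msgs, "'labels' must be non-negative integers")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msgs <- c(msgs, "'spacing' must be 3 positive values (mm)")
        if (is.null(names(object@regionNames)) && length(object@regionNames))
            msgs <- c(msgs, "'regionNames' must be named by label id")
        if ("0" %in% names(object@regionNames))
            msgs <- c(msgs, "label 0 is reserved for background")
        if (anyDuplicated(object@regionNames))
            msgs <- c(msgs, "region names must be unique")
        if (length(msgs)) msgs else TRUE
    })

#' ThresholdScheme: diagnostic HU cutpoints for marrow segmentation
#'
#' Partitions marrow-cavity voxels by CT attenuation into bone marrow adipose
#' tissue (BMAT), red marrow (RM) and bone. The defaults are the clinically
#' derived cutpoints: BMAT in [-200, 115) HU, RM in [115, 300] HU, bone above
#' 300 HU; voxels below -200 HU are flagged out-of-range (air/artefact).
#'
#' @slot yellowLow lower HU bound of the BMAT (yellow marrow) window.
#' @slot bmatRM HU cutpoint between BMAT and red marrow.
#' @slot rmBone HU cutpoint between red marrow and bone.
#' @exportClass ThresholdScheme
setClass("ThresholdScheme",
    representation(yellowLow = "numeric", bmatRM = "numeric", rmBone = "numeric"),
    validity = function(object) {
        if (!(object@yellowLow < object@bmatRM && object@bmatRM < object@rmBone))
            "thresholds must satisfy yellowLow < bmatRM < rmBone"
        else TRUE
    })

#' ROCCurve: per-threshold operating characteristics over integer HU
#'
#' Sensitivity and specificity of the rule "positive iff HU < t" evaluated on
#' an ascending integer threshold grid, with Youden's J and the trapezoidal
#' area under the curve.
#'
#' @slot thresholds ascending integer HU grid.
#' @slot sensitivity fraction of positives with HU < t, per threshold.
#' @slot specificity fraction of negatives with HU >= t, per threshold.
#' @slot youdenJ sensitivity + specificity - 1.
#' @slot auc trapezoidal area under the (1 - specificity, sensitivity) curve.
#' @exportClass ROCCurve
setClass("ROCCurve",
    representation(thresholds = "numeric", sensitivity = "numeric",
                   specificity = "numeric", youdenJ = "numeric", auc = "numeric"),
    validity = function(object) {
        msgs <- character()
        n <- length(object@thresholds)
        if (is.unsorted(object@thresholds, strictly = TRUE))
            msgs <- c(msgs, "'thresholds' must be strictly ascending")
        if (length(object@sensitivity) != n || length(object@specificity) != n ||
            length(object@youdenJ) != n)
            msgs <- c(msgs, "sensitivity/specificity/youdenJ must match threshold grid")
        if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
            any(object@specificity < 0 | object@specificity > 1))
            msgs <- c(msgs, "sensitivity and specificity must lie in [0, 1]")
        if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
            msgs <- c(msgs, "'auc' must be a single value in [0, 1]")
        if (length(msgs)) msgs else TRUE
    })

#' HUHistogram: 1-HU-wide histogram of a VOI's attenuation values
#'
#' @slot binCenters integer HU values, one per 1-HU bin.
#' @slot counts voxel counts per bin.
#' @slot outOfRange number of voxels falling outside the bin range.
#' @slot totalVoxels total voxels in the sample.
#' @slot region region name the sample came from.
#' @exportClass HUHistogram
setClass("HUHistogram",
    representation(binCenters = "numeric", counts = "numeric",
                   outOfRange = "numeric", totalVoxels = "numeric",
                   region = "character"),
    validity = function(object) {
        msgs <- character()
        if (length(object@binCenters) != length(object@counts))
            msgs <- c(msgs, "'counts' must match 'binCenters'")
        if (any(object@counts < 0) || object@outOfRange < 0)
            msgs <- c(msgs, "counts must be non-negative")
        if (!isTRUE(all.equal(sum(object@counts) + object@outOfRange,
                              object@totalVoxels)))
            msgs <- c(msgs, "counts + outOfRange must equal totalVoxels")
        if (length(msgs)) msgs else TRUE
    })

#' CohortHistogramSummary: mean +/- SEM of per-subject HU proportions
#'
#' Each subject's histogram is normalized to proportions of its own total
#' voxel count before averaging, so subjects with different VOI sizes weigh
#' equally.
#'
#' @slot binCenters shared integer HU bin grid.
#' @slot meanProportion per-bin mean of subject proportions.
#' @slot semProportion per-bin standard error of the mean.
#' @slot nSubjects number of subjects averaged.
#' @exportClass CohortHistogramSummary
setClass("CohortHistogramSummary",
    representation(binCenters = "numeric", meanProportion = "numeric",
                   semProportion = "numeric", nSubjects = "numeric"),
    validity = function(object) {
        msgs <- character()
        if (length(object@meanProportion) != length(object@binCenters) ||
            length(object@semProportion) != length(object@binCenters))
            msgs <- c(msgs, "summary vectors must match the bin grid")
        if (any(object@semProportion < 0))
            msgs <- c(msgs, "SEM must be non-negative")
        if (object@nSubjects < 2)
            msgs <- c(msgs, "at least 2 subjects required")
        if (length(msgs)) msgs else TRUE
    })

#' CompartmentSegmentation: per-voxel marrow compartment labels
#'
#' The classification of every voxel in a bone-marrow VOI into BMAT, RM, BONE
#' or OUT_OF_RANGE, together with class counts and the physical volume of one
#' voxel.
#'
#' @slot classes character vector of class labels, one per BM-VOI voxel.
#' @slot counts named numeric: voxels per class (BMAT, RM, BONE, OUT_OF_RANGE).
#' @slot voxelVolumeML volume of a single voxel in mL.
#' @exportClass CompartmentSegmentation
setClass("CompartmentSegmentation",
    representation(classes = "character", counts = "numeric",
                   voxelVolumeML = "numeric"),
    validity = function(object) {
        msgs <- character()
        lv <- c("BMAT", "RM", "BONE", "OUT_OF_RANGE")
        if (!all(object@classes %in% lv))
            msgs <- c(msgs, "classes must be BMAT, RM, BONE or OUT_OF_RANGE")
        if (!identical(sort(names(object@counts)), sort(lv)))
            msgs <- c(msgs, "counts must be named BMAT, RM, BONE, OUT_OF_RANGE")
        else if (sum(object@counts) != length(object@classes))
            msgs <- c(msgs, "class counts must sum to the VOI voxel count")
        if (object@voxelVolumeML <= 0)
            msgs <- c(msgs, "voxelVolumeML must be positive")
        if (length(msgs)) msgs else TRUE
    })

#' CalibrationModel: linear HU ~ density calibration from a rod phantom
#'
#' Ordinary-least-squares fit of rod mean HU on known rod mass density,
#' HU = slope * density + intercept, valid over the rod density range.
#'
#' @slot slope HU per (g/mL).
#' @slot intercept HU at zero density.
#' @slot rSquared coefficient of determination of the fit.
#' @slot densityRange numeric(2): min and max rod density (g/mL).
#' @exportClass CalibrationModel
setClass("CalibrationModel",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", densityRange = "numeric"),
    validity = function(object) {
        msgs <- character()
        if (length(object@slope) != 1L || object@slope == 0)
            msgs <- c(msgs, "'slope' must be a single non-zero value")
        if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
            msgs <- c(msgs, "'rSquared' must lie in [0, 1]")
        if (length(object@densityRange) != 2L ||
            object@densityRange[1] > object@densityRange[2])
            msgs <- c(msgs, "'densityRange' must be (min, max)")
        if (length(msgs)) msgs else TRUE
    })

#' AdipocyteAnnotationSet: 2-D adipocyte annotations for histomorphometry
#'
#' @slot marrowArea total marrow section area in mm^2.
#' @slot adipocytes data.frame with columns \code{area_mm2} (> 0) and
#'   \code{small_droplet_count} (integer >= 0); a cell with 3 or more small
#'   droplets associated with its main droplet counts as multilocular.
#' @exportClass AdipocyteAnnotationSet
setClass("AdipocyteAnnotationSet",
    representation(marrowArea = "numeric", adipocytes = "data.frame"),
    validity = function(object) {
        msgs <- character()
        if (length(object@marrowArea) != 1L || object@marrowArea <= 0)
            msgs <- c(msgs, "'marrowArea' must be a single positive value (mm^2)")
        ad <- object@adipocytes
        if (!all(c("area_mm2", "small_droplet_count") %in% names(ad)))
            msgs <- c(msgs, "'adipocytes' needs columns area_mm2, small_droplet_count")
        else {
            if (nrow(ad) && any(ad$area_mm2 <= 0))
                msgs <- c(msgs, "adipocyte areas must be positive")
            if (nrow(ad) && any(ad$small_droplet_count < 0 |
                                ad$small_droplet_count != floor(ad$small_droplet_count)))
                msgs <- c(msgs, "small_droplet_count must be non-negative integers")
            if (nrow(ad) && sum(ad$area_mm2) > object@marrowArea + 1e-9)
                msgs <- c(msgs, "total adipocyte area exceeds marrow area")
        }
        if (length(msgs)) msgs else TRUE
    })

#' CompositionParams: body-composition constants for the capacity model
#'
#' Defaults encode the model assumptions: bone marrow is ~5\% of body mass,
#' partitioned 70/30 into BMAT and red marrow, with tissue densities of
#' 0.92 (fat), 1.06 (haematopoietic), 1.245 (bone) and 1.055 (muscle) g/mL.
#' \code{splitMode} selects whether the 70/30 partition is applied to marrow
#' mass (default) or marrow volume.
#'
#' @slot bmMassFraction marrow as proportion of body mass.
#' @slot bmatShare,rmShare BMAT and RM shares of marrow (sum to 1).
#' @slot densityFat,densityHaem,densityBone,densityMuscle g/mL.
#' @slot splitMode \code{"mass"} or \code{"volume"}.
#' @exportClass CompositionParams
setClass("CompositionParams",
    representation(bmMassFraction = "numeric", bmatShare = "numeric",
                   rmShare = "numeric", densityFat = "numeric",
                   densityHaem = "numeric", densityBone = "numeric",
                   densityMuscle = "numeric", splitMode = "character"),
    validity = function(object) {
        msgs <- character()
        if (abs(object@bmatShare + object@rmShare - 1) > 1e-9)
            msgs <- c(msgs, "bmatShare + rmShare must equal 1")
        dens <- c(object@densityFat, object@densityHaem,
                  object@densityBone, object@densityMuscle)
        if (any(dens <= 0)) msgs <- c(msgs, "densities must be positive")
        if (object@bmMassFraction <= 0 || object@bmMassFraction >= 1)
            msgs <- c(msgs, "bmMassFraction must lie in (0, 1)")
        if (!object@splitMode %in% c("mass", "volume"))
            msgs <- c(msgs, "splitMode must be 'mass' or 'volume'")
        if (length(msgs)) msgs else TRUE
    })
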