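## HU-distribution analysis and ROC threshold derivation.
##
## Extract per-VOI HU samples, build 1-HU histograms, summarize across a
## cohort as mean +/- SEM of per-subject proportions, and derive diagnostic
## cutpoints by scanning every integer threshold with the rule
## "positive (BMAT-rich) iff HU < t" and maximizing Youden's J.

#' Extract per-voxel HU values from a named VOI
#'
#' @param ct a CT or micro-CT \linkS4class{VoxelVolume}.
#' @param mask a \linkS4class{VOIMask} on the same grid.
#' @param region region name present in \code{regionNames(mask)}.
#' @return Integer HU values at the region's voxels (one per voxel).
#' @export
extractVoiHU <- function(ct, mask, region) {
    validateAlignment(ct, mask)
    ids <- names(regionNames(mask))[regionNames(mask) == region]
    if (!length(ids))
        lookupError(sprintf("region '%s' not present in mask (regions: %s)",
                            region,
                            paste(regionNames(mask), collapse = ", ")))
    sel <- voxelData(mask) == as.integer(ids[[1]])
    if (!any(sel))
        lookupError(sprintf("region '%s' has no voxels", region))
    roundHalfAwayFromZero(voxelData(ct)[sel])
}

#' Build a 1-HU-wide histogram of an HU sample
#'
#' @param sample numeric HU values (rounded to integers internally).
#' @param range integer HU range covered by the bins (default -500..1500);
#'   values outside are counted as out-of-range, not binned.
#' @param region region name to record (default "").
#' @return An \linkS4class{HUHistogram}.
#' @export
buildHistogram <- function(sample, range = c(-500, 1500), region = "") {
    if (!length(sample)) configError("cannot histogram an empty HU sample")
    hu <- roundHalfAwayFromZero(sample)
    centers <- seq(range[1], range[2])
    inRange <- hu >= range[1] & hu <= range[2]
    counts <- tabulate(hu[inRange] - range[1] + 1L, nbins = length(centers))
    new("HUHistogram", binCenters = as.numeric(centers),
        counts = as.numeric(counts),
        outOfRange = as.numeric(sum(!inRange)),
        totalVoxels = as.numeric(length(hu)), region = region)
}

#' Summarize per-subject histograms as mean +/- SEM proportions
#'
#' Each subject's counts are first normalized by that subject's total voxel
#' count (so VOI size does not weight the average), then the per-bin mean and
#' standard error of the mean across subjects are computed.
#'
#' @param histograms list of \linkS4class{HUHistogram}, one per subject, on
#'   identical bin grids (>= 2 subjects).
#' @return A \linkS4class{CohortHistogramSummary}.
#' @export
summarizeCohort <- function(histograms) {
    if (length(histograms) < 2L)
        configError("cohort summary needs at least 2 subjects (SEM undefined for 1)")
    grid <- histograms[[1]]@binCenters
    for (h in histograms)
        if (!identical(h@binCenters, grid))
            configError("all subject histograms must share one bin grid")
    props <- vapply(histograms, function(h) h@counts / h@totalVoxels,
                    numeric(length(grid)))
    n <- length(histograms)
    m <- rowMeans(props)
    sem <- apply(props, 1L, stats::sd) / sqrt(n)
    new("CohortHistogramSummary", binCenters = grid, meanProportion = m,
        semProportion = sem, nSubjects = as.numeric(n))
}

#' Compute a per-voxel ROC curve over integer HU thresholds
#'
#' The positive class is the low-attenuation (BMAT-rich) sample and the
#' classification rule is "predict positive iff HU < t". For each threshold
#' t on the grid, sensitivity is the fraction of positives with HU < t and
#' specificity the fraction of negatives with HU >= t. AUC is the trapezoidal
#' area under the (1 - specificity, sensitivity) curve; with a grid covering
#' every integer in the pooled sample range this equals the Mann-Whitney
#' estimate P(pos < neg) + P(tie)/2.
#'
#' @param posSample,negSample numeric HU samples (non-empty); rounded to
#'   integer HU internally.
#' @param thresholdGrid ascending integer thresholds; default covers
#'   \code{min(pooled)} to \code{max(pooled) + 1}, which anchors the curve at
#'   (0,0) and (1,1).
#' @return An \linkS4class{ROCCurve}.
#' @examples
#' roc <- computeROC(c(10, 50, 120), c(130, 200, 250))
#' optimalThreshold(roc)
#' @export
computeROC <- function(posSample, negSample, thresholdGrid = NULL) {
    if (!length(posSample) || !length(negSample))
        configError("both ROC classes must be non-empty")
    pos <- roundHalfAwayFromZero(posSample)
    neg <- roundHalfAwayFromZero(negSample)
    if (is.null(thresholdGrid))
        thresholdGrid <- seq(floor(min(c(pos, neg))),
                             ceiling(max(c(pos, neg))) + 1)
    if (is.unsorted(thresholdGrid, strictly = TRUE))
        configError("thresholdGrid must be strictly ascending")
    posSorted <- sort(pos)
    negSorted <- sort(neg)
    # #(x < t) via findInterval on t - 0.5 (samples are integers)
    sens <- findInterval(thresholdGrid - 0.5, posSorted) / length(pos)
    spec <- 1 - findInterval(thresholdGrid - 0.5, negSorted) / length(neg)
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    aucVal <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
    aucVal <- min(max(aucVal, 0), 1)
    new("ROCCurve", thresholds = as.numeric(thresholdGrid),
        sensitivity = sens, specificity = spec,
        youdenJ = sens + spec - 1, auc = aucVal)
}

#' Youden-optimal threshold of an ROC curve
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken toward the lowest threshold (favouring BMAT
#' specificity).
#'
#' @param roc an \linkS4class{ROCCurve}.
#' @param criterion \code{"youden"} (default) or \code{"closest"} (minimum
#'   Euclidean distance to the (0, 1) corner of ROC space).
#' @return The optimal threshold (HU).
#' @export
optimalThreshold <- function(roc, criterion = c("youden", "closest")) {
    criterion <- match.arg(criterion)
    score <- switch(criterion,
        youden = roc@youdenJ,
        closest = -sqrt((1 - roc@sensitivity)^2 + (1 - roc@specificity)^2))
    roc@thresholds[which.max(score)]
}

#' Derive the diagnostic threshold scheme from voxel samples
#'
#' Runs two ROC analyses: BMAT-rich vs red marrow for the BMAT/RM cutpoint
#' and red marrow vs bone for the RM/bone cutpoint. The lower bound of the
#' BMAT window is a fixed scheme parameter, not ROC-derived.
#'
#' @param bmatSample,rmSample,boneSample integer HU samples. \code{boneSample}
#'   may be \code{NULL}, in which case the RM/bone cutpoint keeps
#'   \code{fallbackRmBone}.
#' @param yellowLow fixed lower HU bound (default -200).
#' @param fallbackRmBone RM/bone cutpoint used when no bone sample is given.
#' @return list with \code{scheme} (\linkS4class{ThresholdScheme}) and the
#'   underlying \code{rocBmatRm} / \code{rocRmBone} curves.
#' @export
deriveThresholdScheme <- function(bmatSample, rmSample, boneSample = NULL,
                                  yellowLow = -200, fallbackRmBone = 300) {
    rocBmatRm <- computeROC(bmatSample, rmSample)
    bmatRM <- optimalThreshold(rocBmatRm)
    rocRmBone <- NULL
    rmBone <- fallbackRmBone
    if (!is.null(boneSample)) {
        rocRmBone <- computeROC(rmSample, boneSample)
        rmBone <- optimalThreshold(rocRmBone)
    }
    list(scheme = thresholdScheme(yellowLow, bmatRM, rmBone),
         rocBmatRm = rocBmatRm, rocRmBone = rocRmBone)
}

#' Export an ROC curve as a data.frame
#'
#' @param roc an \linkS4class{ROCCurve}.
#' @return data.frame (threshold, sensitivity, specificity, youden_j).
#' @export
rocTable <- function(roc) {
    data.frame(threshold = roc@thresholds, sensitivity = roc@sensitivity,
               specificity = roc@specificity, youden_j = roc@youdenJ)
}
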