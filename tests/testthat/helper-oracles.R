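# Independent brute-force oracles used to check the package's ROC and
# calibration code paths.

# Scan every integer threshold in [min-1, max+1]; rule: positive iff HU < t.
bruteForceRoc <- function(pos, neg) {
    ts <- as.numeric(seq(floor(min(c(pos, neg))) - 1,
                         ceiling(max(c(pos, neg))) + 1))
    sens <- vapply(ts, function(t) mean(pos < t), numeric(1))
    spec <- vapply(ts, function(t) mean(neg >= t), numeric(1))
    data.frame(t = ts, sens = sens, spec = spec, j = sens + spec - 1)
}

bruteForceOptimum <- function(pos, neg) {
    tab <- bruteForceRoc(pos, neg)
    tab$t[which.max(tab$j)]  # which.max returns the first (lowest) maximizer
}

# Mann-Whitney AUC estimate: P(pos < neg) + 0.5 P(pos == neg).
mannWhitneyAuc <- function(pos, neg) {
    cmp <- outer(pos, neg, "<") + 0.5 * outer(pos, neg, "==")
    mean(cmp)
}

# Closed-form two-point line through (d1, h1), (d2, h2).
twoPointLine <- function(d, h) {
    slope <- (h[2] - h[1]) / (d[2] - d[1])
    c(slope = slope, intercept = h[1] - slope * d[1])
}

# Normal-equation OLS solve, independent of lm().
normalEquationOls <- function(x, y) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    c(intercept = beta[1], slope = beta[2])
}

# Small axis-aligned grid volume + single-region mask for quantification
# tests: HU values laid into the first length(hu) voxels.
tinyVolumeAndMask <- function(hu, shape = c(4, 4, 4), spacing = c(1, 1, 1),
                              region = "bm") {
    stopifnot(length(hu) <= prod(shape))
    vals <- rep(-1000, prod(shape))
    labels <- integer(prod(shape))
    vals[seq_along(hu)] <- hu
    labels[seq_along(hu)] <- 1L
    list(ct = voxelVolume(array(vals, shape), spacing = spacing, modality = "CT"),
         mask = voiMask(array(labels, shape), c("1" = region),
                        spacing = spacing))
}
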