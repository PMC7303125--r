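## Total-body tissue volumes from anthropometrics and the glucose-uptake
## capacity index.
##
## Marrow is taken as ~5% of body mass, split 70/30 into BMAT and red marrow;
## each mass is converted to volume by its tissue density (fat 0.92,
## haematopoietic 1.06 g/mL). Bone volume comes from a height-based bone-mass
## model divided by 1.245 g/mL; skeletal-muscle volume from a sex- and
## age-specific muscle percentage of body mass divided by 1.055 g/mL.
## Uptake capacity per tissue is volume x mean SUV, reported relative to
## skeletal muscle.

#' BMAT and red-marrow volumes from body mass
#'
#' In the default \code{"mass"} mode the 70/30 split is applied to marrow
#' mass and each component divided by its own density:
#' V_BMAT = f * M * s_BMAT / rho_fat, V_RM = f * M * s_RM / rho_haem.
#' The alternative \code{"volume"} mode applies the split to marrow volume:
#' V_BM = f * M / (s_BMAT * rho_fat + s_RM * rho_haem), then
#' V_BMAT = s_BMAT * V_BM.
#'
#' @param bodyMass body mass, kg (> 0).
#' @param params a [compositionParams()].
#' @return named numeric: \code{BMAT} and \code{RM} volumes in litres.
#' @examples
#' bmVolumes(59.67)  # ~2.27 and 0.84 L
#' @export
bmVolumes <- function(bodyMass, params = compositionParams()) {
    stopifnot(is(params, "CompositionParams"))
    if (any(bodyMass <= 0)) configError("body mass must be positive (kg)")
    bmMass <- params@bmMassFraction * bodyMass
    if (params@splitMode == "mass") {
        c(BMAT = bmMass * params@bmatShare / params@densityFat,
          RM = bmMass * params@rmShare / params@densityHaem)
    } else {
        vBM <- bmMass / (params@bmatShare * params@densityFat +
                         params@rmShare * params@densityHaem)
        c(BMAT = params@bmatShare * vBM, RM = params@rmShare * vBM)
    }
}

#' Placeholder height-to-bone-mass model (synthetic)
#'
#' The reference coefficients for estimating bone mass from height are not
#' part of this package; this constructor returns a clearly-labelled
#' synthetic linear placeholder for examples and tests. Calibrate against a
#' reference source before scientific use. It must be passed explicitly:
#' [boneVolume()] has no default model.
#'
#' @param interceptKg,slopeKgPerM linear coefficients,
#'   bone mass = intercept + slope * height.
#' @return function(height_m) -> bone mass (kg), tagged
#'   \code{attr(, "placeholder") = TRUE}.
#' @export
placeholderBoneMassModel <- function(interceptKg = -7.2, slopeKgPerM = 9.85) {
    f <- function(height) interceptKg + slopeKgPerM * height
    attr(f, "placeholder") <- TRUE
    f
}

#' Bone volume from height
#'
#' @param height subject height, m.
#' @param model a height -> bone-mass (kg) function; required (see
#'   [placeholderBoneMassModel()] for a labelled synthetic example).
#' @param params a [compositionParams()] (bone density is used).
#' @return bone volume, litres.
#' @export
boneVolume <- function(height, model = NULL, params = compositionParams()) {
    stopifnot(is(params, "CompositionParams"))
    if (is.null(model) || !is.function(model))
        configError(paste("no bone-mass model configured; supply a",
                          "height -> bone-mass (kg) function, e.g.",
                          "placeholderBoneMassModel() (synthetic placeholder)"))
    mass <- model(height)
    if (any(mass <= 0))
        configError("bone-mass model returned a non-positive mass")
    mass / params@densityBone
}

#' Placeholder muscle-percentage reference table (synthetic)
#'
#' Skeletal muscle as percent of body mass by sex and age band. The reference
#' values used clinically are not part of this package; these are synthetic
#' placeholders of plausible magnitude for examples and tests. The table must
#' be passed explicitly: [muscleVolume()] has no default.
#'
#' @return data.frame (sex, age_min, age_max, muscle_pct), tagged
#'   \code{attr(, "placeholder") = TRUE}.
#' @export
placeholderMuscleFractionTable <- function() {
    tab <- data.frame(
        sex = rep(c("male", "female"), each = 3),
        age_min = rep(c(18, 40, 60), 2),
        age_max = rep(c(39, 59, 120), 2),
        muscle_pct = c(42, 38, 33, 35, 32, 27))
    attr(tab, "placeholder") <- TRUE
    tab
}

#' Skeletal-muscle volume from anthropometrics
#'
#' Looks up the subject's sex/age band in the muscle-percentage table and
#' converts the implied muscle mass to volume with the muscle density.
#'
#' @param subject list or one-row data.frame with \code{age}, \code{sex},
#'   \code{mass_kg} (and optionally \code{height_m}).
#' @param table data.frame (sex, age_min, age_max, muscle_pct); required.
#' @param params a [compositionParams()].
#' @return muscle volume, litres.
#' @export
muscleVolume <- function(subject, table = NULL, params = compositionParams()) {
    stopifnot(is(params, "CompositionParams"))
    if (is.null(table))
        configError(paste("no muscle-percentage table configured; supply one",
                          "(see placeholderMuscleFractionTable() for a",
                          "labelled synthetic example)"))
    hit <- table$sex == subject$sex & table$age_min <= subject$age &
        subject$age <= table$age_max
    if (!any(hit))
        lookupError(sprintf("no muscle-percentage entry for sex=%s age=%.0f",
                            subject$sex, subject$age))
    pct <- table$muscle_pct[which(hit)[1]]
    if (pct <= 0 || pct >= 100)
        configError("muscle percentage must lie in (0, 100)")
    (pct / 100) * subject$mass_kg / params@densityMuscle
}

#' Total glucose-uptake-capacity indices
#'
#' Multiplies each tissue's total-body volume by its mean SUV to obtain an
#' uptake-capacity index (arbitrary units) and expresses each tissue relative
#' to skeletal muscle.
#'
#' @param volumes named numeric, litres; must include \code{muscle} (> 0).
#' @param suvs named numeric, mean SUV per tissue; same names as
#'   \code{volumes}; muscle SUV must be > 0.
#' @return data.frame (tissue, volume_L, suv, uptake_index,
#'   percent_of_muscle); muscle row is 100 exactly.
#' @export
capacity <- function(volumes, suvs) {
    if (!"muscle" %in% names(volumes) || !"muscle" %in% names(suvs))
        configError("capacity requires a 'muscle' entry in volumes and suvs")
    if (volumes[["muscle"]] <= 0 || suvs[["muscle"]] <= 0)
        configError("muscle volume and SUV must be positive")
    tissues <- names(volumes)
    missing <- setdiff(tissues, names(suvs))
    if (length(missing))
        configError(sprintf("no SUV supplied for: %s",
                            paste(missing, collapse = ", ")))
    idx <- volumes[tissues] * suvs[tissues]
    data.frame(tissue = tissues,
               volume_L = unname(volumes[tissues]),
               suv = unname(suvs[tissues]),
               uptake_index = unname(idx),
               percent_of_muscle = unname(100 * idx / idx[["muscle"]]),
               row.names = NULL)
}

#' Body mass at which the model returns a target BMAT volume
#'
#' Numerically inverts [bmVolumes()] in its first component. Used to check
#' internal consistency of the composition model against reported cohort-mean
#' volumes.
#'
#' @param targetBmatL target BMAT volume, litres.
#' @param params a [compositionParams()].
#' @return body mass, kg.
#' @export
solveBodyMassForBmat <- function(targetBmatL, params = compositionParams()) {
    if (targetBmatL <= 0) configError("target volume must be positive")
    f <- function(m) bmVolumes(m, params)[["BMAT"]] - targetBmatL
    stats::uniroot(f, interval = c(1e-3, 1e4), tol = 1e-10)$root
}
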