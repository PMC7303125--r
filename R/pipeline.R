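## End-to-end orchestration: simulate / human / mouse / calibrate modes from
## one run configuration, with seed capture and report writing.

#' Assemble and validate a run configuration
#'
#' @param mode \code{"simulate"}, \code{"human"}, \code{"mouse"} or
#'   \code{"calibrate"}.
#' @param ... mode-specific fields, see Details.
#' @param seed master integer seed (default 1).
#'
#' @details
#' \describe{
#'   \item{simulate}{optional \code{phantom} (arguments for
#'     [phantomConfig()]), \code{deriveThresholds} (default TRUE),
#'     \code{suv} (list: injectedDose MBq, bodyMass g; default 185 MBq /
#'     60000 g).}
#'   \item{human}{\code{ctPath}, \code{maskPath}, \code{bmatRichRegion},
#'     \code{bmatDeficientRegion} (for derivation) or \code{scheme}
#'     (yellow_low, bmat_rm, rm_bone), \code{bmRegions} (regions to
#'     quantify), optional \code{petPath} + \code{suv}.}
#'   \item{mouse}{\code{ctPath}, \code{maskPath}, \code{densities},
#'     \code{densityCutoff} (g/mL, required), optional \code{gammaPath}
#'     (CSV: tissue, cpm, conversion, mass_g, elapsed_min) +
#'     \code{injectedDose}.}
#'   \item{calibrate}{\code{ctPath}, \code{maskPath}, \code{densities}.}
#' }
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(mode = c("simulate", "human", "mouse", "calibrate"),
                      ..., seed = 1L) {
    mode <- match.arg(mode)
    cfg <- list(...)
    cfg$mode <- mode
    cfg$seed <- as.integer(seed)
    need <- function(fields) {
        miss <- setdiff(fields, names(cfg))
        if (length(miss))
            configError(sprintf("mode '%s' requires config fields: %s",
                                mode, paste(miss, collapse = ", ")))
    }
    if (mode == "human") {
        need(c("ctPath", "maskPath", "bmRegions"))
        if (is.null(cfg$scheme) &&
            (is.null(cfg$bmatRichRegion) || is.null(cfg$bmatDeficientRegion)))
            configError(paste("human mode needs either 'scheme' or both",
                              "'bmatRichRegion' and 'bmatDeficientRegion'",
                              "for threshold derivation"))
    } else if (mode == "mouse") {
        need(c("ctPath", "maskPath", "densities", "densityCutoff"))
    } else if (mode == "calibrate") {
        need(c("ctPath", "maskPath", "densities"))
    }
    structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys are [runConfig()] arguments.
#' @return A validated \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) ioError(sprintf("config file not found: %s", path))
    y <- yaml::read_yaml(path)
    if (is.null(y$mode)) configError("config must name a 'mode'")
    mode <- y$mode
    seed <- if (is.null(y$seed)) 1L else y$seed
    y$mode <- NULL; y$seed <- NULL
    do.call(runConfig, c(list(mode = mode, seed = seed), y))
}

schemeFromConfig <- function(s) {
    if (is(s, "ThresholdScheme")) return(s)
    thresholdScheme(s$yellow_low %||% -200, s$bmat_rm %||% 115,
                    s$rm_bone %||% 300)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stageError <- function(stage, subject, e) {
    stop(structure(class = c("bmq_stage_error", "bmq_error", "error", "condition"),
                   list(message = sprintf("[stage %s%s] %s", stage,
                                          if (nzchar(subject)) paste0(", subject ", subject) else "",
                                          conditionMessage(e)),
                        call = NULL)))
}

withStage <- function(stage, subject = "", expr) {
    tryCatch(expr, error = function(e) {
        if (inherits(e, "bmq_stage_error")) stop(e)
        stageError(stage, subject, e)
    })
}

quantifyRegions <- function(ct, pet, masks, regions, scheme, suvPar) {
    rows <- list()
    suvRows <- list()
    for (rg in regions) {
        seg <- withStage("segment", rg, segmentBM(ct, masks, rg, scheme))
        adv <- withStage("adiposity", rg, adiposityFraction(seg))
        counts <- classCounts(seg)
        rows[[rg]] <- data.frame(
            region = rg,
            n_voxels = sum(counts),
            bmat_voxels = counts[["BMAT"]], rm_voxels = counts[["RM"]],
            bone_voxels = counts[["BONE"]],
            out_of_range_voxels = counts[["OUT_OF_RANGE"]],
            ad_v_ma_v_pct = adv$ad_v_over_ma_v,
            total_volume_mL = adv$volumes_mL[["total"]],
            bmat_volume_mL = adv$volumes_mL[["BMAT"]],
            row.names = NULL)
        if (!is.null(pet) && !is.null(suvPar)) {
            suv <- withStage("suv", rg,
                             compartmentSUV(pet, masks, rg, seg, suvPar))
            suvRows[[rg]] <- data.frame(region = rg, class = names(suv),
                                        mean_suv = unname(suv),
                                        row.names = NULL)
        }
    }
    list(adiposity = do.call(rbind, rows),
         suv = if (length(suvRows)) do.call(rbind, suvRows) else NULL)
}

#' Run the analysis pipeline
#'
#' Executes one mode end to end and returns a report. In \code{simulate}
#' mode a phantom is generated, thresholds are derived by ROC between the
#' configured BMAT-rich and BMAT-deficient marrow regions (unless
#' \code{deriveThresholds} is FALSE, in which case the default scheme is
#' applied verbatim), all marrow regions are segmented and quantified, and
#' compartment SUVs computed. \code{human} mode does the same from NIfTI
#' inputs. \code{mouse} mode fits the rod calibration, converts the density
#' cutoff to an HU threshold and, if a gamma-count table is supplied,
#' computes \%ID/g per tissue. \code{calibrate} mode fits and reports the
#' calibration only.
#'
#' @param config a \code{"RunConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return list of class \code{"RunReport"}: mode, derived or applied
#'   thresholds, per-region adiposity and SUV tables, calibration and
#'   \%ID/g tables where applicable, and provenance (seed, config hash,
#'   package version).
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "RunConfig"))
        configError("config must be built by runConfig() or readRunConfig()")
    report <- list(mode = config$mode)
    if (config$mode == "simulate") {
        phantomArgs <- config$phantom %||% list()
        phantomArgs$seed <- phantomArgs$seed %||% config$seed
        pc <- withStage("generate", "", do.call(phantomConfig, phantomArgs))
        ph <- withStage("generate", "", generateHumanPhantom(pc))
        derive <- config$deriveThresholds %||% TRUE
        if (derive) {
            fr <- pc$bmRegions$bmat_fraction
            rich <- pc$bmRegions$name[which.max(fr)]
            deficient <- pc$bmRegions$name[which.min(fr)]
            der <- withStage("derive_thresholds", "", deriveThresholdScheme(
                extractVoiHU(ph$ct, ph$masks, rich),
                extractVoiHU(ph$ct, ph$masks, deficient)))
            scheme <- der$scheme
            report$roc <- rocTable(der$rocBmatRm)
        } else {
            scheme <- schemeFromConfig(config$scheme %||% thresholdScheme())
        }
        suvCfg <- config$suv %||% list(injectedDose = 185, bodyMass = 60000)
        suvPar <- suvParams(suvCfg$injectedDose, suvCfg$bodyMass)
        q <- quantifyRegions(ph$ct, ph$pet, ph$masks, pc$bmRegions$name,
                             scheme, suvPar)
        report$thresholds <- thresholds(scheme)
        report$adiposity <- q$adiposity
        report$suv <- q$suv
        report$truth <- data.frame(region = names(ph$truth$true_bmat_fraction),
                                   true_bmat_fraction =
                                       unname(ph$truth$true_bmat_fraction))
    } else if (config$mode == "human") {
        ct <- withStage("read", config$ctPath,
                        readVolume(config$ctPath, "CT"))
        masks <- withStage("read", config$maskPath, readMask(config$maskPath))
        pet <- suvPar <- NULL
        if (!is.null(config$petPath)) {
            pet <- withStage("read", config$petPath,
                             readVolume(config$petPath, "PET"))
            suvCfg <- config$suv %||%
                configError("petPath given but no 'suv' dose/mass parameters")
            suvPar <- suvParams(suvCfg$injectedDose, suvCfg$bodyMass)
        }
        if (is.null(config$scheme)) {
            der <- withStage("derive_thresholds", "", deriveThresholdScheme(
                extractVoiHU(ct, masks, config$bmatRichRegion),
                extractVoiHU(ct, masks, config$bmatDeficientRegion)))
            scheme <- der$scheme
            report$roc <- rocTable(der$rocBmatRm)
        } else {
            scheme <- schemeFromConfig(config$scheme)
        }
        q <- quantifyRegions(ct, pet, masks, config$bmRegions, scheme, suvPar)
        report$thresholds <- thresholds(scheme)
        report$adiposity <- q$adiposity
        report$suv <- q$suv
    } else if (config$mode %in% c("mouse", "calibrate")) {
        ct <- withStage("read", config$ctPath,
                        readVolume(config$ctPath, "UCT"))
        masks <- withStage("read", config$maskPath, readMask(config$maskPath))
        rods <- withStage("measure_rods", "",
                          measureRods(ct, masks, config$densities))
        model <- withStage("fit_calibration", "", fitCalibration(rods))
        report$rods <- rods
        report$calibration <- c(slope = calibrationSlope(model),
                                intercept = calibrationIntercept(model),
                                r_squared = rSquared(model),
                                density_min = densityRange(model)[1],
                                density_max = densityRange(model)[2])
        if (config$mode == "mouse") {
            thr <- withStage("bone_bm_threshold", "",
                             boneBmThreshold(model, config$densityCutoff))
            report$boneBmThresholdHU <- thr
            if (!is.null(config$gammaPath)) {
                gamma <- withStage("read", config$gammaPath, {
                    if (!file.exists(config$gammaPath))
                        ioError(sprintf("gamma table not found: %s",
                                        config$gammaPath))
                    utils::read.csv(config$gammaPath)
                })
                dose <- config$injectedDose %||%
                    configError("gammaPath given but no 'injectedDose'")
                report$percentIdPerG <- data.frame(
                    tissue = gamma$tissue,
                    pct_id_per_g = vapply(seq_len(nrow(gamma)), function(i)
                        withStage("percent_id_per_g", gamma$tissue[i],
                                  percentIdPerG(
                                      gammaSample(gamma$cpm[i],
                                                  gamma$conversion[i],
                                                  gamma$mass_g[i],
                                                  gamma$elapsed_min[i]),
                                      dose)), numeric(1)),
                    row.names = NULL)
            }
        }
    }
    cfgForHash <- unclass(config)
    report$provenance <- list(
        seed = config$seed,
        config_hash = sprintf("%08x", sum(utf8ToInt(
            paste(utils::capture.output(utils::str(cfgForHash)), collapse = "")))),
        package_version = as.character(utils::packageVersion("bmatquant")))
    structure(report, class = "RunReport")
}

#' Write a run report to disk
#'
#' Writes each table as CSV, a JSON manifest (mode, thresholds, provenance)
#' and a plain-text log of every resolved threshold and parameter.
#'
#' @param report a \code{"RunReport"} from [runPipeline()].
#' @param directory output directory; created if absent.
#' @return character vector of written paths, invisibly.
#' @export
writeReport <- function(report, directory) {
    if (!inherits(report, "RunReport"))
        configError("report must come from runPipeline()")
    ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                              showWarnings = FALSE)
    if (!ok || !dir.exists(directory))
        ioError(sprintf("cannot create output directory %s", directory))
    written <- character()
    writeTable <- function(name) {
        tab <- report[[name]]
        if (is.null(tab)) return()
        p <- file.path(directory, paste0(name, ".csv"))
        utils::write.csv(as.data.frame(tab), p, row.names = FALSE)
        written <<- c(written, p)
    }
    for (nm in c("adiposity", "suv", "roc", "rods", "percentIdPerG", "truth"))
        writeTable(nm)
    manifest <- list(mode = report$mode, provenance = report$provenance)
    if (!is.null(report$thresholds))
        manifest$thresholds <- as.list(report$thresholds)
    if (!is.null(report$calibration))
        manifest$calibration <- as.list(report$calibration)
    if (!is.null(report$boneBmThresholdHU))
        manifest$bone_bm_threshold_hu <- report$boneBmThresholdHU
    mp <- file.path(directory, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mp)
    lp <- file.path(directory, "run.log")
    lines <- c(sprintf("mode: %s", report$mode),
               sprintf("seed: %d", report$provenance$seed),
               sprintf("config_hash: %s", report$provenance$config_hash))
    if (!is.null(report$thresholds))
        lines <- c(lines, sprintf("threshold %s: %g HU",
                                  names(report$thresholds),
                                  report$thresholds))
    if (!is.null(report$calibration))
        lines <- c(lines, sprintf("calibration %s: %g",
                                  names(report$calibration),
                                  report$calibration))
    writeLines(lines, lp)
    written <- c(written, lp)
    invisible(written)
}
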