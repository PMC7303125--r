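## NIfTI-1 I/O and the grid-alignment contract.
##
## All volumes in a run share one voxel grid: registration is assumed done
## upstream and no resampling is performed here. CT volumes are stored as
## signed 16-bit integer HU, PET as 32-bit float; spacing and origin travel
## in the sform (axis-aligned, no rotation).

sformAffine <- function(spacing, origin) {
    aff <- diag(4)
    diag(aff)[1:3] <- spacing
    aff[1:3, 4] <- origin
    aff
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param expectedModality modality tag for the returned object:
#'   \code{"CT"}, \code{"PET"} or \code{"UCT"}.
#' @param units optional unit override; defaults by modality.
#' @return A \linkS4class{VoxelVolume} with values, spacing and origin taken
#'   from the file header.
#' @seealso [writeVolume()], [validateAlignment()]
#' @export
readVolume <- function(path, expectedModality = c("CT", "PET", "UCT"),
                       units = NULL) {
    expectedModality <- match.arg(expectedModality)
    if (!file.exists(path))
        ioError(sprintf("volume file not found: %s", path))
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                        ioError(sprintf("failed to read NIfTI volume %s: %s",
                                        path, conditionMessage(e))))
    d <- dim(img)
    if (length(d) != 3L)
        ioError(sprintf("%s: expected a 3-D volume, got %d dimensions",
                        path, length(d)))
    aff <- RNifti::xform(img)
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
    org <- aff[1:3, 4]
    voxelVolume(array(as.numeric(img), dim = d), spacing = sp, origin = org,
                modality = expectedModality, units = units)
}

#' Write a VoxelVolume as NIfTI-1
#'
#' CT and micro-CT volumes are written as signed 16-bit integers, PET volumes
#' as 32-bit floats.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param path destination \code{.nii} or \code{.nii.gz} path.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "VoxelVolume"))
    dtype <- if (modality(volume) %in% c("CT", "UCT")) "int16" else "float"
    vals <- voxelData(volume)
    if (dtype == "int16") vals <- roundHalfAwayFromZero(vals)
    img <- RNifti::asNifti(vals)
    RNifti::sform(img) <- structure(sformAffine(spacing(volume), origin(volume)),
                                    code = 2L)
    ok <- tryCatch({RNifti::writeNifti(img, path, datatype = dtype); TRUE},
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
        ioError(sprintf("could not write volume to %s", path))
    invisible(path)
}

#' Write a VOIMask and its region-name sidecar
#'
#' The label image is written as NIfTI-1 integers and the label-to-name map
#' as a JSON sidecar \code{<path>.json}.
#'
#' @param mask a \linkS4class{VOIMask}.
#' @param path destination \code{.nii} or \code{.nii.gz} path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "VOIMask"))
    img <- RNifti::asNifti(voxelData(mask))
    RNifti::sform(img) <- structure(sformAffine(spacing(mask), origin(mask)),
                                    code = 2L)
    tryCatch(RNifti::writeNifti(img, path, datatype = "int16"),
             error = function(e) ioError(sprintf("could not write mask to %s", path)))
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(as.list(regionNames(mask)), sidecar, auto_unbox = TRUE)
    invisible(path)
}

#' Read a VOIMask written by writeMask
#'
#' @param path label-image path; the region-name map is read from
#'   \code{<path>.json}.
#' @return A \linkS4class{VOIMask}.
#' @export
readMask <- function(path) {
    if (!file.exists(path))
        ioError(sprintf("mask file not found: %s", path))
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        ioError(sprintf("%s: expected a 3-D label image, got %d dimensions",
                        path, length(d)))
    aff <- RNifti::xform(img)
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
        ioError(sprintf("region-name sidecar not found: %s", sidecar))
    rn <- unlist(jsonlite::read_json(sidecar))
    voiMask(array(as.integer(img), dim = d), regionNames = rn,
            spacing = sqrt(colSums(aff[1:3, 1:3]^2)), origin = aff[1:3, 4])
}

#' Check that a volume and a mask share one voxel grid
#'
#' Every operation that pairs a volume with a mask requires co-registered
#' inputs on an identical grid. Shapes must match exactly and spacing within
#' 1e-6 mm per axis.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param mask a \linkS4class{VOIMask} (or second volume).
#' @return \code{TRUE} invisibly; throws an alignment error on mismatch.
#' @export
validateAlignment <- function(volume, mask) {
    d1 <- dim(voxelData(volume)); d2 <- dim(voxelData(mask))
    s1 <- spacing(volume); s2 <- spacing(mask)
    if (!identical(d1, d2))
        alignmentError(sprintf(
            "grid shape mismatch: volume %s vs mask %s",
            paste(d1, collapse = "x"), paste(d2, collapse = "x")))
    if (any(abs(s1 - s2) > 1e-6))
        alignmentError(sprintf(
            "voxel spacing mismatch: volume (%s) mm vs mask (%s) mm",
            paste(format(s1), collapse = ", "),
            paste(format(s2), collapse = ", ")))
    invisible(TRUE)
}
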