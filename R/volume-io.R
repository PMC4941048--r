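# Reading and writing the standard on-disk formats: NIfTI-1 volumes,
# multi-page TIFF stacks with a JSON spacing sidecar, PNG/TIFF 2D masks with
# a CSV manifest, plain-text affines, CSV landmark and score tables.

#' Read a 3D volume
#'
#' NIfTI volumes are reoriented to the package's fixed axis convention (RAS
#' codes) using the header transform; a header without orientation
#' information is an error, never a silent assumption. Spacing is taken from
#' the header in micrometres. TIFF stacks carry no physical spacing, so a
#' JSON sidecar (\code{<file>.json} with \code{spacing_um}, optionally
#' \code{origin_um}) is required. Integer intensities are preserved
#' bit-exactly.
#'
#' @param path file path (.nii, .nii.gz, .tif/.tiff).
#' @param format \code{"auto"} (from extension), \code{"nifti"} or
#'   \code{"tiff"}.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path, format = c("auto", "nifti", "tiff")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
    if (format == "nifti") {
        img <- RNifti::readNifti(path)
        if (length(dim(img)) != 3L)
            stop(sprintf("'%s' is not a 3D volume (dims: %s)", path,
                 paste(dim(img), collapse = "x")))
        x <- RNifti::xform(img)
        if (is.null(attr(x, "code")) || attr(x, "code") == 0)
            stop(sprintf("'%s' has no orientation information (xform code 0)",
                         path))
        if (RNifti::orientation(img) != "RAS")
            RNifti::orientation(img) <- "RAS"
        spc <- RNifti::pixdim(img)[1:3]
        if (any(!is.finite(spc)) || any(spc <= 0))
            stop(sprintf("'%s' has missing or non-positive pixdim", path))
        org <- RNifti::xform(img)[1:3, 4]
        BrainVolume(array(as.numeric(img), dim(img)), spc, org)
    } else {
        planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (!is.list(planes)) planes <- list(planes)
        side <- paste0(path, ".json")
        if (!file.exists(side))
            stop(sprintf("missing spacing sidecar '%s': TIFF carries no physical units",
                         side))
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (is.null(meta$spacing_um))
            stop(sprintf("sidecar '%s' lacks required field 'spacing_um'", side))
        spc <- as.numeric(meta$spacing_um)
        if (length(spc) == 2L) stop("spacing_um must have 3 components (x, y, z)")
        if (length(spc) == 1L) spc <- rep(spc, 3)
        org <- as.numeric(meta$origin_um %||% c(0, 0, 0))
        nz <- length(planes)
        d <- dim(planes[[1]])
        arr <- array(0, c(d[2], d[1], nz))  # planes are [y, x]; store [x, y, z]
        for (k in seq_len(nz)) arr[, , k] <- t(planes[[k]])
        BrainVolume(arr, spc, org)
    }
}

#' Write a 3D volume
#'
#' @param v a [BrainVolume-class] (or [LabelVolume-class] via
#'   [writeLabelVolume()]).
#' @param path output path; format from extension as in [readVolume()].
#' @return The path, invisibly.
#' @export
writeVolume <- function(v, path) {
    if (grepl("\\.nii(\\.gz)?$", path)) {
        arr <- voxelData(v)
        img <- RNifti::asNifti(arr)
        RNifti::pixdim(img) <- spacing(v)
        m <- diag(c(spacing(v), 1))
        m[1:3, 4] <- origin(v)
        RNifti::qform(img) <- structure(m, code = 2L)
        RNifti::writeNifti(img, path)
    } else {
        arr <- voxelData(v)
        isInt <- all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 65535
        planes <- lapply(seq_len(dim(arr)[3]), function(k) {
            p <- t(arr[, , k])
            if (isInt) p / 65535 else p
        })
        if (isInt)
            tiff::writeTIFF(planes, path, bits.per.sample = 16L)
        else
            tiff::writeTIFF(lapply(planes, function(p)
                matrix(as.numeric(p), nrow(p))), path,
                bits.per.sample = 32L, sample.format = "float")
        jsonlite::write_json(list(spacing_um = spacing(v),
                                  origin_um = origin(v)),
                             paste0(path, ".json"), auto_unbox = FALSE,
                             digits = NA)
    }
    invisible(path)
}

#' Read/write label volumes
#'
#' Labels are stored as integer NIfTI volumes; the label table travels in a
#' CSV sidecar \code{<file>.labels.csv} (columns id, acronym).
#'
#' @param path NIfTI path.
#' @return \code{readLabelVolume}: a [LabelVolume-class].
#' @export
readLabelVolume <- function(path) {
    v <- readVolume(path, "nifti")
    side <- paste0(path, ".labels.csv")
    lt <- if (file.exists(side))
        utils::read.csv(side, stringsAsFactors = FALSE) else NULL
    LabelVolume(array(as.integer(round(voxelData(v))), dim(v)), spacing(v),
                origin(v), lt)
}

#' @rdname readLabelVolume
#' @param lv a [LabelVolume-class].
#' @export
writeLabelVolume <- function(lv, path) {
    writeVolume(BrainVolume(array(as.double(labelData(lv)), dim(lv)),
                            spacing(lv), origin(lv)), path)
    utils::write.csv(labelTable(lv), paste0(path, ".labels.csv"),
                     row.names = FALSE)
    invisible(path)
}

#' Plain-text 4x4 affine transforms
#'
#' Row-major whitespace-separated text at full double precision;
#' round-trips exactly at the printed precision.
#'
#' @param t an [AffineTransform3D-class]; @param path file path.
#' @export
writeAffine <- function(t, path) {
    stopifnot(is(t, "AffineTransform3D"))
    validObject(t)
    writeLines(apply(t@matrix, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), path)
    invisible(path)
}

#' @rdname writeAffine
#' @return \code{readAffine}: an [AffineTransform3D-class].
#' @export
readAffine <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != 4)
        stop(sprintf("expected 4 matrix rows in '%s', found %d", path,
                     length(lines)))
    rows <- lapply(seq_along(lines), function(i) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                     "\\s+")[[1]]))
        if (length(vals) != 4 || any(is.na(vals)))
            stop(sprintf("malformed affine at line %d of '%s'", i, path))
        vals
    })
    affineTransform(do.call(rbind, rows))
}

#' Read/write FFD transforms
#'
#' The control-point displacement field is stored as a 5D NIfTI vector
#' field (nx, ny, nz, 1, 3) and the lattice/reference geometry plus the
#' initial affine in a JSON sidecar \code{<file>.json}.
#'
#' @param t an [FFDTransform-class]; @param path NIfTI path.
#' @export
writeFFD <- function(t, path) {
    co <- t@coefficients
    d <- dim(co)
    img <- RNifti::asNifti(array(co, c(d[1:3], 1L, 3L)))
    RNifti::writeNifti(img, path)
    meta <- list(grid_spacing_um = t@gridSpacing, grid_origin_um = t@gridOrigin,
                 ref_dim = t@refDim, ref_spacing_um = t@refSpacing,
                 ref_origin_um = t@refOrigin,
                 affine = as.numeric(t@affine@matrix))
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
    invisible(path)
}

#' @rdname writeFFD
#' @return \code{readFFD}: an [FFDTransform-class].
#' @export
readFFD <- function(path) {
    img <- RNifti::readNifti(path)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    d <- dim(img)
    co <- array(as.numeric(img), c(d[1:3], 3L))
    new("FFDTransform", coefficients = co,
        gridSpacing = as.numeric(meta$grid_spacing_um),
        gridOrigin = as.numeric(meta$grid_origin_um),
        refDim = as.integer(meta$ref_dim),
        refSpacing = as.numeric(meta$ref_spacing_um),
        refOrigin = as.numeric(meta$ref_origin_um),
        affine = affineTransform(matrix(as.numeric(meta$affine), 4, 4)))
}

#' Read a panel of 2D masks from a manifest
#'
#' Masks are single-plane PNG (or TIFF) files listed in a CSV manifest with
#' columns \code{file, rater, brain, structure, attempt, z_index,
#' pixel_size} and an optional \code{invalid} flag (nonzero rows are
#' excluded, e.g. segmentations of the wrong structure or hemisphere).
#' Every manifest row must have its file and every mask file in the
#' directory must be listed, otherwise an error names the offenders.
#'
#' @param dir directory containing the manifest and mask files.
#' @param manifest manifest file name within \code{dir}.
#' @return List of [RaterSegmentation-class]; the number of excluded rows
#'   is attached as attribute \code{"nInvalid"}.
#' @export
readMasks <- function(dir, manifest = "manifest.csv") {
    mf <- utils::read.csv(file.path(dir, manifest), stringsAsFactors = FALSE)
    need <- c("file", "rater", "brain", "structure", "attempt", "z_index",
              "pixel_size")
    if (!all(need %in% names(mf)))
        stop(sprintf("manifest lacks columns: %s",
             paste(setdiff(need, names(mf)), collapse = ", ")))
    missing <- mf$file[!file.exists(file.path(dir, mf$file))]
    onDisk <- setdiff(list.files(dir, pattern = "\\.(png|tif|tiff)$"), mf$file)
    if (length(missing) || length(onDisk))
        stop(sprintf("manifest/file mismatch: missing files [%s]; unlisted files [%s]",
             paste(missing, collapse = ", "), paste(onDisk, collapse = ", ")))
    inval <- if ("invalid" %in% names(mf)) mf$invalid > 0 else rep(FALSE, nrow(mf))
    recs <- lapply(which(!inval), function(i) {
        r <- mf[i, ]
        m <- readMask(file.path(dir, r$file), r$pixel_size, r$z_index)
        RaterSegmentation(m, r$rater, r$brain, r$structure, as.integer(r$attempt))
    })
    attr(recs, "nInvalid") <- sum(inval)
    recs
}

#' Read/write a single 2D mask as PNG
#'
#' @param path PNG path; @param pixelSize,zIndex mask geometry metadata.
#' @export
readMask <- function(path, pixelSize = 1, zIndex = 1L) {
    if (grepl("\\.png$", path)) {
        img <- png::readPNG(path)
        if (length(dim(img)) == 3L) img <- img[, , 1]
    } else {
        img <- tiff::readTIFF(path)
        if (length(dim(img)) == 3L) img <- img[, , 1]
    }
    Mask2D(t(img) > 0.5, pixelSize, zIndex)
}

#' @rdname readMask
#' @param mask a [Mask2D-class].
#' @export
writeMask <- function(mask, path) {
    png::writePNG(t(pixels(mask) * 1), path)
    invisible(path)
}

#' Read/write landmark CSV files
#'
#' Columns \code{name, x, y, z} in world micrometres.
#'
#' @param path CSV path.
#' @export
readLandmarks <- function(path) {
    LandmarkSet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readLandmarks
#' @param lm a [LandmarkSet-class].
#' @export
writeLandmarks <- function(lm, path) {
    utils::write.csv(landmarks(lm), path, row.names = FALSE)
    invisible(path)
}

#' Write a long-form score table as CSV
#'
#' Fixed schema: brain_id, structure, source, comparison, metric, value.
#'
#' @param table a [scorePanel()] data.frame.
#' @param path CSV path.
#' @export
writeScoreTable <- function(table, path) {
    utils::write.csv(table[, c("brain_id", "structure", "source",
                               "comparison", "metric", "value")],
                     path, row.names = FALSE)
    invisible(path)
}
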