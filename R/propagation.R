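# Atlas label propagation and reduction of 3D segmentations to 2D outlines
# comparable with manual raters.

#' Smooth a label volume without mixing label ids
#'
#' Each label's binary indicator (background included) is smoothed
#' \code{passes} times with an isotropic Gaussian, and the output label at
#' every voxel is the argmax over the smoothed indicators. This removes
#' single-voxel, high-frequency border fluctuations (as found in atlases
#' reconstructed from serial 2D annotations) without creating spurious
#' intermediate ids, which direct smoothing of the integer image would.
#' Direct integer smoothing remains available via \code{literal = TRUE} for
#' fidelity experiments.
#'
#' @param lv a [LabelVolume-class].
#' @param sigmaVox Gaussian s.d. in voxels (default 0.5).
#' @param passes number of sequential smoothing passes (default 2).
#' @param literal smooth the raw integer image instead (then round).
#' @return A smoothed [LabelVolume-class].
#' @export
smoothLabels <- function(lv, sigmaVox = 0.5, passes = 2L, literal = FALSE) {
    stopifnot(is(lv, "LabelVolume"), sigmaVox >= 0, passes >= 0)
    if (passes == 0L || sigmaVox == 0) return(lv)
    d <- dim(lv)
    if (literal) {
        arr <- array(as.double(labelData(lv)), d)
        for (p in seq_len(passes))
            arr <- .gaussianSmoothCpp(arr, d, rep(sigmaVox, 3))
        return(LabelVolume(array(as.integer(round(arr)), d), spacing(lv),
                           origin(lv), labelTable(lv)))
    }
    ids <- c(0L, sort(labelTable(lv)$id))
    best <- array(-Inf, d)
    out <- array(0L, d)
    for (id in ids) {
        ind <- array(as.double(labelData(lv) == id), d)
        for (p in seq_len(passes))
            ind <- .gaussianSmoothCpp(ind, d, rep(sigmaVox, 3))
        sel <- ind > best
        out[sel] <- id
        best[sel] <- ind[sel]
    }
    LabelVolume(out, spacing(lv), origin(lv), labelTable(lv))
}

#' Propagate atlas labels through recovered transforms
#'
#' Pre-smooths the atlas labels (per-label indicator smoothing, see
#' [smoothLabels()]) and resamples them onto the reference grid by
#' nearest-neighbour pull-back through the composed transform
#' \code{T(x) = A x + D(x)}. Never produces an id absent from the atlas.
#'
#' @param atlasLabels the atlas [LabelVolume-class].
#' @param affine an [AffineTransform3D-class] (reference to atlas world).
#' @param ffd optional [FFDTransform-class] composed over the affine; its
#'   initial affine is ignored in favour of \code{affine}.
#' @param reference a [BrainVolume-class] whose grid defines the output.
#' @param smoothSigmaVox,smoothPasses atlas pre-smoothing (defaults 0.5, 2).
#' @return A [LabelVolume-class] on the reference grid.
#' @export
propagateLabels <- function(atlasLabels, affine, ffd = NULL, reference,
                            smoothSigmaVox = 0.5, smoothPasses = 2L) {
    stopifnot(is(atlasLabels, "LabelVolume"), is(affine, "AffineTransform3D"))
    sm <- smoothLabels(atlasLabels, smoothSigmaVox, smoothPasses)
    grid <- NULL; coef <- NULL
    if (!is.null(ffd)) {
        grid <- ffdGridList(ffd)
        coef <- ffd@coefficients
    }
    arr <- .resampleCpp(array(as.double(labelData(sm)), dim(sm)), dim(sm),
                        spacing(sm), origin(sm), dim(reference),
                        spacing(reference), origin(reference),
                        affine@matrix, grid, coef, 0L, 0)
    LabelVolume(array(as.integer(arr), dim(reference)), spacing(reference),
                origin(reference), labelTable(atlasLabels))
}

#' Extract 2D coronal outlines of one structure
#'
#' For each z section in the window, the filled binary mask of the structure
#' on that coronal plane. Planes without the structure yield empty-flagged
#' masks.
#'
#' @param seg a [LabelVolume-class].
#' @param structureId label id present in the segmentation's table.
#' @param zWindow integer(2), inclusive 1-based z range.
#' @return List of [Mask2D-class], one per section.
#' @export
extractOutline <- function(seg, structureId, zWindow) {
    stopifnot(is(seg, "LabelVolume"))
    if (!structureId %in% labelTable(seg)$id)
        stop(sprintf("unknown structure id %d", structureId))
    d <- dim(seg)
    if (zWindow[1] < 1 || zWindow[2] > d[3] || zWindow[1] > zWindow[2])
        stop("z window outside volume")
    if (abs(spacing(seg)[1] - spacing(seg)[2]) > 1e-9)
        stop("in-plane spacing must be isotropic for 2D outlines")
    lapply(zWindow[1]:zWindow[2], function(z) {
        m <- labelData(seg)[, , z] == structureId
        if (any(m))
            m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
        Mask2D(m, spacing(seg)[1], z)
    })
}

#' Resample a binary mask to a new pixel grid
#'
#' Nearest-neighbour resampling onto a grid of the given pixel size (and
#' optionally a fixed shape). Both grids share the plane corner as origin,
#' with pixel centres at \code{(i - 0.5) * pixelSize}.
#'
#' @param mask a [Mask2D-class].
#' @param targetPx target pixel size, um.
#' @param targetDim optional integer(2) output shape.
#' @return A [Mask2D-class] at the target pixel size.
#' @export
resampleMask <- function(mask, targetPx, targetDim = NULL) {
    px <- pixelSize(mask)
    d <- dim(mask)
    if (is.null(targetDim))
        targetDim <- pmax(1L, as.integer(round(d * px / targetPx)))
    ix <- pmin(pmax(round(((seq_len(targetDim[1]) - 0.5) * targetPx) / px + 0.5), 1L), d[1])
    iy <- pmin(pmax(round(((seq_len(targetDim[2]) - 0.5) * targetPx) / px + 0.5), 1L), d[2])
    Mask2D(pixels(mask)[ix, iy, drop = FALSE], targetPx, zIndex(mask))
}

#' Select the best-matching 2D plane against a consensus
#'
#' Candidates are resampled onto the consensus pixel grid and the candidate
#' with the highest Dice score is returned; ties break to the lowest z
#' index. If every candidate is empty while the consensus is not, the first
#' candidate is returned with Dice 0 and \code{allEmpty = TRUE}.
#'
#' @param candidates list of [Mask2D-class] (e.g. from [extractOutline()]).
#' @param consensus a [Mask2D-class] on the scoring grid.
#' @return list(mask, zIndex, dice, allEmpty).
#' @export
bestPlane <- function(candidates, consensus) {
    if (length(candidates) == 0) stop("no candidate planes")
    scored <- lapply(candidates, function(m) {
        r <- resampleMask(m, pixelSize(consensus), dim(consensus))
        list(mask = r, z = zIndex(m), dice = diceScore(r, consensus))
    })
    if (all(vapply(scored, function(s) s$mask@empty, logical(1))) &&
        !consensus@empty)
        return(list(mask = scored[[1]]$mask, zIndex = scored[[1]]$z,
                    dice = 0, allEmpty = TRUE))
    dices <- vapply(scored, `[[`, numeric(1), "dice")
    zs <- vapply(scored, `[[`, numeric(1), "z")
    best <- which(dices == max(dices))
    best <- best[which.min(zs[best])]
    list(mask = scored[[best]]$mask, zIndex = as.integer(zs[best]),
         dice = dices[best], allEmpty = FALSE)
}
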