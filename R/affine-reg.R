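# Symmetric block-matching affine registration: multi-resolution, least
# trimmed squares fit, forward/backward symmetrization in the matrix-log
# domain.

#' Parameters for block-matching affine registration
#'
#' @param blockSizeVox edge length of the non-overlapping matching blocks.
#' @param varianceKeepFraction fraction of blocks retained after ranking by
#'   intensity variance.
#' @param searchRadiusVox half-width of the integer displacement search.
#' @param ltsFraction fraction of correspondences kept by the least trimmed
#'   squares fit.
#' @param nLevels,nLevelsComputed pyramid depth and number of (coarsest)
#'   levels optimized; levels with minimum dimension below
#'   \code{minLevelDim} are skipped.
#' @param maxIterPerLevel block-match/fit iterations per level.
#' @param minLevelDim minimum level dimension, voxels.
#' @return Named parameter list.
#' @export
blockMatchParams <- function(blockSizeVox = 4L, varianceKeepFraction = 0.5,
                             searchRadiusVox = 3L, ltsFraction = 0.5,
                             nLevels = 6L, nLevelsComputed = 5L,
                             maxIterPerLevel = 5L, minLevelDim = 16L) {
    stopifnot(varianceKeepFraction > 0, varianceKeepFraction <= 1,
              ltsFraction > 0, ltsFraction <= 1,
              nLevelsComputed <= nLevels)
    as.list(environment())
}

#' Block-matching correspondences between two volumes
#'
#' Partitions the reference into non-overlapping cubes, keeps the most
#' intensity-variant fraction, and matches each retained block to the
#' displacement maximizing normalized cross-correlation within the search
#' radius. Both volumes must be on the same grid.
#'
#' @param ref,flt [BrainVolume-class] objects on a common grid.
#' @param params a [blockMatchParams()] list.
#' @return data.frame with world-coordinate reference points (\code{rx, ry,
#'   rz}), matched floating points (\code{fx, fy, fz}) and the NCC.
#' @export
matchBlocks <- function(ref, flt, params = blockMatchParams()) {
    stopifnot(is(ref, "BrainVolume"), is(flt, "BrainVolume"))
    if (!identical(dim(ref), dim(flt)) ||
        max(abs(spacing(ref) - spacing(flt))) > 1e-9)
        stop("volumes must share a grid for block matching")
    m <- .blockMatchCpp(as.numeric(voxelData(ref)),
                        as.numeric(voxelData(flt)), dim(ref),
                        as.integer(params$blockSizeVox),
                        params$varianceKeepFraction,
                        as.integer(params$searchRadiusVox))
    spc <- spacing(ref); org <- origin(ref)
    data.frame(
        rx = org[1] + m[, "cx"] * spc[1],
        ry = org[2] + m[, "cy"] * spc[2],
        rz = org[3] + m[, "cz"] * spc[3],
        fx = org[1] + (m[, "cx"] + m[, "dx"]) * spc[1],
        fy = org[2] + (m[, "cy"] + m[, "dy"]) * spc[2],
        fz = org[3] + (m[, "cz"] + m[, "dz"]) * spc[3],
        ncc = m[, "ncc"])
}

#' Least-trimmed-squares affine fit to point correspondences
#'
#' Iterates least-squares fit, residual ranking, and refit on the best
#' fraction until the support set stabilizes. Deterministic given an
#' order-independent residual ranking.
#'
#' @param refPts,fltPts n x 3 matrices of corresponding world points.
#' @param ltsFraction fraction of pairs retained.
#' @param maxIter refit iteration cap.
#' @return An [AffineTransform3D-class] mapping refPts to fltPts.
#' @export
fitAffineLTS <- function(refPts, fltPts, ltsFraction = 0.5, maxIter = 20L) {
    refPts <- as.matrix(refPts); fltPts <- as.matrix(fltPts)
    n <- nrow(refPts)
    if (n < 4) stop("need at least 4 correspondences")
    fit <- function(idx) {
        X <- cbind(refPts[idx, , drop = FALSE], 1)
        if (qr(X)$rank < 4) stop("degenerate correspondence geometry")
        qr.solve(X, fltPts[idx, , drop = FALSE])
    }
    keep <- seq_len(n)
    nkeep <- max(4L, ceiling(ltsFraction * n))
    B <- fit(keep)
    for (it in seq_len(maxIter)) {
        res <- rowSums((cbind(refPts, 1) %*% B - fltPts)^2)
        newKeep <- order(res)[seq_len(nkeep)]
        if (setequal(newKeep, keep)) break
        keep <- newKeep
        B <- fit(keep)
    }
    m <- diag(4)
    m[1:3, 1:3] <- t(B[1:3, ])
    m[1:3, 4] <- B[4, ]
    affineTransform(m)
}

# symmetrize an incremental update: average forward and inverted-backward
# in the matrix-log domain, with a linear fallback for pathological logs
.symmetrizeAffine <- function(Mf, Mbinv) {
    out <- tryCatch({
        L <- (pracma::logm(Mf) + pracma::logm(Mbinv)) / 2
        pracma::expm(L)
    }, error = function(e) (Mf + Mbinv) / 2)
    if (any(!is.finite(out))) out <- (Mf + Mbinv) / 2
    out[4, ] <- c(0, 0, 0, 1)
    out
}

#' Affine registration by symmetric block matching
#'
#' Coarse-to-fine loop: at each optimized pyramid level the floating volume
#' is warped onto the reference grid through the current estimate, block
#' matching is run in both directions (reference to warped and warped to
#' reference), each match set is fit by least trimmed squares, and the
#' forward update is averaged with the inverted backward update in the
#' matrix-log domain to enforce symmetry. The final transform maps
#' reference world coordinates to floating world coordinates.
#'
#' @param ref reference [BrainVolume-class] (the sample).
#' @param flt floating [BrainVolume-class] (the atlas average).
#' @param params a [blockMatchParams()] list.
#' @param init optional initial [AffineTransform3D-class].
#' @param verbose print per-level progress.
#' @return An [AffineTransform3D-class].
#' @export
registerAffine <- function(ref, flt, params = blockMatchParams(),
                           init = affineTransform(), verbose = FALSE) {
    stopifnot(is(ref, "BrainVolume"), is(flt, "BrainVolume"))
    sched <- pyramidSchedule(dim(ref), params$nLevels, params$nLevelsComputed,
                             params$minLevelDim)
    tm <- init@matrix
    for (li in which(sched$computed)) {
        f <- sched$factor[li]
        refL <- downsampleVolume(ref, f)
        fltL <- downsampleVolume(flt, f)
        voxTol <- 0.01 * spacing(refL)[1]
        corners <- volumeCorners(dim(refL), spacing(refL), origin(refL))
        for (it in seq_len(params$maxIterPerLevel)) {
            warped <- applyTransform(fltL, affineTransform(tm), refL, "linear")
            fw <- matchBlocks(refL, warped, params)
            if (nrow(fw) < 4) break
            Mf <- fitAffineLTS(fw[, c("rx", "ry", "rz")],
                               fw[, c("fx", "fy", "fz")],
                               params$ltsFraction)@matrix
            bw <- matchBlocks(warped, refL, params)
            Msym <- if (nrow(bw) >= 4) {
                Mb <- fitAffineLTS(bw[, c("rx", "ry", "rz")],
                                   bw[, c("fx", "fy", "fz")],
                                   params$ltsFraction)@matrix
                .symmetrizeAffine(Mf, solve(Mb))
            } else Mf
            tm <- tm %*% Msym
            shift <- max(sqrt(rowSums(
                (applyAffineToPoints(Msym, corners) - corners)^2)))
            if (verbose)
                message(sprintf("  affine level f=%d iter %d: update %.4g um",
                                f, it, shift))
            if (shift < voxTol) break
        }
    }
    affineTransform(tm)
}
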