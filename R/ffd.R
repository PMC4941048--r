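# Free-form deformation registration: cubic B-spline control lattice
# optimized under normalized mutual information with bending-energy
# regularization, conjugate-gradient ascent, multi-resolution.

#' Parameters for free-form registration
#'
#' Defaults reproduce the standard pipeline configuration: NMI with 128-bin
#' discretization, bending-energy weight 0.95, control-point spacing of 10
#' reference voxels, 1-voxel Gaussian input smoothing, and a six-level
#' coarse-to-fine pyramid of which the four coarsest available levels are
#' optimized.
#'
#' @param similarity only \code{"nmi"} is implemented as default;
#'   \code{"lncc"} (locally normalized cross-correlation) is accepted as a
#'   configuration value for parameter searches.
#' @param nmiBins requested histogram bins (>= 8). At coarse pyramid levels
#'   the effective bin count is capped near the cube root of the voxel count
#'   so the joint histogram stays populated.
#' @param beWeight bending-energy weight in [0, 1); objective is
#'   \code{(1 - beWeight) * NMI - beWeight * BE}.
#' @param gridSpacingVox control-point spacing in voxels of the current
#'   pyramid level (so physical spacing doubles per coarser level).
#' @param inputSmoothSigmaVox Gaussian smoothing of both inputs per level.
#' @param nLevels,nLevelsComputed pyramid depth and number of (coarsest)
#'   levels optimized; levels whose minimum dimension would drop below
#'   \code{minLevelDim} voxels are skipped.
#' @param maxIterPerLevel,convergenceTol conjugate-gradient iteration cap and
#'   relative objective-gain stopping tolerance.
#' @param gradientSmoothKnots s.d. (in knots) of Gaussian smoothing applied
#'   to the NMI gradient before the CG step; 0 disables.
#' @param beStride stride (voxels) of the dense reference sampling used for
#'   the bending energy during optimization.
#' @param minLevelDim minimum level dimension, voxels.
#' @return A named list of parameters.
#' @export
ffdParams <- function(similarity = "nmi", nmiBins = 128L, beWeight = 0.95,
                      gridSpacingVox = 10L, inputSmoothSigmaVox = 1,
                      nLevels = 6L, nLevelsComputed = 4L,
                      maxIterPerLevel = 300L, convergenceTol = 1e-5,
                      gradientSmoothKnots = 1, beStride = 2L,
                      minLevelDim = 16L) {
    stopifnot(nmiBins >= 8, beWeight >= 0, beWeight < 1,
              nLevelsComputed <= nLevels)
    as.list(environment())
}

#' Apply an FFD transform to points
#'
#' Maps world points through \code{T(x) = A x + D(x)}: the initial affine
#' plus the cubic B-spline interpolation of the control displacements.
#'
#' @param t an [FFDTransform-class].
#' @param points n x 3 matrix of world coordinates (um).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
deformPoints <- function(t, points) {
    stopifnot(is(t, "FFDTransform"))
    .deformPointsCpp(rbind(points), t@affine@matrix, ffdGridList(t),
                     t@coefficients)
}

#' Normalized mutual information between two volumes
#'
#' \code{(H(A) + H(B)) / H(A, B)} with entropies in nats, computed from a
#' joint histogram with linear (first-order Parzen) binning whose edges are
#' derived from the min/max of each image over the overlap. Both volumes
#' must share a grid; the value exceeds 1 unless the images are independent
#' and reaches 2 for identical images whose values fill bins exactly.
#'
#' @param ref,warped [BrainVolume-class] objects on the same grid.
#' @param bins histogram bins per image.
#' @return NMI value (scalar).
#' @export
nmi <- function(ref, warped, bins = 128L) {
    stopifnot(is(ref, "BrainVolume"), is(warped, "BrainVolume"))
    if (!identical(dim(ref), dim(warped)))
        stop("volumes must share a grid for NMI")
    if (prod(dim(ref)) == 0) stop("empty overlap")
    .nmiPairCpp(as.numeric(voxelData(ref)), as.numeric(voxelData(warped)),
                as.integer(bins))$nmi
}

#' Bending energy of an FFD transform
#'
#' Mean, over a dense sampling of the reference grid, of the sum of squared
#' second spatial derivatives of the displacement field (mixed terms
#' doubled). Derivatives are taken with respect to the control-grid index
#' and displacements measured in millimetres, the convention under which the
#' usual penalty weights (e.g. 0.95) are quoted. Zero exactly when the
#' displacement is globally affine over the sampled region.
#'
#' @param t an [FFDTransform-class].
#' @param stride sampling stride in voxels (1 = every reference voxel).
#' @return Non-negative scalar.
#' @export
bendingEnergy <- function(t, stride = 1L) {
    stopifnot(is(t, "FFDTransform"))
    .bendingEnergyCpp(ffdGridList(t), t@coefficients, t@refDim, t@refSpacing,
                      t@refOrigin, as.integer(stride), FALSE)$value
}

#' Jacobian-determinant diagnostics of a deformation
#'
#' Determinant of the spatial Jacobian of \code{T(x) = A x + D(x)} sampled
#' on the reference grid; negative values indicate folding.
#'
#' @param t an [FFDTransform-class].
#' @param stride sampling stride in voxels.
#' @return \code{jacobianDeterminants}: vector of determinants.
#' @export
jacobianDeterminants <- function(t, stride = 1L) {
    stopifnot(is(t, "FFDTransform"))
    .jacobianDetCpp(t@affine@matrix, ffdGridList(t), t@coefficients,
                    t@refDim, t@refSpacing, t@refOrigin, as.integer(stride))
}

#' @rdname jacobianDeterminants
#' @return \code{negJacobianFraction}: fraction of sampled voxels with a
#'   negative determinant.
#' @export
negJacobianFraction <- function(t, stride = 1L) {
    d <- jacobianDeterminants(t, stride)
    mean(d < 0)
}

# effective histogram bins for a level: keep the joint histogram populated
.effectiveBins <- function(nvox, requested) {
    b <- 2 ^ floor(log2(nvox^(1 / 3)))
    as.integer(max(16, min(requested, b)))
}

# dyadic refinement of cubic B-spline coefficients when the knot spacing
# halves (tensor product of the 1D subdivision masks 1/8(1,6,1) / 1/2(1,1));
# both lattices are anchored two knots before the shared reference origin.
.subdivideAxis <- function(co, axis, nNew) {
    d <- dim(co)
    nOld <- d[axis]
    idxNew <- seq_len(nNew) - 1L
    even <- idxNew %% 2L == 0L
    iC <- ifelse(even, (idxNew + 2L) %/% 2L, (idxNew + 1L) %/% 2L)
    clamp <- function(i) pmin(pmax(i, 0L), nOld - 1L) + 1L
    pick <- function(i) {
        idx <- rep(list(quote(expr = )), length(d))
        idx[[axis]] <- clamp(i)
        do.call(`[`, c(list(co), idx, list(drop = FALSE)))
    }
    out <- array(0, replace(d, axis, nNew))
    lo <- pick(iC - 1L); mi <- pick(iC); hi <- pick(iC + 1L)
    wl <- ifelse(even, 1 / 8, 0)
    wm <- ifelse(even, 6 / 8, 1 / 2)
    wh <- ifelse(even, 1 / 8, 1 / 2)
    dimw <- rep(1L, length(d)); dimw[axis] <- nNew
    wshape <- function(w) array(rep(w, each = prod(d[seq_len(axis - 1)])),
                                replace(d, axis, nNew))
    # broadcast weights along the subdivided axis
    out <- wshape(wl) * lo + wshape(wm) * mi + wshape(wh) * hi
    out
}

.subdivideCoefficients <- function(co, nNewKnots) {
    for (axis in 1:3) co <- .subdivideAxis(co, axis, nNewKnots[axis])
    co
}

# warp floating volume through affine+FFD onto the reference grid
.warpVolume <- function(flt, affine, grid, coef, ref, interp = 1L) {
    BrainVolume(.resampleCpp(voxelData(flt), dim(flt), spacing(flt),
                             origin(flt), dim(ref), spacing(ref), origin(ref),
                             affine, grid, coef, interp, 0),
                spacing(ref), origin(ref))
}

#' Free-form registration of a floating volume to a reference
#'
#' Maximizes \code{(1 - w) NMI - w BE} over the control-point displacements
#' of a cubic B-spline lattice by conjugate-gradient ascent with a
#' backtracking line search, over a coarse-to-fine pyramid. The initial
#' affine is fixed throughout; the returned transform maps reference world
#' coordinates to floating world coordinates. Deterministic given inputs and
#' parameters.
#'
#' The result carries an attribute \code{"history"}: one entry per optimized
#' level with the objective trace (non-decreasing by construction), NMI and
#' bending-energy values, and the level geometry.
#'
#' @param ref reference [BrainVolume-class] (the sample).
#' @param flt floating [BrainVolume-class] (the atlas average).
#' @param init initial [AffineTransform3D-class].
#' @param params an [ffdParams()] list.
#' @param verbose print per-level progress.
#' @return An [FFDTransform-class] on the full-resolution reference grid.
#' @export
registerFFD <- function(ref, flt, init = affineTransform(),
                        params = ffdParams(), verbose = FALSE) {
    stopifnot(is(ref, "BrainVolume"), is(flt, "BrainVolume"))
    if (stats::var(as.numeric(voxelData(ref))) == 0 ||
        stats::var(as.numeric(voxelData(flt))) == 0)
        stop("volumes must be non-constant for intensity-based registration")
    sched <- pyramidSchedule(dim(ref), params$nLevels, params$nLevelsComputed,
                             params$minLevelDim)
    history <- list()
    ffd <- NULL
    for (li in seq_len(nrow(sched))) {
        f <- sched$factor[li]
        refL <- smoothVolume(downsampleVolume(ref, f), params$inputSmoothSigmaVox)
        if (!sched$computed[li]) {
            # carry: refine the lattice onto this level's grid without
            # further optimization
            ffd <- .regridFFD(ffd, refL, params$gridSpacingVox, init)
            next
        }
        fltL <- smoothVolume(downsampleVolume(flt, f), params$inputSmoothSigmaVox)
        ffd <- .regridFFD(ffd, refL, params$gridSpacingVox, init)
        opt <- .optimizeFFDLevel(refL, fltL, ffd, params, verbose,
                                 level = sum(sched$computed[seq_len(li)]))
        ffd <- opt$ffd
        history[[length(history) + 1L]] <-
            c(list(factor = f, dim = dim(refL)), opt[c("objective", "nmi",
              "be", "iterations", "bins")])
    }
    attr(ffd, "history") <- history
    ffd
}

# build (or refine) the control lattice for a level's reference grid
.regridFFD <- function(ffd, refL, gridSpacingVox, init) {
    h <- gridSpacingVox * spacing(refL)
    g <- makeFFDGrid(dim(refL), spacing(refL), origin(refL), h)
    if (is.null(ffd)) {
        co <- array(0, c(g$nknots, 3L))
    } else {
        ratio <- ffd@gridSpacing[1] / h[1]
        if (abs(ratio - 2) < 1e-9) {
            co <- .subdivideCoefficients(ffd@coefficients, g$nknots)
        } else if (abs(ratio - 1) < 1e-9 &&
                   identical(dim(ffd@coefficients)[1:3], g$nknots)) {
            co <- ffd@coefficients
        } else stop("unexpected lattice refinement ratio")
    }
    new("FFDTransform", coefficients = co, gridSpacing = g$spacing,
        gridOrigin = g$origin, refDim = as.integer(dim(refL)),
        refSpacing = spacing(refL), refOrigin = origin(refL), affine = init)
}

.ffdObjectiveValue <- function(refL, fltL, ffd, coef, params, bins) {
    r <- .ffdNmiCpp(as.numeric(voxelData(refL)), dim(refL), spacing(refL),
                    origin(refL), as.numeric(voxelData(fltL)), dim(fltL),
                    spacing(fltL), origin(fltL), ffd@affine@matrix,
                    ffdGridList(ffd), coef, bins, FALSE, NULL, NULL, NULL)
    be <- .bendingEnergyCpp(ffdGridList(ffd), coef, ffd@refDim,
                            ffd@refSpacing, ffd@refOrigin,
                            as.integer(params$beStride), FALSE)$value
    w <- params$beWeight
    list(J = (1 - w) * r$nmi - w * be, nmi = r$nmi, be = be)
}

.optimizeFFDLevel <- function(refL, fltL, ffd, params, verbose, level) {
    bins <- .effectiveBins(prod(dim(refL)), params$nmiBins)
    garr <- volumeGradient(voxelData(fltL), spacing(fltL))
    grid <- ffdGridList(ffd)
    nk <- grid$nknots
    w <- params$beWeight
    coef <- ffd@coefficients
    gradient <- function(coef) {
        r <- .ffdNmiCpp(as.numeric(voxelData(refL)), dim(refL), spacing(refL),
                        origin(refL), as.numeric(voxelData(fltL)), dim(fltL),
                        spacing(fltL), origin(fltL), ffd@affine@matrix, grid,
                        coef, bins, TRUE, garr$x, garr$y, garr$z)
        be <- .bendingEnergyCpp(grid, coef, ffd@refDim, ffd@refSpacing,
                                ffd@refOrigin, as.integer(params$beStride),
                                TRUE)
        g <- (1 - w) * r$grad - w * be$grad
        if (params$gradientSmoothKnots > 0)
            for (m in 1:3)
                g[, , , m] <- .gaussianSmoothCpp(array(g[, , , m], nk), nk,
                                  rep(params$gradientSmoothKnots, 3))
        list(J = (1 - w) * r$nmi - w * be$value, nmi = r$nmi, be = be$value,
             grad = g)
    }
    value <- function(coef) .ffdObjectiveValue(refL, fltL, ffd, coef, params,
                                               bins)$J
    h <- ffd@gridSpacing[1]
    maxStep <- h / 2
    step <- h / 4
    minStep <- h * 1e-3
    cur <- gradient(coef)
    if (!is.finite(cur$J))
        stop(sprintf("non-finite objective at level %d, iteration 0", level))
    trace <- cur$J
    dirPrev <- NULL
    gPrev <- NULL
    iter <- 0L
    while (iter < params$maxIterPerLevel) {
        iter <- iter + 1L
        g <- cur$grad
        if (is.null(dirPrev)) {
            d <- g
        } else {
            beta <- sum(g * (g - gPrev)) / max(sum(gPrev * gPrev), 1e-30)
            beta <- max(0, beta)  # Polak-Ribiere+
            d <- g + beta * dirPrev
            if (sum(d * g) <= 0) d <- g  # reset on non-ascent direction
        }
        dmax <- max(abs(d))
        if (dmax == 0) break
        dhat <- d / dmax
        improved <- FALSE
        s <- min(step, maxStep)
        while (s >= minStep) {
            cand <- coef + s * dhat
            Jc <- value(cand)
            if (is.finite(Jc) && Jc > cur$J) { improved <- TRUE; break }
            s <- s / 2
        }
        if (!improved) break
        coef <- cand
        gPrev <- g
        dirPrev <- d
        step <- min(s * 2, maxStep)
        prevJ <- cur$J
        cur <- gradient(coef)
        if (!is.finite(cur$J))
            stop(sprintf("non-finite objective at level %d, iteration %d",
                         level, iter))
        # keep the trace monotone in the reported (accepted) objective
        trace <- c(trace, cur$J)
        if (verbose)
            message(sprintf("  level %d iter %3d: J=%.6f NMI=%.5f BE=%.3g step=%.3g",
                            level, iter, cur$J, cur$nmi, cur$be, s))
        if (abs(cur$J - prevJ) < params$convergenceTol * max(abs(prevJ), 1e-12))
            break
    }
    ffd@coefficients <- coef
    list(ffd = ffd, objective = trace, nmi = cur$nmi, be = cur$be,
         iterations = iter, bins = bins)
}
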