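# Geometry helpers shared across modules. Voxel indices are 1-based in R;
# world = origin + (index - 1) * spacing refers to voxel centres.

#' Voxel-to-world and world-to-voxel coordinate mapping
#'
#' @param v a [BrainVolume-class] or [LabelVolume-class].
#' @param idx matrix of 1-based voxel indices (n x 3).
#' @return \code{voxelToWorld}: n x 3 matrix of world coordinates (um).
#' @export
voxelToWorld <- function(v, idx) {
    idx <- rbind(idx)
    sweep(sweep(idx - 1, 2, spacing(v), "*"), 2, origin(v), "+")
}

#' @rdname voxelToWorld
#' @param world matrix of world coordinates (n x 3, um).
#' @return \code{worldToVoxel}: n x 3 matrix of (fractional) 1-based indices.
#' @export
worldToVoxel <- function(v, world) {
    world <- rbind(world)
    sweep(sweep(world, 2, origin(v), "-"), 2, spacing(v), "/") + 1
}

# world coordinates of the 8 corners of a volume's grid
volumeCorners <- function(d, spc, org) {
    g <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
    sweep(sweep(g, 2, spc, "*"), 2, org, "+")
}

#' Invert and compose affine transforms
#'
#' \code{composeAffine(a, b)} returns the transform applying \code{b} first,
#' then \code{a} (i.e. \code{a(b(x))}).
#'
#' @param a,b [AffineTransform3D-class] objects.
#' @return An \linkS4class{AffineTransform3D}.
#' @export
invertAffine <- function(a) affineTransform(solve(a@matrix))

#' @rdname invertAffine
#' @export
composeAffine <- function(a, b) affineTransform(a@matrix %*% b@matrix)

# Apply a 4x4 to an n x 3 matrix of points
applyAffineToPoints <- function(m, pts) {
    pts <- rbind(pts)
    t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
}

# --- FFD control lattice -----------------------------------------------------

# Lattice anchored two knots before the reference origin so every reference
# position has a full 4-knot support without clamping.
makeFFDGrid <- function(refDim, refSpacing, refOrigin, knotSpacing) {
    if (length(knotSpacing) == 1L) knotSpacing <- rep(knotSpacing, 3L)
    extent <- (refDim - 1) * refSpacing
    nknots <- as.integer(floor(extent / knotSpacing) + 6)
    list(nknots = nknots, spacing = as.numeric(knotSpacing),
         origin = as.numeric(refOrigin - 2 * knotSpacing))
}

#' Create an identity (zero-displacement) FFD transform
#'
#' @param reference a [BrainVolume-class] defining the reference grid.
#' @param knotSpacing control-point spacing in micrometres (scalar or 3).
#' @param affine initial affine, identity by default.
#' @return An \linkS4class{FFDTransform} with zero displacements.
#' @export
identityFFD <- function(reference, knotSpacing, affine = affineTransform()) {
    d <- dim(reference)
    g <- makeFFDGrid(d, spacing(reference), origin(reference), knotSpacing)
    new("FFDTransform",
        coefficients = array(0, c(g$nknots, 3L)),
        gridSpacing = g$spacing, gridOrigin = g$origin,
        refDim = as.integer(d), refSpacing = spacing(reference),
        refOrigin = origin(reference), affine = affine)
}

ffdGridList <- function(t) {
    list(nknots = as.integer(dim(t@coefficients)[1:3]),
         spacing = t@gridSpacing, origin = t@gridOrigin)
}

# Central-difference gradient of a volume, per micrometre, one array per axis.
volumeGradient <- function(arr, spc) {
    d <- dim(arr)
    g <- vector("list", 3L)
    for (a in 1:3) {
        hi <- c(2:d[a], d[a])
        lo <- c(1, 1:(d[a] - 1))
        idx_hi <- switch(a, list(hi, TRUE, TRUE), list(TRUE, hi, TRUE),
                         list(TRUE, TRUE, hi))
        idx_lo <- switch(a, list(lo, TRUE, TRUE), list(TRUE, lo, TRUE),
                         list(TRUE, TRUE, lo))
        gr <- (do.call(`[`, c(list(arr), idx_hi)) -
               do.call(`[`, c(list(arr), idx_lo)))
        # boundary rows use one-sided differences over a single step
        step <- rep(2, d[a]); step[1] <- 1; step[d[a]] <- 1
        gr <- sweep(array(gr, d), a, step * spc[a], "/")
        g[[a]] <- gr
    }
    names(g) <- c("x", "y", "z")
    g
}

# Multi-resolution pyramid schedule. Levels whose downsampled minimum
# dimension would fall below `minDim` are dropped; the `nComputed` coarsest
# surviving levels are optimized, the rest only carry the transform.
pyramidSchedule <- function(d, nLevels, nComputed, minDim = 16L) {
    factors <- 2 ^ ((nLevels - 1):0)
    keep <- vapply(factors, function(f) f == 1 || min(ceiling(d / f)) >= minDim,
                   logical(1))
    factors <- factors[keep]
    computed <- seq_along(factors) <= nComputed
    data.frame(factor = factors, computed = computed)
}

# Downsample a volume by an integer factor with Gaussian anti-aliasing
# (sigma = 0.4 * factor source voxels), trilinear resampling.
downsampleVolume <- function(v, factor) {
    if (factor <= 1) return(v)
    arr <- .gaussianSmoothCpp(voxelData(v), dim(v), rep(0.4 * factor, 3))
    sm <- BrainVolume(arr, spacing(v), origin(v))
    resampleToGrid(sm, spacing(v) * factor)
}

# Resample onto a new grid with the same origin and world extent.
resampleToGrid <- function(v, newSpacing, interp = 1L) {
    d <- dim(v)
    extent <- (d - 1) * spacing(v)
    nd <- as.integer(floor(extent / newSpacing + 1e-6) + 1)
    arr <- .resampleCpp(voxelData(v), dim(v), spacing(v), origin(v),
                        nd, newSpacing, origin(v), diag(4),
                        NULL, NULL, as.integer(interp), 0)
    BrainVolume(arr, newSpacing, origin(v))
}
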