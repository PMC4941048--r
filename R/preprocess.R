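#' Anisotropic z-smoothing
#'
#' Gaussian smoothing along the z (anterior-posterior) axis only, with the
#' kernel width given in voxels. This is the standard pre-step before
#' isotropic downsampling of serial-section stacks whose z sampling is much
#' coarser than the in-plane resolution; the default pipeline uses a 5-voxel
#' standard deviation. Boundary handling is half-sample reflection, which
#' avoids edge dimming at the brain boundary.
#'
#' @param v a [BrainVolume-class].
#' @param sigmaVox kernel standard deviation in voxels (>= 0; 0 returns the
#'   input unchanged).
#' @return A smoothed [BrainVolume-class] with unchanged shape and spacing.
#' @export
smoothZ <- function(v, sigmaVox) {
    stopifnot(is(v, "BrainVolume"))
    if (sigmaVox < 0) stop("sigmaVox must be non-negative")
    if (sigmaVox == 0) return(v)
    arr <- .gaussianSmoothCpp(voxelData(v), dim(v), c(0, 0, sigmaVox))
    BrainVolume(arr, spacing(v), origin(v))
}

# Isotropic Gaussian smoothing, sigma in voxels (internal).
smoothVolume <- function(v, sigmaVox) {
    if (all(sigmaVox <= 0)) return(v)
    if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
    BrainVolume(.gaussianSmoothCpp(voxelData(v), dim(v), sigmaVox),
                spacing(v), origin(v))
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear resampling onto an isotropic grid of the requested spacing that
#' covers the same world extent and shares the origin. When downsampling by a
#' factor larger than one, an anti-aliasing Gaussian of
#' \code{0.4 * target/source} voxels is applied per axis first; upsampling is
#' allowed but warned about.
#'
#' @param v a [BrainVolume-class].
#' @param targetUm target isotropic voxel size in micrometres (default 12.5).
#' @return A resampled [BrainVolume-class].
#' @export
resampleIsotropic <- function(v, targetUm = 12.5) {
    stopifnot(is(v, "BrainVolume"), targetUm > 0)
    if (any(targetUm < spacing(v)))
        warning("target spacing finer than source: upsampling")
    sig <- pmax(0, 0.4 * (targetUm / spacing(v)) * (targetUm > spacing(v)))
    arr <- voxelData(v)
    if (any(sig > 0)) arr <- .gaussianSmoothCpp(arr, dim(v), sig)
    sm <- BrainVolume(arr, spacing(v), origin(v))
    resampleToGrid(sm, rep(targetUm, 3L))
}

#' Resample a volume through an affine transform
#'
#' Pull-back resampling of \code{v} onto the grid of \code{reference}:
#' \code{out(i) = v(t(world(i)))}. Out-of-field voxels take the pad value 0
#' (the dark background of fluorescence data).
#'
#' @param v the floating [BrainVolume-class] to be resampled.
#' @param t an [AffineTransform3D-class] mapping reference world coordinates
#'   to \code{v}'s world coordinates.
#' @param reference a [BrainVolume-class] whose grid defines the output.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return A [BrainVolume-class] on the reference grid.
#' @export
applyTransform <- function(v, t, reference, interp = c("linear", "nearest")) {
    stopifnot(is(v, "BrainVolume"), is(t, "AffineTransform3D"))
    interp <- match.arg(interp)
    validObject(t)
    arr <- .resampleCpp(voxelData(v), dim(v), spacing(v), origin(v),
                        dim(reference), spacing(reference), origin(reference),
                        t@matrix, NULL, NULL,
                        if (interp == "nearest") 0L else 1L, 0)
    BrainVolume(arr, spacing(reference), origin(reference))
}
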