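#' Accessors for volumetric and mask objects
#'
#' \code{spacing} and \code{origin} return the physical geometry in
#' micrometres; \code{voxelData} the intensity array of a
#' \linkS4class{BrainVolume}; \code{labelData} and \code{labelTable} the
#' integer array and id table of a \linkS4class{LabelVolume};
#' \code{pixels}, \code{pixelSize} and \code{zIndex} the contents of a
#' \linkS4class{Mask2D}; \code{affineMatrix} the 4x4 matrix of an
#' \linkS4class{AffineTransform3D} (or the initial affine of an
#' \linkS4class{FFDTransform}); \code{landmarks} the point table of a
#' \linkS4class{LandmarkSet}.
#'
#' @param x an atlasmap object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases spacing origin voxelData labelData labelTable pixels pixelSize
#'   zIndex affineMatrix landmarks
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("zIndex", function(x) standardGeneric("zIndex"))
#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @rdname accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setMethod("spacing", "BrainVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("origin", "BrainVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelTable", "LabelVolume", function(x) x@labelTable)
#' @rdname accessors
#' @export
setMethod("pixels", "Mask2D", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "RaterSegmentation", function(x) x@mask@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Mask2D", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("zIndex", "Mask2D", function(x) x@zIndex)
#' @rdname accessors
#' @export
setMethod("zIndex", "RaterSegmentation", function(x) x@mask@zIndex)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "AffineTransform3D", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "FFDTransform", function(x) x@affine@matrix)
#' @rdname accessors
#' @export
setMethod("landmarks", "LandmarkSet", function(x) x@points)

#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@voxels))
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))
#' @export
setMethod("dim", "Mask2D", function(x) dim(x@pixels))

setMethod("show", "BrainVolume", function(object) {
    cat(sprintf("BrainVolume: %s voxels, spacing (%s) um, origin (%s) um\n",
        paste(dim(object@voxels), collapse = " x "),
        paste(format(object@spacing), collapse = ", "),
        paste(format(object@origin), collapse = ", ")))
    rng <- range(object@voxels)
    cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "LabelVolume", function(object) {
    cat(sprintf("LabelVolume: %s voxels, %d structures, spacing (%s) um\n",
        paste(dim(object@labels), collapse = " x "),
        nrow(object@labelTable),
        paste(format(object@spacing), collapse = ", ")))
    if (nrow(object@labelTable))
        cat("  ", paste(sprintf("%d=%s", object@labelTable$id,
            object@labelTable$acronym), collapse = ", "), "\n")
})

setMethod("show", "AffineTransform3D", function(object) {
    cat("AffineTransform3D (reference world um -> floating world um):\n")
    print(round(object@matrix, 6))
})

setMethod("show", "FFDTransform", function(object) {
    d <- dim(object@coefficients)
    mx <- max(abs(object@coefficients))
    cat(sprintf(
        "FFDTransform: %d x %d x %d control lattice, spacing (%s) um, max |d| = %.3g um\n",
        d[1], d[2], d[3],
        paste(format(object@gridSpacing), collapse = ", "), mx))
})

setMethod("show", "Mask2D", function(object) {
    cat(sprintf("Mask2D: %d x %d px at %.3g um/px, z = %d, %d foreground px%s\n",
        nrow(object@pixels), ncol(object@pixels), object@pixelSize,
        object@zIndex, sum(object@pixels),
        if (object@empty) " (flagged empty)" else ""))
})

setMethod("show", "RaterSegmentation", function(object) {
    cat(sprintf(
        "RaterSegmentation: rater %s, brain %s, structure %s, attempt %d, z = %d\n",
        object@raterId, object@brainId, object@structure, object@attempt,
        object@mask@zIndex))
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf(
        "ConsensusResult: %d x %d px, %d raters, %d EM iterations (%sconverged)\n",
        nrow(object@probabilityMap), ncol(object@probabilityMap),
        length(object@sensitivity), object@nIterations,
        if (object@converged) "" else "not "))
    cat(sprintf("  sensitivity %.3f-%.3f, specificity %.3f-%.3f, prior %.3f\n",
        min(object@sensitivity), max(object@sensitivity),
        min(object@specificity), max(object@specificity), object@prior))
})
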