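#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib atlasmap, .registration = TRUE
NULL

#' 3D scalar volume with physical geometry
#'
#' The unit of registration: a 3D grid of scalar intensities together with its
#' physical voxel spacing and world origin, both in micrometres. The axis
#' convention is fixed: x runs medio-lateral, y dorso-ventral and z
#' anterior-posterior, so a coronal plane is a fixed-z slice. World
#' coordinates refer to voxel centres, \code{world = origin + (index-1) *
#' spacing} for 1-based indices.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size in micrometres per axis, all > 0.
#' @slot origin numeric(3), world position (um) of voxel (1,1,1).
#' @export
setClass("BrainVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"),
    prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("BrainVolume", function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
        msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be three finite values")
    if (any(!is.finite(object@voxels)))
        msg <- c(msg, "voxels must be finite everywhere")
    if (is.null(msg)) TRUE else msg
})

#' Integer-labelled volume with a label table
#'
#' Anatomical annotation on a voxel grid: non-negative integer ids with 0
#' reserved for background, plus a table mapping each id to a structure
#' acronym. Shares the geometry conventions of [BrainVolume-class].
#'
#' @slot labels 3D integer array; 0 is background.
#' @slot spacing,origin as in [BrainVolume-class].
#' @slot labelTable data.frame with columns \code{id}, \code{acronym}.
#' @export
setClass("LabelVolume",
    representation(labels = "array", spacing = "numeric", origin = "numeric",
                   labelTable = "data.frame"),
    prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
              labelTable = data.frame(id = integer(), acronym = character())))

setValidity("LabelVolume", function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "labels must be a 3D array")
    if (any(object@labels < 0))
        msg <- c(msg, "label ids must be non-negative (0 = background)")
    if (!all(c("id", "acronym") %in% names(object@labelTable)))
        msg <- c(msg, "labelTable needs columns 'id' and 'acronym'")
    ids <- setdiff(unique(as.integer(object@labels)), 0L)
    if (!all(ids %in% object@labelTable$id))
        msg <- c(msg, sprintf("label ids missing from labelTable: %s",
                 paste(setdiff(ids, object@labelTable$id), collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' 3D affine transform in world coordinates
#'
#' A 4x4 homogeneous matrix mapping reference-space world coordinates (um) to
#' floating-space world coordinates (um).
#'
#' @slot matrix 4x4 numeric matrix; last row (0,0,0,1), invertible 3x3 block.
#' @export
setClass("AffineTransform3D", representation(matrix = "matrix"),
         prototype(matrix = diag(4)))

setValidity("AffineTransform3D", function(object) {
    m <- object@matrix
    msg <- NULL
    if (!all(dim(m) == c(4, 4)) || any(!is.finite(m)))
        msg <- c(msg, "matrix must be a finite 4x4 matrix")
    else {
        if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-10)
            msg <- c(msg, "last row must be (0, 0, 0, 1)")
        if (abs(det(m[1:3, 1:3])) < 1e-12)
            msg <- c(msg, "linear 3x3 block must be invertible")
    }
    if (is.null(msg)) TRUE else msg
})

#' Free-form deformation transform
#'
#' A cubic B-spline displacement field on a regular control-point lattice,
#' composed over an initial affine: \code{T(x) = A x + D(x)} where \code{D} is
#' the tensor-product cubic B-spline interpolation of the control
#' displacements. The lattice covers the reference extent plus at least a
#' one-knot margin on every side; queries beyond the lattice use the clamped
#' border cells.
#'
#' @slot coefficients 4D numeric array (nx, ny, nz, 3) of control-point
#'   displacements in micrometres.
#' @slot gridSpacing numeric(3), knot spacing in micrometres.
#' @slot gridOrigin numeric(3), world position of knot (1,1,1).
#' @slot refDim integer(3); @slot refSpacing,refOrigin geometry of the
#'   reference grid the transform is defined on.
#' @slot affine the initial [AffineTransform3D-class].
#' @export
setClass("FFDTransform",
    representation(coefficients = "array", gridSpacing = "numeric",
                   gridOrigin = "numeric", refDim = "integer",
                   refSpacing = "numeric", refOrigin = "numeric",
                   affine = "AffineTransform3D"))

setValidity("FFDTransform", function(object) {
    msg <- NULL
    d <- dim(object@coefficients)
    if (length(d) != 4L || d[4] != 3L)
        msg <- c(msg, "coefficients must be an (nx, ny, nz, 3) array")
    if (any(!is.finite(object@coefficients)))
        msg <- c(msg, "control displacements must be finite")
    if (any(object@gridSpacing <= 0))
        msg <- c(msg, "gridSpacing must be positive")
    if (is.null(msg)) {
        # one-knot margin: first interior support must start at or before the
        # reference origin, last must end at or after the reference extent
        lo <- object@gridOrigin + object@gridSpacing
        hi <- object@gridOrigin + (d[1:3] - 2) * object@gridSpacing
        ext <- object@refOrigin + (object@refDim - 1) * object@refSpacing
        if (any(lo > object@refOrigin + 1e-6) || any(hi < ext - 1e-6))
            msg <- c(msg, "control lattice must cover the reference extent plus a one-knot margin")
    }
    if (is.null(msg)) TRUE else msg
})

#' 2D binary mask with pixel geometry
#'
#' A single-plane binary segmentation: pixels indexed (x, y), an isotropic
#' in-plane pixel size in micrometres and the 1-based z index of the section
#' it was drawn on. An all-background mask must be explicitly flagged empty;
#' the constructor [Mask2D()] does this automatically.
#'
#' @slot pixels logical matrix, first index x.
#' @slot pixelSize positive scalar, um per pixel.
#' @slot zIndex integer, 1-based section index within its stack.
#' @slot empty logical flag for masks with no foreground.
#' @export
setClass("Mask2D",
    representation(pixels = "matrix", pixelSize = "numeric",
                   zIndex = "integer", empty = "logical"),
    prototype(pixelSize = 1, zIndex = 1L, empty = FALSE))

setValidity("Mask2D", function(object) {
    msg <- NULL
    if (!is.logical(object@pixels))
        msg <- c(msg, "pixels must be a logical matrix")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a positive scalar")
    if (!object@empty && !any(object@pixels))
        msg <- c(msg, "mask has no foreground but is not flagged empty")
    if (is.null(msg)) TRUE else msg
})

#' Named anatomical landmarks in world coordinates
#'
#' @slot points data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z}; names unique, coordinates finite, in micrometres.
#' @export
setClass("LandmarkSet", representation(points = "data.frame"),
         prototype(points = data.frame(name = character(), x = numeric(),
                                       y = numeric(), z = numeric())))

setValidity("LandmarkSet", function(object) {
    p <- object@points
    msg <- NULL
    if (!all(c("name", "x", "y", "z") %in% names(p)))
        msg <- c(msg, "points needs columns name, x, y, z")
    else {
        if (anyDuplicated(p$name))
            msg <- c(msg, "landmark names must be unique")
        if (any(!is.finite(as.matrix(p[, c("x", "y", "z")]))))
            msg <- c(msg, "landmark coordinates must be finite")
    }
    if (is.null(msg)) TRUE else msg
})

#' One manual segmentation by one rater
#'
#' The unit of manual scoring: a 2D mask plus the identity of the rater,
#' brain, target structure and attempt (1 or 2), and the z section the rater
#' chose. The tuple (rater, brain, structure, attempt) is unique within a
#' panel.
#'
#' @slot mask a [Mask2D-class].
#' @slot raterId,brainId,structure character identifiers.
#' @slot attempt integer, 1 or 2.
#' @export
setClass("RaterSegmentation",
    representation(mask = "Mask2D", raterId = "character",
                   brainId = "character", structure = "character",
                   attempt = "integer"),
    prototype(attempt = 1L))

setValidity("RaterSegmentation", function(object) {
    if (!object@attempt %in% c(1L, 2L)) "attempt must be 1 or 2" else TRUE
})

#' STAPLE consensus estimate
#'
#' Result of the STAPLE EM algorithm: the per-pixel posterior probability of
#' foreground, the thresholded consensus mask (posterior >= 0.5, ties to
#' foreground), the estimated per-rater sensitivity p and specificity q, the
#' foreground prior, and the EM trace.
#'
#' @slot probabilityMap numeric matrix of posteriors in [0, 1].
#' @slot consensusMask [Mask2D-class], \code{probabilityMap >= 0.5}.
#' @slot sensitivity,specificity named numeric, one entry per rater.
#' @slot prior scalar foreground prior gamma.
#' @slot nIterations integer; @slot converged logical.
#' @slot logLik numeric, complete-data log-likelihood per EM iteration.
#' @export
setClass("ConsensusResult",
    representation(probabilityMap = "matrix", consensusMask = "Mask2D",
                   sensitivity = "numeric", specificity = "numeric",
                   prior = "numeric", nIterations = "integer",
                   converged = "logical", logLik = "numeric"))

setValidity("ConsensusResult", function(object) {
    msg <- NULL
    if (any(object@probabilityMap < -1e-12 | object@probabilityMap > 1 + 1e-12))
        msg <- c(msg, "posteriors must lie in [0, 1]")
    if (!identical(dim(object@probabilityMap), dim(object@consensusMask@pixels)))
        msg <- c(msg, "probability map and consensus mask shapes differ")
    if (is.null(msg)) TRUE else msg
})
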