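#' Construct a BrainVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel size in micrometres, length 1 (isotropic) or 3.
#' @param origin world position (um) of the first voxel centre.
#' @return A \linkS4class{BrainVolume}.
#' @examples
#' v <- BrainVolume(array(rnorm(8^3), c(8, 8, 8)), spacing = 12.5)
#' spacing(v)
#' @export
BrainVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(voxels) <- "double"
    new("BrainVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' If no label table is given, one is generated with acronyms \code{S<id>}.
#'
#' @param labels 3D array of non-negative integer ids (0 = background).
#' @param spacing,origin geometry as in [BrainVolume()].
#' @param labelTable data.frame with columns \code{id}, \code{acronym}.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        labelTable = NULL) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(labels) <- "integer"
    if (is.null(labelTable)) {
        ids <- setdiff(sort(unique(as.integer(labels))), 0L)
        labelTable <- data.frame(id = ids, acronym = sprintf("S%d", ids))
    }
    new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin), labelTable = labelTable)
}

#' Construct an affine transform
#'
#' @param matrix a 4x4 homogeneous matrix (world um to world um).
#' @return An \linkS4class{AffineTransform3D}.
#' @export
affineTransform <- function(matrix = diag(4)) {
    new("AffineTransform3D", matrix = unname(as.matrix(matrix)))
}

#' Build a 4x4 affine from rotation, scale and translation
#'
#' Parameterized affine used by the phantom generator and the recovery
#' experiments: rotations (degrees, applied x then y then z), per-axis or
#' global scale, and a translation in micrometres, all about a given centre.
#'
#' @param rotation numeric(3), degrees about the x, y, z axes.
#' @param scale scalar or numeric(3).
#' @param translation numeric(3), micrometres.
#' @param center numeric(3), rotation/scaling centre in world um.
#' @return An \linkS4class{AffineTransform3D}.
#' @export
makeAffine <- function(rotation = c(0, 0, 0), scale = 1,
                       translation = c(0, 0, 0), center = c(0, 0, 0)) {
    r <- rotation * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
    Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
    Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
    if (length(scale) == 1L) scale <- rep(scale, 3L)
    L <- Rz %*% Ry %*% Rx %*% diag(scale)
    m <- diag(4)
    m[1:3, 1:3] <- L
    m[1:3, 4] <- translation + center - L %*% center
    affineTransform(m)
}

#' Construct a 2D mask
#'
#' Non-logical input is thresholded at > 0. A mask without foreground is
#' flagged empty automatically.
#'
#' @param pixels matrix, first index x.
#' @param pixelSize isotropic pixel size in micrometres.
#' @param zIndex 1-based section index.
#' @return A \linkS4class{Mask2D}.
#' @export
Mask2D <- function(pixels, pixelSize = 1, zIndex = 1L) {
    if (!is.logical(pixels)) pixels <- pixels > 0
    new("Mask2D", pixels = pixels, pixelSize = as.numeric(pixelSize),
        zIndex = as.integer(zIndex), empty = !any(pixels))
}

#' Construct a landmark set
#'
#' @param points data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z} (world um).
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(points) {
    points$name <- as.character(points$name)
    new("LandmarkSet", points = points[, c("name", "x", "y", "z")])
}

#' Construct a rater segmentation record
#'
#' @param mask a [Mask2D-class].
#' @param raterId,brainId,structure identifiers.
#' @param attempt 1 or 2.
#' @return A \linkS4class{RaterSegmentation}.
#' @export
RaterSegmentation <- function(mask, raterId, brainId, structure, attempt = 1L) {
    new("RaterSegmentation", mask = mask, raterId = as.character(raterId),
        brainId = as.character(brainId), structure = as.character(structure),
        attempt = as.integer(attempt))
}
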