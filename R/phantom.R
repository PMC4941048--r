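# Synthetic phantom brains: structured intensity volumes with exact label
# rasterization, analytic landmarks, known ground-truth deformations and
# simulated rater panels. These stand in for serial-section fluorescence
# stacks and the annotated average-brain atlas so that every pipeline stage
# can be exercised and scored against a known truth.

#' Specify a phantom brain
#'
#' The default phantom is a 64^3 volume at 12.5 um isotropic spacing holding
#' five parametric structures of graded size: an ellipsoidal "cortex" shell
#' and four nuclei (ellipsoids/spheres), mimicking a target set spanning a
#' broad range of sizes and difficulty. Later structures overwrite earlier
#' ones where solids touch. Intensities are per-structure offsets over a
#' bright brain interior, softened by a 1-voxel Gaussian (partial-volume
#' edges), plus a low-frequency bias field and i.i.d. Gaussian noise.
#'
#' @param shape integer(3) voxel grid shape.
#' @param spacingUm isotropic voxel size, micrometres.
#' @param structures list of solids; each a list with \code{id},
#'   \code{acronym}, \code{type} ("ellipsoid" or "shell"), \code{center}
#'   (voxel offsets from the volume centre), \code{semi} (semi-axes, voxels;
#'   for shells \code{semi} is the outer and \code{inner} the inner
#'   ellipsoid), and \code{intensity}.
#' @param interiorIntensity intensity of unlabelled brain interior.
#' @param noiseSigma s.d. of additive Gaussian noise (intensity units).
#' @param biasAmplitude amplitude of the smooth additive bias field.
#' @param textureAmplitude s.d. of the smooth anatomical texture field added
#'   inside the brain (a stand-in for vasculature and cytoarchitecture; it
#'   deforms with the anatomy, unlike the acquisition noise).
#' @param textureSigmaVox correlation length of the texture, voxels.
#' @param seed integer seed fixing all randomness.
#' @return A list spec understood by [makePhantom()].
#' @export
phantomSpec <- function(shape = c(64L, 64L, 64L), spacingUm = 12.5,
                        structures = defaultStructures(),
                        interiorIntensity = 100, noiseSigma = 5,
                        biasAmplitude = 15, textureAmplitude = 12,
                        textureSigmaVox = 1.5, seed = 1L) {
    list(shape = as.integer(shape), spacingUm = spacingUm,
         structures = structures, interiorIntensity = interiorIntensity,
         noiseSigma = noiseSigma, biasAmplitude = biasAmplitude,
         textureAmplitude = textureAmplitude,
         textureSigmaVox = textureSigmaVox, seed = as.integer(seed))
}

#' @rdname phantomSpec
#' @export
defaultStructures <- function() {
    list(
        list(id = 1L, acronym = "CTX", type = "shell",
             center = c(0, 0, 0), semi = c(26, 24, 25),
             inner = c(19, 17, 18), intensity = 140),
        list(id = 2L, acronym = "HPC", type = "ellipsoid",
             center = c(0, -5, 3), semi = c(10, 6, 8), intensity = 180),
        list(id = 3L, acronym = "TH", type = "ellipsoid",
             center = c(6, 4, -4), semi = c(7, 7, 7), intensity = 160),
        list(id = 4L, acronym = "VPM", type = "ellipsoid",
             center = c(-8, 4, -2), semi = c(5, 5, 5), intensity = 210),
        list(id = 5L, acronym = "ACA", type = "ellipsoid",
             center = c(0, -10, 9), semi = c(4, 4, 5), intensity = 190))
}

# normalized squared ellipsoid coordinate on the voxel grid
.ellipsoidQ <- function(shape, center, semi) {
    cx <- (shape - 1) / 2 + center
    X <- slice.index(array(0, shape), 1) - 1
    Y <- slice.index(array(0, shape), 2) - 1
    Z <- slice.index(array(0, shape), 3) - 1
    ((X - cx[1]) / semi[1])^2 + ((Y - cx[2]) / semi[2])^2 +
        ((Z - cx[3]) / semi[3])^2
}

#' Generate a phantom brain
#'
#' @param spec a [phantomSpec()].
#' @return A list with elements \code{volume} ([BrainVolume-class]),
#'   \code{labels} ([LabelVolume-class], exact solid rasterization) and
#'   \code{landmarks} ([LandmarkSet-class], analytic points: structure
#'   centroids and poles of the brain ellipsoid).
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(32, 32, 32), seed = 7))
#' ph$volume
#' ph$labels
#' @export
makePhantom <- function(spec) {
    shape <- spec$shape
    shell <- spec$structures[[1]]
    if (!is.null(spec$seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(spec$seed)
    }
    outerQ <- .ellipsoidQ(shape, shell$center, shell$semi)
    labels <- array(0L, shape)
    intens <- array(0, shape)
    intens[outerQ <= 1] <- spec$interiorIntensity
    for (s in spec$structures) {
        if (s$type == "shell") {
            innerQ <- .ellipsoidQ(shape, s$center, s$inner)
            m <- .ellipsoidQ(shape, s$center, s$semi) <= 1 & innerQ > 1
        } else {
            m <- .ellipsoidQ(shape, s$center, s$semi) <= 1
        }
        if (!any(m)) stop(sprintf("structure %s lies outside the volume", s$acronym))
        ctr <- (shape - 1) / 2 + s$center
        if (any(ctr < 0) || any(ctr > shape - 1))
            stop(sprintf("structure %s lies outside the volume", s$acronym))
        labels[m] <- s$id
        intens[m] <- s$intensity
    }
    # anatomical texture: smoothed noise that belongs to the tissue (and so
    # deforms with it), restricted to the brain interior
    if (spec$textureAmplitude > 0) {
        tex <- .gaussianSmoothCpp(array(stats::rnorm(prod(shape)), shape),
                                  shape, rep(spec$textureSigmaVox, 3))
        tex <- tex / stats::sd(tex) * spec$textureAmplitude
        intens[outerQ <= 1] <- intens[outerQ <= 1] + tex[outerQ <= 1]
    }
    # soften intensity edges (partial volume), leave labels exact
    intens <- .gaussianSmoothCpp(intens, shape, rep(1, 3))
    # low-frequency bias field with seeded random phases
    ph <- stats::runif(3, 0, 2 * pi)
    X <- (slice.index(intens, 1) - 1) / (shape[1] - 1)
    Y <- (slice.index(intens, 2) - 1) / (shape[2] - 1)
    Z <- (slice.index(intens, 3) - 1) / (shape[3] - 1)
    bias <- spec$biasAmplitude *
        (sin(2 * pi * 0.7 * X + ph[1]) + sin(2 * pi * 0.9 * Y + ph[2]) +
         sin(2 * pi * 0.8 * Z + ph[3])) / 3
    intens <- intens + bias
    if (spec$noiseSigma > 0)
        intens <- intens + stats::rnorm(length(intens), 0, spec$noiseSigma)
    vol <- BrainVolume(array(intens, shape), spec$spacingUm)
    lt <- data.frame(
        id = vapply(spec$structures, `[[`, integer(1), "id"),
        acronym = vapply(spec$structures, `[[`, character(1), "acronym"))
    lab <- LabelVolume(labels, spec$spacingUm, labelTable = lt)
    list(volume = vol, labels = lab, landmarks = phantomLandmarks(spec))
}

# Analytic landmark list: poles of the brain ellipsoid and nucleus centroids,
# named after the conventional rodent landmark vocabulary.
phantomLandmarks <- function(spec) {
    shape <- spec$shape
    spc <- spec$spacingUm
    shell <- spec$structures[[1]]
    ctr <- ((shape - 1) / 2 + shell$center) * spc
    a <- shell$semi * spc
    vox <- function(off) ((shape - 1) / 2 + off) * spc
    pts <- rbind(
        data.frame(name = "frontal middle",
                   x = ctr[1], y = ctr[2], z = ctr[3] - a[3]),
        data.frame(name = "frontal right",
                   x = ctr[1] + a[1] * sin(pi / 6), y = ctr[2],
                   z = ctr[3] - a[3] * cos(pi / 6)),
        data.frame(name = "frontal left",
                   x = ctr[1] - a[1] * sin(pi / 6), y = ctr[2],
                   z = ctr[3] - a[3] * cos(pi / 6)),
        data.frame(name = "dorsal middle",
                   x = ctr[1], y = ctr[2] - a[2], z = ctr[3]),
        data.frame(name = "ventral middle",
                   x = ctr[1], y = ctr[2] + a[2], z = ctr[3]),
        data.frame(name = "occipital middle",
                   x = ctr[1], y = ctr[2], z = ctr[3] + a[3]))
    cent <- lapply(spec$structures[-1], function(s) {
        p <- vox(s$center)
        data.frame(name = switch(s$acronym,
                       HPC = "hippocampus middle", TH = "thalamus middle",
                       VPM = "ventral nucleus middle",
                       ACA = "cingulate middle",
                       paste(tolower(s$acronym), "middle")),
                   x = p[1], y = p[2], z = p[3])
    })
    LandmarkSet(do.call(rbind, c(list(pts), cent)))
}

#' Generate a phantom pair related by a known affine + FFD deformation
#'
#' Builds a noiseless textured phantom, warps it by a known random smooth
#' free-form deformation composed with a known affine (the true transform
#' maps moving-space world coordinates to fixed-space world coordinates,
#' pull-back convention), carries labels (nearest-neighbour) and landmarks
#' (exact inverse mapping, Newton iteration) and finally adds independent
#' Gaussian noise to the fixed and moving volumes. The true field is
#' fold-free by construction (its minimum Jacobian determinant is asserted
#' positive at generation).
#'
#' @param spec a [phantomSpec()]; its seed drives all randomness here.
#' @param affineParams list with \code{rotation} (deg, 3), \code{scale}
#'   (1 or 3), \code{translationVox} (3). \code{NULL} entries are drawn
#'   uniformly from rotation +/- 6 deg, scale 0.95-1.05, translation +/- 3
#'   voxels.
#' @param ffdParams list with \code{gridSpacingVox} (default 16) and
#'   \code{maxDispVox} (default 4); the maximum displacement must stay below
#'   half the grid spacing (fold-free guarantee).
#' @return A list: \code{fixed}, \code{moving} ([BrainVolume-class]),
#'   \code{trueAffine}, \code{trueFFD}, \code{fixedLabels},
#'   \code{deformedLabels}, \code{fixedLandmarks}, \code{deformedLandmarks},
#'   \code{labelTable}.
#' @export
makeDeformedPair <- function(spec = phantomSpec(),
                             affineParams = list(),
                             ffdParams = list(gridSpacingVox = 16,
                                              maxDispVox = 4)) {
    gs <- ffdParams$gridSpacingVox %||% 16
    md <- ffdParams$maxDispVox %||% 4
    if (md >= gs / 2)
        stop("maxDispVox must be below gridSpacingVox/2 (fold-free guarantee)")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    noiseless <- spec
    noiseless$noiseSigma <- 0
    noiseless$seed <- NULL  # RNG already seeded; keep one stream
    ph <- makePhantom(noiseless)
    fixed0 <- ph$volume
    spc <- spacing(fixed0)
    ctrWorld <- (dim(fixed0) - 1) / 2 * spc

    rot <- affineParams$rotation %||% stats::runif(3, -6, 6)
    scl <- affineParams$scale %||% stats::runif(1, 0.95, 1.05)
    trl <- (affineParams$translationVox %||% stats::runif(3, -3, 3)) * spc
    trueAffine <- makeAffine(rot, scl, trl, center = ctrWorld)

    # random smooth knot displacements, rescaled to the requested amplitude
    ffd <- identityFFD(fixed0, gs * spc[1], trueAffine)
    nk <- dim(ffd@coefficients)[1:3]
    co <- array(stats::runif(prod(nk) * 3, -1, 1), c(nk, 3))
    for (m in 1:3)
        co[, , , m] <- .gaussianSmoothCpp(co[, , , m], nk, rep(0.75, 3))
    if (md > 0 && max(abs(co)) > 0)
        co <- co / max(abs(co)) * md * spc[1]
    else co[] <- 0
    ffd@coefficients <- co

    dets <- .jacobianDetCpp(trueAffine@matrix, ffdGridList(ffd),
                            ffd@coefficients, dim(fixed0), spc,
                            origin(fixed0), 1L)
    if (min(dets) <= 0)
        stop("generated true deformation folds; use a different seed or a smaller maxDispVox")

    moving <- BrainVolume(
        .resampleCpp(voxelData(fixed0), dim(fixed0), spc, origin(fixed0),
                     dim(fixed0), spc, origin(fixed0), trueAffine@matrix,
                     ffdGridList(ffd), ffd@coefficients, 1L, 0),
        spc, origin(fixed0))
    deformedLabels <- LabelVolume(
        .resampleCpp(array(as.double(labelData(ph$labels)), dim(ph$labels)),
                     dim(ph$labels), spc, origin(fixed0),
                     dim(fixed0), spc, origin(fixed0), trueAffine@matrix,
                     ffdGridList(ffd), ffd@coefficients, 0L, 0),
        spc, origin(fixed0), labelTable = labelTable(ph$labels))

    lmFixed <- ph$landmarks
    lmMovingPts <- landmarks(lmFixed)
    xyz <- as.matrix(lmMovingPts[, c("x", "y", "z")])
    for (i in seq_len(nrow(xyz)))
        xyz[i, ] <- .invertFFDPoint(ffd, xyz[i, ])
    lmMovingPts[, c("x", "y", "z")] <- xyz

    if (spec$noiseSigma > 0) {
        fixed <- BrainVolume(voxelData(fixed0) +
            stats::rnorm(prod(dim(fixed0)), 0, spec$noiseSigma), spc, origin(fixed0))
        moving <- BrainVolume(voxelData(moving) +
            stats::rnorm(prod(dim(moving)), 0, spec$noiseSigma), spc, origin(moving))
    } else fixed <- fixed0

    list(fixed = fixed, moving = moving, trueAffine = trueAffine,
         trueFFD = ffd, fixedLabels = ph$labels,
         deformedLabels = deformedLabels, fixedLandmarks = lmFixed,
         deformedLandmarks = LandmarkSet(lmMovingPts),
         labelTable = labelTable(ph$labels))
}

# Solve T(y) = p for y by damped Newton iteration on the composed transform.
.invertFFDPoint <- function(ffd, p, tol = 1e-10, maxIter = 100L) {
    y <- as.numeric(solve(ffd@affine@matrix, c(p, 1))[1:3])
    for (it in seq_len(maxIter)) {
        fy <- as.numeric(deformPoints(ffd, rbind(y)))
        r <- fy - p
        if (max(abs(r)) < tol) return(y)
        # numeric Jacobian via central differences on a small step
        h <- 1e-3
        J <- matrix(0, 3, 3)
        for (a in 1:3) {
            e <- c(0, 0, 0); e[a] <- h
            J[, a] <- (as.numeric(deformPoints(ffd, rbind(y + e))) -
                       as.numeric(deformPoints(ffd, rbind(y - e)))) / (2 * h)
        }
        y <- y - as.numeric(solve(J, r))
    }
    y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a panel of raters from a true mask
#'
#' Two composable corruption channels model rater disagreement: (i) smooth
#' boundary jitter, a low-order angular perturbation of the contour applied
#' through the signed distance function (amplitude in pixels), producing
#' closed, simply connected masks; and (ii) per-pixel Bernoulli flips at
#' rates 1-p (misses) and 1-q (false positives) over the whole plane -- the
#' STAPLE generative model. Per-rater p and q are drawn uniformly from the
#' given ranges and returned for recovery tests.
#'
#' @param trueMask a [Mask2D-class] ground-truth mask.
#' @param n number of raters.
#' @param pRange,qRange ranges for per-rater sensitivity/specificity.
#' @param boundaryJitterPx jitter amplitude in pixels (0 disables).
#' @param zValues,zProbs discrete distribution of z-choices (defaults to the
#'   true mask's z for all raters).
#' @param attempts 1 or 2 independent corruptions per rater.
#' @param brainId,structure identifiers stamped on the records.
#' @param seed integer seed.
#' @return list with \code{raters} (list of [RaterSegmentation-class]),
#'   \code{p}, \code{q} (true per-rater values), \code{zChoices}.
#' @export
simulateRaters <- function(trueMask, n, pRange = c(0.85, 0.99),
                           qRange = c(0.95, 0.999), boundaryJitterPx = 0,
                           zValues = NULL, zProbs = NULL, attempts = 1L,
                           brainId = "B1", structure = "S1", seed = 1L) {
    if (n < 1) stop("need at least one rater")
    if (any(pRange <= 0 | pRange > 1) || any(qRange <= 0 | qRange > 1))
        stop("invalid sensitivity/specificity ranges")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    tm <- pixels(trueMask)
    if (is.null(zValues)) zValues <- zIndex(trueMask)
    p <- stats::runif(n, pRange[1], pRange[2])
    q <- stats::runif(n, qRange[1], qRange[2])
    sd2 <- NULL
    if (boundaryJitterPx > 0) {
        inside <- EBImage::distmap(EBImage::Image(tm * 1))
        outside <- EBImage::distmap(EBImage::Image((1 - tm) * 1))
        sd2 <- EBImage::imageData(outside) - EBImage::imageData(inside)  # negative inside
        cc <- colMeans(which(tm, arr.ind = TRUE))
        X <- row(tm) - cc[1]
        Y <- col(tm) - cc[2]
        theta <- atan2(Y, X)
    }
    raters <- list()
    zchoice <- integer(0)
    for (j in seq_len(n)) {
        for (att in seq_len(attempts)) {
            base <- tm
            if (boundaryJitterPx > 0) {
                k <- 1:4
                amp <- stats::rnorm(4, 0, 1) / sqrt(k)
                phi <- stats::runif(4, 0, 2 * pi)
                e <- matrix(0, nrow(tm), ncol(tm))
                for (h in k) e <- e + amp[h] * cos(h * theta + phi[h])
                if (max(abs(e)) > 0) e <- e / max(abs(e))
                base <- sd2 <= boundaryJitterPx * e
            }
            u <- matrix(stats::runif(length(tm)), nrow(tm))
            noisy <- ifelse(base, u <= p[j], u > q[j])
            z <- if (is.null(zProbs)) sample(rep(zValues, 2), 1)
                 else sample(zValues, 1, prob = zProbs)
            m <- Mask2D(noisy, pixelSize(trueMask), z)
            raters[[length(raters) + 1L]] <- RaterSegmentation(
                m, sprintf("R%02d", j), brainId, structure, att)
            if (att == 1L) zchoice <- c(zchoice, z)
        }
    }
    list(raters = raters, p = p, q = q, zChoices = zchoice)
}
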