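# Orchestration: configuration, the full segmentation pipeline
# (preprocess -> affine -> free-form -> propagate), the bending-energy sweep
# harness, and a self-contained phantom validation experiment.

#' Default pipeline configuration
#'
#' A flat key-value namespace mirroring the module parameters. Every
#' standard parameter of the pipeline carries its usual production value:
#' 5-voxel z-smoothing, 12.5 um isotropic working resolution, 6/5 affine
#' and 6/4 free-form pyramid levels, 128 NMI bins, 10-voxel control-point
#' spacing, bending-energy weight 0.95, 1-voxel input smoothing, two
#' 0.5-voxel atlas label smoothing passes, 4 um outline scoring grid.
#'
#' @param ... overrides, e.g. \code{defaultConfig(ffd.be_weight = 0.5)}.
#' @return Named list of configuration values.
#' @export
defaultConfig <- function(...) {
    cfg <- list(
        preprocess.z_sigma_vox = 5,
        preprocess.target_um = 12.5,
        affine.block_size_vox = 4L,
        affine.variance_keep_fraction = 0.5,
        affine.search_radius_vox = 3L,
        affine.lts_fraction = 0.5,
        affine.n_levels = 6L,
        affine.n_levels_computed = 5L,
        affine.max_iter_per_level = 5L,
        ffd.similarity = "nmi",
        ffd.nmi_bins = 128L,
        ffd.be_weight = 0.95,
        ffd.grid_spacing_vox = 10L,
        ffd.input_smooth_sigma_vox = 1,
        ffd.n_levels = 6L,
        ffd.n_levels_computed = 4L,
        ffd.max_iter_per_level = 300L,
        ffd.convergence_tol = 1e-5,
        atlas.smooth_sigma_vox = 0.5,
        atlas.smooth_passes = 2L,
        outline.pixel_um = 4,
        scoring.clean_min_area_px = 50L,
        scoring.section_step_um = 15)
    ov <- list(...)
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
        stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
    cfg[names(ov)] <- ov
    cfg
}

#' Read/write flat INI-style configuration files
#'
#' One \code{key = value} pair per line; \code{#} comments allowed. Values
#' are parsed as numbers where possible.
#'
#' @param path file path.
#' @return \code{readConfig}: a config list merged over [defaultConfig()].
#' @export
readConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    kv <- lapply(lines, function(l) {
        parts <- strsplit(l, "=", fixed = TRUE)[[1]]
        key <- trimws(parts[1])
        val <- trimws(paste(parts[-1], collapse = "="))
        num <- suppressWarnings(as.numeric(val))
        list(key = key, value = if (is.na(num)) val else num)
    })
    ov <- stats::setNames(lapply(kv, `[[`, "value"),
                          vapply(kv, `[[`, character(1), "key"))
    do.call(defaultConfig, ov)
}

#' @rdname readConfig
#' @param config a configuration list.
#' @export
writeConfig <- function(config, path) {
    writeLines(vapply(names(config), function(k)
        sprintf("%s = %s", k, format(config[[k]], digits = 17)),
        character(1)), path)
    invisible(path)
}

.affineParamsFromConfig <- function(cfg)
    blockMatchParams(blockSizeVox = cfg$affine.block_size_vox,
                     varianceKeepFraction = cfg$affine.variance_keep_fraction,
                     searchRadiusVox = cfg$affine.search_radius_vox,
                     ltsFraction = cfg$affine.lts_fraction,
                     nLevels = cfg$affine.n_levels,
                     nLevelsComputed = cfg$affine.n_levels_computed,
                     maxIterPerLevel = cfg$affine.max_iter_per_level)

.ffdParamsFromConfig <- function(cfg)
    ffdParams(similarity = cfg$ffd.similarity,
              nmiBins = as.integer(cfg$ffd.nmi_bins),
              beWeight = cfg$ffd.be_weight,
              gridSpacingVox = as.integer(cfg$ffd.grid_spacing_vox),
              inputSmoothSigmaVox = cfg$ffd.input_smooth_sigma_vox,
              nLevels = as.integer(cfg$ffd.n_levels),
              nLevelsComputed = as.integer(cfg$ffd.n_levels_computed),
              maxIterPerLevel = as.integer(cfg$ffd.max_iter_per_level),
              convergenceTol = cfg$ffd.convergence_tol)

#' Run the full atlas-propagation pipeline
#'
#' preprocess (z-smooth + isotropic resample of the sample) -> affine
#' block-matching registration of the atlas average brain to the sample ->
#' free-form refinement -> nearest-neighbour propagation of the atlas labels
#' through the composed transform. A provenance record captures the
#' configuration, package version and per-stage wall time. Ground-truth
#' transforms can be injected via \code{bypass} to skip registration (the
#' oracle mode used in validation).
#'
#' @param sample the sample [BrainVolume-class] to segment.
#' @param atlasAvg the atlas average-intensity [BrainVolume-class].
#' @param atlasLbl the atlas [LabelVolume-class].
#' @param config a [defaultConfig()] list.
#' @param bypass optional list(affine, ffd) of ground-truth transforms.
#' @param verbose print stage progress.
#' @return list(labels, affine, ffd, reference, provenance).
#' @export
runPipeline <- function(sample, atlasAvg, atlasLbl, config = defaultConfig(),
                        bypass = NULL, verbose = FALSE) {
    prov <- list(config = config,
                 package_version = as.character(utils::packageVersion("atlasmap")),
                 stages = list())
    tic <- function() proc.time()[["elapsed"]]
    stage <- function(name, expr) {
        t0 <- tic()
        out <- tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        prov$stages[[name]] <<- list(seconds = tic() - t0)
        if (verbose) message(sprintf("[%s] %.1f s", name,
                                     prov$stages[[name]]$seconds))
        out
    }
    ref <- stage("preprocess", {
        v <- smoothZ(sample, config$preprocess.z_sigma_vox)
        if (max(abs(spacing(v) - config$preprocess.target_um)) > 1e-9)
            resampleIsotropic(v, config$preprocess.target_um) else v
    })
    if (is.null(bypass)) {
        aff <- stage("affine",
            registerAffine(ref, atlasAvg, .affineParamsFromConfig(config)))
        ffd <- stage("ffd",
            registerFFD(ref, atlasAvg, aff, .ffdParamsFromConfig(config)))
    } else {
        aff <- bypass$affine
        ffd <- bypass$ffd
        prov$stages$registration <- list(bypassed = TRUE)
    }
    labels <- stage("propagate",
        propagateLabels(atlasLbl, aff, ffd, ref,
                        smoothSigmaVox = config$atlas.smooth_sigma_vox,
                        smoothPasses = config$atlas.smooth_passes))
    list(labels = labels, affine = aff, ffd = ffd, reference = ref,
         provenance = prov)
}

#' Bending-energy weight sweep
#'
#' Reruns the free-form registration from a fixed affine initialization for
#' each weight of a grid (default: 18 values evenly spanning 0.2-0.99) and
#' reports, per weight, the mean per-structure Dice of the propagated labels
#' against reference labels, the mean landmark distance, and the fraction of
#' negative-Jacobian voxels (the over-fitting diagnostic).
#'
#' @param sample,atlasAvg,atlasLbl as in [runPipeline()] (sample assumed
#'   preprocessed).
#' @param refLabels ground-truth [LabelVolume-class] on the sample grid.
#' @param landmarksRef,landmarksFlt [LandmarkSet-class] pairs (sample and
#'   atlas space).
#' @param weights bending-energy weights to test.
#' @param config pipeline configuration.
#' @param affine optional precomputed [AffineTransform3D-class].
#' @param verbose print per-weight progress.
#' @return data.frame(weight, mean_dice, mean_landmark_um,
#'   neg_jacobian_fraction), one row per weight.
#' @export
beSweep <- function(sample, atlasAvg, atlasLbl, refLabels, landmarksRef,
                    landmarksFlt, weights = seq(0.2, 0.99, length.out = 18),
                    config = defaultConfig(), affine = NULL, verbose = FALSE) {
    if (length(weights) < 2 || any(weights < 0 | weights >= 1))
        stop("need >= 2 weights in [0, 1)")
    if (is.null(affine))
        affine <- registerAffine(sample, atlasAvg,
                                 .affineParamsFromConfig(config))
    ids <- sort(labelTable(atlasLbl)$id)
    rows <- lapply(weights, function(w) {
        p <- .ffdParamsFromConfig(config)
        p$beWeight <- w
        ffd <- registerFFD(sample, atlasAvg, affine, p)
        lab <- propagateLabels(atlasLbl, affine, ffd, sample,
                               smoothSigmaVox = config$atlas.smooth_sigma_vox,
                               smoothPasses = config$atlas.smooth_passes)
        dice <- mean(labelDice(lab, refLabels, ids))
        lm <- landmarkDistance(landmarksRef, landmarksFlt, affine, ffd)
        nj <- negJacobianFraction(ffd, stride = 2L)
        if (verbose)
            message(sprintf("BE weight %.3f: dice %.3f, landmark %.1f um, negJ %.4f",
                            w, dice, lm$meanUm, nj))
        data.frame(weight = w, mean_dice = dice,
                   mean_landmark_um = lm$meanUm, neg_jacobian_fraction = nj)
    })
    do.call(rbind, rows)
}

#' Self-contained phantom validation experiment
#'
#' Generates a deformed phantom pair, runs the full pipeline (the phantom
#' stands for already-preprocessed data, so z-smoothing is disabled in the
#' experiment configuration), simulates a rater panel on the ground-truth
#' outline of each structure at the 4 um scoring grid, builds STAPLE
#' consensus segmentations, selects the automated plane per structure, and
#' assembles the long-form score table. Fully deterministic given the seed.
#'
#' @param seed integer seed for phantom, deformation and raters.
#' @param shape phantom grid shape (default 48^3 for desk-scale runtimes).
#' @param nRaters raters per structure; @param jitterPx boundary jitter.
#' @param config pipeline configuration overrides are applied on top of the
#'   experiment defaults.
#' @param bypass use ground-truth transforms instead of registration.
#' @return list(scores, pipeline, pair, consensus).
#' @export
runValidationExperiment <- function(seed = 1L, shape = c(48L, 48L, 48L),
                                    nRaters = 6L, jitterPx = 3,
                                    config = defaultConfig(), bypass = FALSE) {
    config$preprocess.z_sigma_vox <- 0
    spec <- phantomSpec(shape = shape, seed = seed)
    pair <- makeDeformedPair(spec)
    run <- runPipeline(pair$moving, pair$fixed, pair$fixedLabels, config,
        bypass = if (bypass) list(affine = pair$trueAffine, ffd = pair$trueFFD)
                 else NULL)
    pxOut <- config$outline.pixel_um
    ids <- labelTable(pair$fixedLabels)$id
    acr <- labelTable(pair$fixedLabels)$acronym
    consensus <- list()
    autoMasks <- list()
    records <- list()
    for (i in seq_along(ids)) {
        id <- ids[i]
        truth3d <- labelData(pair$deformedLabels) == id
        area <- apply(truth3d, 3, sum)
        if (max(area) == 0) next
        zBest <- which.max(area)
        truth <- Mask2D(truth3d[, , zBest], spacing(pair$moving)[1], zBest)
        truthHi <- resampleMask(truth, pxOut)
        zs <- pmin(pmax(zBest + (-2:2), 1L), dim(pair$moving)[3])
        sim <- simulateRaters(truthHi, nRaters, pRange = c(0.92, 0.99),
                              qRange = c(0.995, 0.9995),
                              boundaryJitterPx = jitterPx,
                              zValues = zs, attempts = 2L,
                              brainId = "P1", structure = acr[i],
                              seed = seed + 97L * i)
        recs <- lapply(sim$raters, function(r) {
            r@mask <- cleanMask(r@mask, config$scoring.clean_min_area_px)
            if (r@mask@empty) r@mask <- sim$raters[[1]]@mask  # degenerate guard
            r
        })
        key <- paste("P1", acr[i], sep = "|")
        consensus[[key]] <- staple(lapply(recs, function(r) r@mask))
        win <- range(vapply(recs, zIndex, integer(1)))
        cand <- extractOutline(run$labels, id, win)
        autoMasks[[key]] <- bestPlane(cand, consensus[[key]]@consensusMask)$mask
        records <- c(records, recs)
    }
    scores <- scorePanel(records, consensus, autoMasks)
    list(scores = scores, pipeline = run, pair = pair, consensus = consensus)
}
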