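# Quantitative comparison metrics: Dice, Hausdorff, z-distance, z-window
# filtering, landmark distance, and score-table assembly.

.checkAligned <- function(a, b) {
    if (!identical(dim(a), dim(b)) ||
        abs(pixelSize(a) - pixelSize(b)) > 1e-9)
        stop("masks are not on a common pixel grid")
}

#' Dice overlap score of two masks
#'
#' \code{2|A n B| / (|A| + |B|)}: the intersection divided by half the sum
#' of the areas. Two empty masks score 1 (agreement on absence); one empty
#' mask scores 0.
#'
#' @param a,b aligned [Mask2D-class] objects.
#' @return Dice score in [0, 1].
#' @export
diceScore <- function(a, b) {
    .checkAligned(a, b)
    pa <- pixels(a); pb <- pixels(b)
    sa <- sum(pa); sb <- sum(pb)
    if (sa + sb == 0) return(1)
    2 * sum(pa & pb) / (sa + sb)
}

#' Hausdorff distance between two masks
#'
#' The longest distance from any foreground pixel of one mask to its nearest
#' foreground pixel in the other (symmetric: the maximum of the two directed
#' distances), over pixel-centre coordinates scaled by the pixel size. All
#' foreground pixels are used rather than boundary pixels only; the value is
#' identical.
#'
#' @param a,b aligned, non-empty [Mask2D-class] objects.
#' @return Distance in micrometres.
#' @export
hausdorffDistance <- function(a, b) {
    .checkAligned(a, b)
    if (!any(pixels(a)) || !any(pixels(b)))
        stop("Hausdorff distance requires non-empty masks")
    ca <- which(pixels(a), arr.ind = TRUE) * pixelSize(a)
    cb <- which(pixels(b), arr.ind = TRUE) * pixelSize(b)
    .hausdorffCpp(ca, cb)
}

#' Remove small connected components from a mask
#'
#' Mirrors the manual cleaning of accidental isolated touches before
#' scoring: 8-connected components smaller than \code{minAreaPx} pixels are
#' removed.
#'
#' @param mask a [Mask2D-class].
#' @param minAreaPx minimum component area in pixels (default 50, intended
#'   for the 4 um scoring grid).
#' @return A cleaned [Mask2D-class].
#' @export
cleanMask <- function(mask, minAreaPx = 50L) {
    m <- pixels(mask)
    if (!any(m)) return(mask)
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    tab <- table(as.vector(lab[lab > 0]))
    keep <- as.integer(names(tab)[tab >= minAreaPx])
    Mask2D(matrix(EBImage::imageData(lab) %in% keep, nrow(m)), pixelSize(mask),
           zIndex(mask))
}

#' Pairwise z-distances of rater section choices
#'
#' All unordered rater pairs for one brain and structure: the absolute
#' difference in chosen section index times the physical section step.
#'
#' @param records list of [RaterSegmentation-class] (one brain+structure).
#' @param sectionStepUm distance between optical sections, default 15 um.
#' @return list(pairs = data.frame(i, j, distanceUm), medianUm).
#' @export
zDistanceTable <- function(records, sectionStepUm = 15) {
    if (length(records) < 2) stop("need at least two records")
    z <- vapply(records, zIndex, integer(1))
    cmb <- utils::combn(length(z), 2)
    dist <- abs(z[cmb[1, ]] - z[cmb[2, ]]) * sectionStepUm
    list(pairs = data.frame(i = cmb[1, ], j = cmb[2, ], distanceUm = dist),
         medianUm = stats::median(dist))
}

#' Filter records to the best z window
#'
#' Places a window of \code{window} consecutive sections to contain the
#' maximum possible number of segmentations (ties to the lowest starting
#' section) and flags records outside it. Discarded records are flagged, not
#' deleted; the caller recomputes the consensus on the survivors.
#'
#' @param records list of [RaterSegmentation-class].
#' @param window window length in sections (>= 1).
#' @return list(records, keep = logical, windowStart, windowEnd).
#' @export
zWindowFilter <- function(records, window) {
    stopifnot(window >= 1)
    z <- vapply(records, zIndex, integer(1))
    starts <- seq(min(z), max(z))
    counts <- vapply(starts, function(s) sum(z >= s & z <= s + window - 1),
                     integer(1))
    s <- starts[which.max(counts)]  # which.max ties to lowest start
    keep <- z >= s & z <= s + window - 1
    list(records = records, keep = keep, windowStart = s,
         windowEnd = s + window - 1L)
}

#' Landmark distances through a recovered transform
#'
#' Maps each reference-space landmark through the composed transform and
#' reports the Euclidean distance to the correspondingly named
#' floating-space landmark, plus their mean. Named landmarks can be omitted
#' (e.g. when obscured by an imaging artefact).
#'
#' @param placedRef [LandmarkSet-class] in reference (sample) space.
#' @param placedFlt [LandmarkSet-class] in floating (atlas) space.
#' @param affine [AffineTransform3D-class]; @param ffd optional
#'   [FFDTransform-class] composed over it.
#' @param omit character vector of landmark names to exclude.
#' @return list(perLandmark = named numeric (um), meanUm).
#' @export
landmarkDistance <- function(placedRef, placedFlt, affine, ffd = NULL,
                             omit = character()) {
    pr <- landmarks(placedRef); pf <- landmarks(placedFlt)
    pr <- pr[!pr$name %in% omit, ]; pf <- pf[!pf$name %in% omit, ]
    if (!setequal(pr$name, pf$name))
        stop(sprintf("landmark name mismatch: %s",
             paste(union(setdiff(pr$name, pf$name), setdiff(pf$name, pr$name)),
                   collapse = ", ")))
    pf <- pf[match(pr$name, pf$name), ]
    X <- as.matrix(pr[, c("x", "y", "z")])
    mapped <- if (is.null(ffd)) applyAffineToPoints(affine@matrix, X)
              else deformPoints(ffd, X)
    dist <- sqrt(rowSums((mapped - as.matrix(pf[, c("x", "y", "z")]))^2))
    names(dist) <- pr$name
    list(perLandmark = dist, meanUm = mean(dist))
}

#' Per-structure Dice between two label volumes
#'
#' 3D Dice per label id over two label volumes on the same grid.
#'
#' @param a,b [LabelVolume-class] objects with a common grid.
#' @param ids label ids to score (default: all ids in \code{a}'s table).
#' @return Named numeric vector of Dice scores.
#' @export
labelDice <- function(a, b, ids = NULL) {
    stopifnot(is(a, "LabelVolume"), is(b, "LabelVolume"))
    if (!identical(dim(a), dim(b))) stop("label volumes must share a grid")
    if (is.null(ids)) ids <- sort(labelTable(a)$id)
    la <- labelData(a); lb <- labelData(b)
    out <- vapply(ids, function(id) {
        sa <- sum(la == id); sb <- sum(lb == id)
        if (sa + sb == 0) return(1)
        2 * sum(la == id & lb == id) / (sa + sb)
    }, numeric(1))
    names(out) <- as.character(ids)
    out
}

#' Assemble a long-form score table for a rater panel
#'
#' Produces rows (brain_id, structure, source, comparison, metric, value):
#' inter-rater rows compare every attempt (or first attempts only) with the
#' STAPLE consensus of the panel; intra-rater rows compare each rater's
#' second attempt with their first; automated rows compare the
#' pipeline-selected plane with the consensus under source \code{"auto"}.
#' Dice is always reported; Hausdorff (um) when both masks are non-empty.
#'
#' @param records list of [RaterSegmentation-class].
#' @param consensusPerStructure named list of [Mask2D-class] or
#'   [ConsensusResult-class], keyed \code{"<brain>|<structure>"}.
#' @param autoMasks optional named list of [Mask2D-class], same keys.
#' @param firstAttemptOnly restrict inter-rater rows to attempt 1.
#' @param hausdorff also emit hausdorff_um rows.
#' @return data.frame score table.
#' @export
scorePanel <- function(records, consensusPerStructure, autoMasks = NULL,
                       firstAttemptOnly = FALSE, hausdorff = TRUE) {
    key <- function(r) paste(r@brainId, r@structure, sep = "|")
    cons <- lapply(consensusPerStructure, function(cc)
        if (is(cc, "ConsensusResult")) cc@consensusMask else cc)
    rows <- list()
    add <- function(brain, structure, source, comparison, metric, value)
        rows[[length(rows) + 1L]] <<- data.frame(
            brain_id = brain, structure = structure, source = source,
            comparison = comparison, metric = metric, value = value)
    for (r in records) {
        k <- key(r)
        if (is.null(cons[[k]]))
            stop(sprintf("missing consensus for %s", k))
        if (firstAttemptOnly && r@attempt != 1L) next
        cm <- cons[[k]]
        m <- r@mask
        add(r@brainId, r@structure, r@raterId, "inter", "dice",
            diceScore(m, cm))
        if (hausdorff && !m@empty && !cm@empty)
            add(r@brainId, r@structure, r@raterId, "inter", "hausdorff_um",
                hausdorffDistance(m, cm))
    }
    # intra: attempt 2 vs attempt 1 of the same rater
    ids <- vapply(records, function(r)
        paste(r@raterId, r@brainId, r@structure, sep = "|"), character(1))
    for (u in unique(ids)) {
        grp <- records[ids == u]
        att <- vapply(grp, function(r) r@attempt, integer(1))
        if (all(c(1L, 2L) %in% att)) {
            r1 <- grp[[which(att == 1L)[1]]]; r2 <- grp[[which(att == 2L)[1]]]
            add(r1@brainId, r1@structure, r1@raterId, "intra", "dice",
                diceScore(r2@mask, r1@mask))
            if (hausdorff && !r1@mask@empty && !r2@mask@empty)
                add(r1@brainId, r1@structure, r1@raterId, "intra",
                    "hausdorff_um", hausdorffDistance(r2@mask, r1@mask))
        }
    }
    if (!is.null(autoMasks)) {
        for (k in names(autoMasks)) {
            if (is.null(cons[[k]]))
                stop(sprintf("missing consensus for %s", k))
            bs <- strsplit(k, "|", fixed = TRUE)[[1]]
            add(bs[1], bs[2], "auto", "auto_vs_consensus", "dice",
                diceScore(autoMasks[[k]], cons[[k]]))
            if (hausdorff && !autoMasks[[k]]@empty && !cons[[k]]@empty)
                add(bs[1], bs[2], "auto", "auto_vs_consensus", "hausdorff_um",
                    hausdorffDistance(autoMasks[[k]], cons[[k]]))
        }
    }
    if (length(rows) == 0)
        return(data.frame(brain_id = character(), structure = character(),
                          source = character(), comparison = character(),
                          metric = character(), value = numeric()))
    do.call(rbind, rows)
}

#' Convenience hypothesis tests on a score table
#'
#' Thin wrappers over standard routines, not part of the validated core:
#' Mann-Whitney U on the Dice values of two sources and a Levene-type test
#' (Brown-Forsythe: ANOVA on absolute deviations from group medians) for
#' equality of variance.
#'
#' @param table a [scorePanel()] score table.
#' @param sourceA,sourceB source labels to compare (Dice rows only).
#' @return list with \code{mannWhitney} and \code{levene} htest results.
#' @export
compareScores <- function(table, sourceA, sourceB) {
    d <- table[table$metric == "dice", ]
    a <- d$value[d$source == sourceA]
    b <- d$value[d$source == sourceB]
    grp <- factor(rep(c(sourceA, sourceB), c(length(a), length(b))))
    vals <- c(a, b)
    dev <- abs(vals - stats::ave(vals, grp, FUN = stats::median))
    list(mannWhitney = stats::wilcox.test(a, b, exact = FALSE),
         levene = stats::oneway.test(dev ~ grp, var.equal = TRUE))
}
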