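# Consensus segmentation from rater panels: STAPLE (EM estimation of a
# probabilistic truth plus per-rater sensitivity/specificity) and
# shape-based averaging (mean signed distance transform).

.panelMasks <- function(masks) {
    masks <- lapply(masks, function(m) if (is(m, "RaterSegmentation")) m@mask else m)
    if (length(masks) < 1) stop("need at least one mask")
    d <- dim(masks[[1]])
    px <- pixelSize(masks[[1]])
    ok <- vapply(masks, function(m)
        identical(dim(m), d) && abs(pixelSize(m) - px) < 1e-9, logical(1))
    if (!all(ok)) stop("masks are not on a common pixel grid")
    masks
}

#' STAPLE consensus of a rater panel
#'
#' Binary STAPLE: an EM algorithm that simultaneously estimates the hidden
#' true segmentation (as a per-pixel posterior) and each rater's sensitivity
#' p and specificity q. E-step: the posterior foreground probability given
#' all decisions and current (p, q); M-step: p and q re-estimated from the
#' posterior-weighted decisions. All raters are initialized to the same
#' quality level. Estimation runs over an analysis region of interest (the
#' bounding box of the panel union dilated by \code{roiDilatePx}); a
#' near-infinite all-background plane would make specificity estimates
#' degenerate, so the ROI is explicit and configurable.
#'
#' @param masks list of aligned [Mask2D-class] or
#'   [RaterSegmentation-class] objects.
#' @param initPq common initial sensitivity/specificity (default 0.99).
#' @param gamma foreground prior; \code{"auto"} (default) uses the mean
#'   foreground fraction across masks within the ROI.
#' @param tol EM stopping tolerance on max |change| in p and q.
#' @param maxIter EM iteration cap.
#' @param roiDilatePx dilation of the union bounding box, pixels.
#' @return A [ConsensusResult-class]; the consensus mask thresholds the
#'   posterior at 0.5 (ties to foreground).
#' @export
staple <- function(masks, initPq = 0.99, gamma = "auto", tol = 1e-6,
                   maxIter = 200L, roiDilatePx = 10L) {
    masks <- .panelMasks(masks)
    J <- length(masks)
    d <- dim(masks[[1]])
    px <- pixelSize(masks[[1]])
    D <- vapply(masks, function(m) as.numeric(pixels(m)), numeric(prod(d)))
    if (all(D == 0)) stop("all masks are empty")
    union <- rowSums(D) > 0
    um <- array(union, d)
    rows <- range(which(apply(um, 1, any)))
    cols <- range(which(apply(um, 2, any)))
    r0 <- max(1, rows[1] - roiDilatePx); r1 <- min(d[1], rows[2] + roiDilatePx)
    c0 <- max(1, cols[1] - roiDilatePx); c1 <- min(d[2], cols[2] + roiDilatePx)
    roi <- array(FALSE, d)
    roi[r0:r1, c0:c1] <- TRUE
    roiIdx <- which(as.vector(roi))
    Dr <- D[roiIdx, , drop = FALSE]
    g <- if (identical(gamma, "auto")) mean(Dr) else as.numeric(gamma)
    p <- rep(initPq, J); q <- rep(initPq, J)
    clog <- function(x) log(pmax(x, 1e-12))
    W <- NULL
    ll <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        la <- Dr %*% clog(p) + (1 - Dr) %*% clog(1 - p)
        lb <- Dr %*% clog(1 - q) + (1 - Dr) %*% clog(q)
        num <- g * exp(la)
        den <- num + (1 - g) * exp(lb)
        W <- as.numeric(num / pmax(den, 1e-300))
        ll <- c(ll, sum(log(pmax(den, 1e-300))))
        sw <- sum(W); swc <- sum(1 - W)
        pNew <- as.numeric(crossprod(Dr, W)) / max(sw, 1e-300)
        qNew <- as.numeric(crossprod(1 - Dr, 1 - W)) / max(swc, 1e-300)
        delta <- max(abs(pNew - p), abs(qNew - q))
        p <- pNew; q <- qNew
        if (delta < tol) { converged <- TRUE; break }
    }
    pm <- array(0, d)
    pm[roiIdx] <- W
    rn <- names(masks)
    if (is.null(rn)) rn <- sprintf("R%02d", seq_len(J))
    names(p) <- rn; names(q) <- rn
    zi <- stats::median(vapply(masks, zIndex, integer(1)))
    new("ConsensusResult", probabilityMap = pm,
        consensusMask = Mask2D(pm >= 0.5, px, as.integer(zi)),
        sensitivity = p, specificity = q, prior = g,
        nIterations = it, converged = converged, logLik = ll)
}

#' Shape-based averaging of a rater panel
#'
#' Consensus by averaging per-mask signed Euclidean distance transforms
#' (negative inside, positive outside, in pixels) and keeping pixels whose
#' mean signed distance is at most zero — the geometric mean shape of the
#' panel.
#'
#' @param masks list of aligned, non-empty [Mask2D-class] or
#'   [RaterSegmentation-class] objects.
#' @return A [Mask2D-class] consensus.
#' @export
sba <- function(masks) {
    masks <- .panelMasks(masks)
    rn <- names(masks)
    if (is.null(rn)) rn <- sprintf("R%02d", seq_along(masks))
    acc <- NULL
    for (j in seq_along(masks)) {
        m <- pixels(masks[[j]])
        if (!any(m))
            stop(sprintf("empty mask in panel: %s", rn[j]))
        inside <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
        outside <- EBImage::imageData(EBImage::distmap(EBImage::Image((1 - m) * 1)))
        sd <- outside - inside
        acc <- if (is.null(acc)) sd else acc + sd
    }
    zi <- stats::median(vapply(masks, zIndex, integer(1)))
    Mask2D(acc / length(masks) <= 0, pixelSize(masks[[1]]), as.integer(zi))
}
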