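test_that("B-spline deformation satisfies partition of unity and knot weights", {
    v <- BrainVolume(array(0, c(16, 16, 16)), 12.5)
    f <- identityFFD(v, 40)
    set.seed(41)
    pts <- matrix(runif(30, 0, 15 * 12.5), 10)
    expect_equal(deformPoints(f, pts), pts, tolerance = 1e-12)
    # uniform knot displacement moves every point by exactly that vector
    f@coefficients[, , , 1] <- 7
    f@coefficients[, , , 2] <- -3
    f@coefficients[, , , 3] <- 1.5
    expect_equal(deformPoints(f, pts),
                 sweep(pts, 2, c(7, -3, 1.5), "+"), tolerance = 1e-12)
    # single displaced knot: value at the knot position is d * (2/3)^3
    # (the 1D basis weights at a knot are 1/6, 2/3, 1/6)
    f2 <- identityFFD(v, 40)
    nk <- dim(f2@coefficients)[1:3]
    kc <- floor(nk / 2)
    f2@coefficients[kc[1], kc[2], kc[3], 1] <- 10
    kw <- f2@gridOrigin + (kc - 1) * f2@gridSpacing
    d <- deformPoints(f2, rbind(kw)) - rbind(kw)
    expect_equal(as.numeric(d), c(10 * (2 / 3)^3, 0, 0), tolerance = 1e-12)
})

test_that("NMI reaches 2 for identical exact-bin images and is symmetric", {
    set.seed(42)
    img <- array(sample(0:127, 24^3, TRUE), c(24, 24, 24))
    va <- BrainVolume(img, 12.5)
    expect_equal(nmi(va, va, 128), 2, tolerance = 1e-6)
    # hand-computed toy joint histogram {(0,0): n/2, (1,1): n/2} -> NMI = 2
    toy <- BrainVolume(array(rep(c(0, 1), 32), c(4, 4, 4)), 1)
    expect_equal(nmi(toy, toy, 2), 2, tolerance = 1e-12)
    vb <- BrainVolume(array(rnorm(24^3) * 40 + 100, dim(img)), 12.5)
    expect_equal(nmi(va, vb, 64), nmi(vb, va, 64), tolerance = 1e-12)
    # independently shuffled copy: NMI -> 1 once the histogram is populated
    # (n much larger than the number of joint bins)
    big <- array(sample(0:63, 32^3, TRUE), c(32, 32, 32))
    vbig <- BrainVolume(big, 12.5)
    vshuf <- BrainVolume(array(sample(big), dim(big)), 12.5)
    expect_lt(abs(nmi(vbig, vshuf, 64) - 1), 0.02)
    expect_error(nmi(va, BrainVolume(array(0, c(2, 2, 2)), 1)), "grid")
})

test_that("bending energy vanishes for affine fields and matches finite differences", {
    v <- BrainVolume(array(0, c(16, 16, 16)), 12.5)
    f <- identityFFD(v, 40)
    expect_equal(bendingEnergy(f), 0)
    # globally linear displacement (shear) has zero second derivatives
    nk <- dim(f@coefficients)[1:3]
    for (i in seq_len(nk[1])) for (j in seq_len(nk[2])) {
        w <- f@gridOrigin[2] + (j - 1) * f@gridSpacing[2]
        f@coefficients[i, j, , 1] <- 0.3 * w
        f@coefficients[i, j, , 2] <- 5
    }
    expect_lt(bendingEnergy(f), 1e-10)
    # constant displacement offset leaves the bending energy unchanged
    f2 <- identityFFD(v, 40)
    set.seed(43)
    f2@coefficients[] <- rnorm(length(f2@coefficients), 0, 3)
    be <- bendingEnergy(f2)
    expect_gt(be, 0)
    f3 <- f2
    f3@coefficients[, , , 1] <- f3@coefficients[, , , 1] + 50
    expect_equal(bendingEnergy(f3), be, tolerance = 1e-10)
    # numerical second-difference oracle on a single displaced knot
    f4 <- identityFFD(v, 40)
    kc <- floor(nk / 2)
    f4@coefficients[kc[1], kc[2], kc[3], 1] <- 10
    num <- local({
        d <- f4@refDim; spc <- f4@refSpacing; org <- f4@refOrigin
        idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
        W <- sweep(sweep(idx, 2, spc, "*"), 2, org, "+")
        disp <- function(P) deformPoints(f4, P) - P
        h <- f4@gridSpacing
        eps <- 0.05
        tot <- 0
        for (t in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))) {
            ea <- diag(3)[t[1], ] * h[t[1]] * eps
            eb <- diag(3)[t[2], ] * h[t[2]] * eps
            if (t[1] == t[2]) {
                D2 <- (disp(sweep(W, 2, ea, "+")) - 2 * disp(W) +
                       disp(sweep(W, 2, ea, "-"))) / eps^2
                tot <- tot + rowSums(D2^2)
            } else {
                D2 <- (disp(sweep(sweep(W, 2, ea, "+"), 2, eb, "+")) -
                       disp(sweep(sweep(W, 2, ea, "+"), 2, eb, "-")) -
                       disp(sweep(sweep(W, 2, ea, "-"), 2, eb, "+")) +
                       disp(sweep(sweep(W, 2, ea, "-"), 2, eb, "-"))) /
                      (4 * eps^2)
                tot <- tot + 2 * rowSums(D2^2)
            }
        }
        mean(tot) / 1e6  # displacements were in um; energy uses mm
    })
    expect_equal(bendingEnergy(f4), num, tolerance = 0.01)
})

test_that("self-registration leaves displacements near zero with a monotone objective", {
    ph <- makePhantom(smallPhantomSpec(seed = 44))
    ffd <- registerFFD(ph$volume, ph$volume, params = fastFFDParams())
    meanDisp <- mean(sqrt(apply(ffd@coefficients^2, 1:3, sum)))
    expect_lt(meanDisp / spacing(ph$volume)[1], 0.2)
    for (lv in attr(ffd, "history"))
        expect_true(all(diff(lv$objective) >= -1e-12))
})

test_that("free-form registration recovers a known smooth deformation", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 45, shape = c(48L, 48L, 48L)))
    aff <- registerAffine(pair$moving, pair$fixed)
    ffd <- registerFFD(pair$moving, pair$fixed, aff, fastFFDParams())
    # compare mapped positions of foreground voxels against the true map
    fg <- which(labelData(pair$deformedLabels) > 0)
    d <- dim(pair$moving)
    idx <- arrayInd(fg, d)[seq(1, length(fg), by = 7), ]
    W <- sweep(sweep(idx - 1, 2, spacing(pair$moving), "*"), 2,
               origin(pair$moving), "+")
    errUm <- sqrt(rowSums((deformPoints(ffd, W) -
                           deformPoints(pair$trueFFD, W))^2))
    expect_lt(stats::median(errUm) / spacing(pair$moving)[1], 1)
})

test_that("fold diagnostics report non-negative Jacobian for smooth true fields", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 46))
    expect_equal(negJacobianFraction(pair$trueFFD, 2), 0)
    expect_true(all(jacobianDeterminants(pair$trueFFD, 2) > 0))
})
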