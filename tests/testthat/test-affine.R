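test_that("block matching finds self-matches and known shifts", {
    ph <- makePhantom(smallPhantomSpec(seed = 31))
    v <- ph$volume
    self <- matchBlocks(v, v)
    disp <- sqrt((self$fx - self$rx)^2 + (self$fy - self$ry)^2 +
                 (self$fz - self$rz)^2)
    expect_lt(stats::median(disp), 0.2 * spacing(v)[1])
    # floating shifted by 2 voxels in x: modal displacement (2, 0, 0)
    arr <- voxelData(v)
    shifted <- array(0, dim(arr))
    shifted[1:(dim(arr)[1] - 2), , ] <- arr[3:dim(arr)[1], , ]
    mb <- matchBlocks(v, BrainVolume(shifted, spacing(v)))
    dx <- round((mb$fx - mb$rx) / spacing(v)[1])
    dy <- round((mb$fy - mb$ry) / spacing(v)[2])
    mode <- function(x) as.numeric(names(which.max(table(x))))
    expect_equal(mode(dx), -2)  # content moved towards lower x
    expect_equal(mode(dy), 0)
    # constant reference has no informative blocks
    flat <- BrainVolume(array(1, c(16, 16, 16)), 12.5)
    expect_error(matchBlocks(flat, flat), "no informative blocks")
    tiny <- BrainVolume(array(rnorm(8), c(2, 2, 2)), 12.5)
    expect_error(matchBlocks(tiny, tiny), "too small")
})

test_that("least-trimmed-squares affine fitting recovers exact and outlier-contaminated fits", {
    set.seed(32)
    truth <- makeAffine(rotation = c(5, -3, 8), scale = 1.07,
                        translation = c(20, -10, 5), center = rep(200, 3))
    P <- matrix(runif(3 * 200, 0, 400), ncol = 3)
    Q <- atlasmap:::applyAffineToPoints(truth@matrix, P)
    fit <- fitAffineLTS(P, Q, 0.5)
    expect_lt(max(abs(fit@matrix - truth@matrix)), 1e-8)
    # identity-generated pairs give the identity
    expect_lt(max(abs(fitAffineLTS(P, P, 0.5)@matrix - diag(4))), 1e-8)
    # 30% gross outliers, trimming at 50%
    Qc <- Q
    bad <- sample(nrow(Q), 60)
    Qc[bad, ] <- Qc[bad, ] + matrix(runif(180, 100, 500), ncol = 3)
    fit2 <- fitAffineLTS(P, Qc, 0.5)
    expect_lt(max(abs(fit2@matrix - truth@matrix)), 1e-6)
    expect_error(fitAffineLTS(P[1:3, ], Q[1:3, ]), "at least 4")
    Pc <- cbind(runif(10), runif(10), 1)  # coplanar
    expect_error(fitAffineLTS(Pc, Pc), "degenerate")
})

test_that("affine registration is near-identity on self and recovers a known affine", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 33, shape = c(48L, 48L, 48L)),
                             affineParams = list(rotation = c(0, 0, 8),
                                                 scale = 1,
                                                 translationVox = c(3, -2, 1)),
                             ffdParams = list(gridSpacingVox = 16,
                                              maxDispVox = 0))
    self <- registerAffine(pair$fixed, pair$fixed)
    expect_lt(cornerErrorVox(self, affineTransform(), dim(pair$fixed),
                             spacing(pair$fixed)), 0.5)
    aff <- registerAffine(pair$moving, pair$fixed)
    expect_lt(cornerErrorVox(aff, pair$trueAffine, dim(pair$moving),
                             spacing(pair$moving)), 1)
})

test_that("affine registration is symmetric under swapping of the inputs", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 34, shape = c(48L, 48L, 48L)),
                             affineParams = list(rotation = c(3, -2, 5),
                                                 scale = 1.04,
                                                 translationVox = c(2, 1, -2)),
                             ffdParams = list(gridSpacingVox = 16,
                                              maxDispVox = 0))
    fwd <- registerAffine(pair$moving, pair$fixed)
    bwd <- registerAffine(pair$fixed, pair$moving)
    expect_lt(cornerErrorVox(fwd, invertAffine(bwd), dim(pair$moving),
                             spacing(pair$moving)), 1)
})
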