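test_that("label smoothing de-jitters borders without mixing ids", {
    lv <- LabelVolume(array(sample(c(0L, 1L, 2L), 10^3, TRUE), c(10, 10, 10)),
                      12.5)
    expect_identical(smoothLabels(lv, 0.5, 0L), lv)
    # single-voxel island of id 7 inside a large id-3 region is removed:
    # the smoothed indicator of 7 has less mass than 3 at that voxel
    L <- array(3L, c(12, 12, 12)); L[6, 6, 6] <- 7L
    sl <- smoothLabels(LabelVolume(L, 12.5,
              labelTable = data.frame(id = c(3L, 7L),
                                      acronym = c("TH", "VPM"))), 0.5, 2L)
    expect_equal(labelData(sl)[6, 6, 6], 3L)
    expect_true(all(labelData(sl) == 3L))
    # half-space split: interiors untouched, only the boundary layer may move
    H <- array(1L, c(12, 12, 12)); H[7:12, , ] <- 2L
    sh <- smoothLabels(LabelVolume(H, 12.5), 0.5, 2L)
    expect_true(all(labelData(sh)[1:5, , ] == 1L))
    expect_true(all(labelData(sh)[8:12, , ] == 2L))
    # idempotent on thick structures
    sh2 <- smoothLabels(sh, 0.5, 2L)
    expect_identical(labelData(sh2), labelData(sh))
})

test_that("propagation through ground-truth transforms reproduces the oracle labels", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 51))
    lab <- propagateLabels(pair$fixedLabels, pair$trueAffine, pair$trueFFD,
                           pair$moving)
    d <- labelDice(lab, pair$deformedLabels)
    expect_gte(stats::median(d), 0.99)
    expect_true(all(unique(as.vector(labelData(lab))) %in%
                    c(0L, labelTable(pair$fixedLabels)$id)))
    # identity transforms only resample onto the reference grid
    lab2 <- propagateLabels(pair$fixedLabels, affineTransform(), NULL,
                            pair$fixed, smoothPasses = 0L)
    expect_identical(labelData(lab2), labelData(pair$fixedLabels))
})

test_that("coronal outline extraction matches analytic sections", {
    ph <- makePhantom(smallPhantomSpec(seed = 52))
    # VPM is a sphere of radius 5 voxels; its central section is a disk
    ctr <- (dim(ph$labels) - 1) / 2 + c(-8, 4, -2)
    zc <- round(ctr[3]) + 1L
    masks <- extractOutline(ph$labels, 4L, c(zc, zc))
    expect_equal(sum(pixels(masks[[1]])), pi * 25, tolerance = 0.1)
    # a 40-plane window yields 40 masks (padded window on a larger phantom)
    ph2 <- makePhantom(phantomSpec(shape = c(24L, 24L, 48L), seed = 52,
               structures = list(list(id = 1L, acronym = "CTX",
                   type = "shell", center = c(0, 0, 0), semi = c(10, 10, 20),
                   inner = c(7, 7, 16), intensity = 140))))
    m40 <- extractOutline(ph2$labels, 1L, c(5, 44))
    expect_length(m40, 40)
    # plane outside the structure is empty-flagged
    far <- extractOutline(ph$labels, 4L, c(1, 1))
    expect_true(far[[1]]@empty)
    expect_error(extractOutline(ph$labels, 99L, c(1, 2)), "unknown structure")
    expect_error(extractOutline(ph$labels, 4L, c(0, 2)), "window")
})

test_that("best-plane selection maximizes Dice with a deterministic tie-break", {
    cons <- diskMask(64, 12, px = 4)
    # shrinking disks across z: the matching radius wins
    cands <- lapply(1:6, function(i) diskMask(64, 16 - 2 * i, px = 4, z = i))
    bp <- bestPlane(cands, cons)
    expect_equal(bp$zIndex, 2L)  # radius 12 at z = 2
    expect_equal(bp$dice, 1)
    # exact match returns dice 1 at that plane
    expect_equal(bestPlane(list(diskMask(64, 12, px = 4, z = 17)), cons)$dice, 1)
    # two equal-Dice planes: lowest z wins
    tie <- list(diskMask(64, 10, px = 4, z = 9), diskMask(64, 10, px = 4, z = 4))
    expect_equal(bestPlane(tie, cons)$zIndex, 4L)
    # all-empty candidates are flagged
    empty <- list(Mask2D(matrix(FALSE, 64, 64), 4, 3L))
    bp2 <- bestPlane(empty, cons)
    expect_true(bp2$allEmpty)
    expect_equal(bp2$dice, 0)
})

test_that("running outlines against their own source section scores dice 1", {
    ph <- makePhantom(smallPhantomSpec(seed = 53))
    ctr <- (dim(ph$labels) - 1) / 2 + c(-8, 4, -2)
    zc <- round(ctr[3]) + 1L
    truth <- extractOutline(ph$labels, 4L, c(zc, zc))[[1]]
    cands <- extractOutline(ph$labels, 4L, c(zc - 3L, zc + 3L))
    bp <- bestPlane(cands, truth)
    expect_equal(bp$dice, 1)
    # the sphere is symmetric about a half-integer section, so the two
    # central planes tie at dice 1 and the lower z wins
    expect_true(bp$zIndex %in% c(zc - 1L, zc))
})

test_that("mask resampling maps between pixel grids consistently", {
    m <- diskMask(32, 10, px = 12.5)
    hi <- resampleMask(m, 4)
    expect_equal(pixelSize(hi), 4)
    # area is conserved up to boundary discretization
    expect_equal(sum(pixels(hi)) * 16, sum(pixels(m)) * 12.5^2,
                 tolerance = 0.05)
    back <- resampleMask(hi, 12.5, dim(m))
    expect_gt(diceScore(back, m), 0.98)
})
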