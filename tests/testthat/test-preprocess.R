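test_that("z-smoothing follows the discrete Gaussian kernel", {
    set.seed(21)
    v <- BrainVolume(array(rnorm(6^3), c(6, 6, 6)), 12.5)
    expect_identical(smoothZ(v, 0), v)
    expect_error(smoothZ(v, -1), "non-negative")
    cv <- BrainVolume(array(3.7, c(8, 8, 32)), 12.5)
    expect_equal(voxelData(smoothZ(cv, 5)), voxelData(cv), tolerance = 1e-12)
    # unit impulse at the centre of a long 1x1xN line reproduces the
    # normalized kernel evaluated directly
    imp <- array(0, c(1, 1, 65)); imp[1, 1, 33] <- 1
    sm <- smoothZ(BrainVolume(imp, 12.5), 5)
    r <- ceiling(4 * 5)
    k <- exp(-0.5 * ((-r:r) / 5)^2); k <- k / sum(k)
    expect_equal(voxelData(sm)[1, 1, (33 - r):(33 + r)], k, tolerance = 1e-12)
    # smoothing only acts along z
    ximp <- array(0, c(65, 1, 1)); ximp[33, 1, 1] <- 1
    expect_equal(voxelData(smoothZ(BrainVolume(ximp, 1), 5)), ximp)
})

test_that("z-smoothing preserves interior mean intensity", {
    set.seed(22)
    v <- BrainVolume(array(50 + rnorm(16 * 16 * 48), c(16, 16, 48)), 12.5)
    sm <- smoothZ(v, 5)
    interior <- voxelData(sm)[, , 21:28]
    expect_equal(mean(interior), mean(voxelData(v)[, , 21:28]),
                 tolerance = 1e-2)
    # constant-padded volume: interior mean exact to 1e-6 relative
    cpad <- array(7, c(8, 8, 64))
    smc <- smoothZ(BrainVolume(cpad, 12.5), 5)
    expect_equal(mean(voxelData(smc)[, , 25:40]) / 7, 1, tolerance = 1e-6)
})

test_that("isotropic resampling preserves grids, constants and ramps", {
    set.seed(23)
    v <- BrainVolume(array(rnorm(12^3), c(12, 12, 12)), 12.5)
    same <- resampleIsotropic(v, 12.5)
    expect_equal(dim(same), dim(v))
    expect_equal(voxelData(same), voxelData(v), tolerance = 1e-9)
    cv <- BrainVolume(array(2.5, c(10, 10, 10)), 5)
    expect_equal(as.numeric(voxelData(resampleIsotropic(cv, 12.5))),
                 rep(2.5, prod(dim(resampleIsotropic(cv, 12.5)))),
                 tolerance = 1e-9)
    # linear ramp along x keeps its world-space slope at voxel centres
    ramp <- BrainVolume(array(rep(0:15, 16 * 16) * 2, c(16, 16, 16)), 10)
    rs <- resampleIsotropic(ramp, 20)
    xw <- (seq_len(dim(rs)[1]) - 1) * 20
    expect_equal(voxelData(rs)[2:7, 4, 4], 0.2 * xw[2:7], tolerance = 1e-2)
    expect_warning(resampleIsotropic(cv, 2), "upsampling")
})

test_that("resampling reproduces the source bounding box within one voxel", {
    set.seed(24)
    v <- BrainVolume(array(rnorm(20 * 14 * 9), c(20, 14, 9)),
                     c(2, 3, 10), c(5, -5, 40))
    rs <- suppressWarnings(resampleIsotropic(v, 6))  # in-plane upsampling
    srcExtent <- (dim(v) - 1) * spacing(v)
    outExtent <- (dim(rs) - 1) * spacing(rs)
    expect_true(all(abs(srcExtent - outExtent) <= 6))
    expect_equal(origin(rs), origin(v))
})

test_that("affine volume resampling follows the pull-back convention", {
    set.seed(25)
    a <- array(rnorm(10^3), c(10, 10, 10))
    v <- BrainVolume(a, 12.5)
    idm <- applyTransform(v, affineTransform(), v, "nearest")
    expect_equal(voxelData(idm), a)
    expect_equal(voxelData(applyTransform(v, affineTransform(), v, "linear")),
                 a, tolerance = 1e-9)
    # one-voxel translation along x: out(i) = v(i + 1)
    m <- diag(4); m[1, 4] <- 12.5
    out <- applyTransform(v, affineTransform(m), v, "nearest")
    expect_equal(voxelData(out)[1:9, , ], a[2:10, , ])
    expect_equal(voxelData(out)[10, , ], matrix(0, 10, 10))  # pad value
    sing <- diag(4); sing[2, 2] <- 0
    expect_error(applyTransform(v, affineTransform(sing), v), "invertible")
})

test_that("nearest-neighbour resampling cannot invent label values", {
    set.seed(26)
    lv <- LabelVolume(array(sample(c(0L, 3L, 7L), 12^3, TRUE), c(12, 12, 12)),
                      12.5)
    ref <- BrainVolume(array(0, c(15, 15, 15)), 10)
    out <- propagateLabels(lv, makeAffine(rotation = c(4, 2, -3),
                                          center = rep(70, 3)),
                           NULL, ref, smoothPasses = 0L)
    expect_true(all(unique(as.vector(labelData(out))) %in% c(0L, 3L, 7L)))
})
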