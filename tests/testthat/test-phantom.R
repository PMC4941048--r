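test_that("phantom generation is deterministic and geometrically exact", {
    a <- makePhantom(smallPhantomSpec(seed = 7))
    b <- makePhantom(smallPhantomSpec(seed = 7))
    expect_identical(voxelData(a$volume), voxelData(b$volume))
    expect_identical(labelData(a$labels), labelData(b$labels))
    expect_identical(landmarks(a$landmarks), landmarks(b$landmarks))
    c <- makePhantom(smallPhantomSpec(seed = 8))
    expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
    # noiseless spec gives a piecewise-smooth volume with exact label solids
    spec0 <- smallPhantomSpec(seed = 7)
    spec0$noiseSigma <- 0
    ph0 <- makePhantom(spec0)
    expect_identical(labelData(ph0$labels), labelData(a$labels))
})

test_that("rasterized sphere volumes match the analytic value", {
    for (r in c(10, 12)) {
        spec <- phantomSpec(shape = c(40L, 40L, 40L), seed = 1,
            structures = list(
                list(id = 1L, acronym = "CTX", type = "shell",
                     center = c(0, 0, 0), semi = c(19, 19, 19),
                     inner = c(18, 18, 18), intensity = 140),
                list(id = 2L, acronym = "SPH", type = "ellipsoid",
                     center = c(0, 0, 0), semi = rep(r, 3), intensity = 200)))
        ph <- makePhantom(spec)
        expect_equal(sum(labelData(ph$labels) == 2L), 4 / 3 * pi * r^3,
                     tolerance = 0.02)
    }
    bad <- phantomSpec(shape = c(20L, 20L, 20L), structures = list(
        list(id = 1L, acronym = "CTX", type = "shell", center = c(0, 0, 0),
             semi = c(9, 9, 9), inner = c(7, 7, 7), intensity = 140),
        list(id = 2L, acronym = "OUT", type = "ellipsoid",
             center = c(40, 0, 0), semi = c(2, 2, 2), intensity = 1)))
    expect_error(makePhantom(bad), "outside the volume")
})

test_that("deformed pairs honour their construction guarantees", {
    spec <- smallPhantomSpec(seed = 81)
    # zero-magnitude FFD and identity affine reproduce the fixed volume
    idp <- makeDeformedPair(spec,
        affineParams = list(rotation = c(0, 0, 0), scale = 1,
                            translationVox = c(0, 0, 0)),
        ffdParams = list(gridSpacingVox = 16, maxDispVox = 0))
    expect_equal(voxelData(idp$moving), voxelData(idp$fixed),
                 tolerance = 0.15)  # only the independent noise differs
    expect_identical(labelData(idp$deformedLabels),
                     labelData(idp$fixedLabels))
    # displacement bound and positive Jacobian
    pair <- makeDeformedPair(spec, ffdParams = list(gridSpacingVox = 16,
                                                    maxDispVox = 4))
    maxDispVox <- max(abs(pair$trueFFD@coefficients)) /
        spacing(pair$fixed)[1]
    expect_lte(maxDispVox, 4 + 1e-9)
    expect_true(min(jacobianDeterminants(pair$trueFFD, 2)) > 0)
    # fold-free precondition is enforced
    expect_error(makeDeformedPair(spec, ffdParams = list(gridSpacingVox = 8,
                                                         maxDispVox = 5)),
                 "fold-free")
    # landmarks carried exactly: mapping the deformed landmarks through the
    # true transform reproduces the originals
    dl <- as.matrix(landmarks(pair$deformedLandmarks)[, c("x", "y", "z")])
    fl <- as.matrix(landmarks(pair$fixedLandmarks)[, c("x", "y", "z")])
    expect_lt(max(abs(deformPoints(pair$trueFFD, dl) - fl)), 1e-9 * 1e3)
})

test_that("simulated raters follow the generative model", {
    truth <- diskMask(64, 15)
    perfect <- simulateRaters(truth, 3, pRange = c(1, 1), qRange = c(1, 1),
                              boundaryJitterPx = 0, seed = 82)
    for (r in perfect$raters)
        expect_identical(pixels(r@mask), pixels(truth))
    # Bernoulli-only channel: empirical sensitivity within a binomial CI
    sim <- simulateRaters(truth, 12, pRange = c(0.85, 0.99),
                          qRange = c(0.95, 0.999), seed = 83)
    nfg <- sum(pixels(truth))
    for (j in seq_along(sim$raters)) {
        emp <- sum(pixels(sim$raters[[j]]@mask) & pixels(truth)) / nfg
        ci <- 4 * sqrt(sim$p[j] * (1 - sim$p[j]) / nfg)
        expect_lt(abs(emp - sim$p[j]), ci + 1e-9)
    }
    expect_error(simulateRaters(truth, 3, pRange = c(0, 1.5)), "ranges")
    # same seed reproduces the panel exactly
    sim2 <- simulateRaters(truth, 12, pRange = c(0.85, 0.99),
                           qRange = c(0.95, 0.999), seed = 83)
    expect_identical(pixels(sim$raters[[5]]@mask),
                     pixels(sim2$raters[[5]]@mask))
})

test_that("z-choices follow the requested discrete distribution", {
    truth <- diskMask(32, 8, z = 10L)
    sim <- simulateRaters(truth, 40, zValues = c(9L, 10L, 11L),
                          zProbs = c(0.25, 0.5, 0.25), seed = 84)
    expect_true(all(sim$zChoices %in% 9:11))
    expect_gt(mean(sim$zChoices == 10L), 0.25)
    fixedz <- simulateRaters(truth, 5, seed = 85)
    expect_true(all(fixedz$zChoices == 10L))
})
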