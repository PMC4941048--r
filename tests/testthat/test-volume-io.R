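test_that("NIfTI volumes round-trip with geometry intact", {
    td <- withr::local_tempdir()
    set.seed(5)
    v <- BrainVolume(array(sample(0:4095, 16^3, TRUE), c(16, 16, 16)),
                     c(12.5, 12.5, 12.5), c(100, -50, 0))
    writeVolume(v, file.path(td, "v.nii.gz"))
    v2 <- readVolume(file.path(td, "v.nii.gz"))
    expect_identical(voxelData(v2), voxelData(v))
    expect_equal(spacing(v2), c(12.5, 12.5, 12.5))
    expect_equal(origin(v2), c(100, -50, 0))
})

test_that("NIfTI volumes in a flipped orientation are reoriented on load", {
    td <- withr::local_tempdir()
    a <- array(as.double(1:27), c(3, 3, 3))
    img <- RNifti::asNifti(a)
    m <- diag(c(-1, 1, 1, 1)) # LAS: x axis flipped
    RNifti::qform(img) <- structure(m, code = 2L)
    f <- file.path(td, "flip.nii")
    RNifti::writeNifti(img, f)
    v <- readVolume(f)
    expect_equal(voxelData(v), a[3:1, , ])
})

test_that("TIFF stacks require a sidecar and round-trip bit-exactly", {
    td <- withr::local_tempdir()
    set.seed(6)
    v <- BrainVolume(array(sample(0:65535, 8 * 10 * 40, TRUE), c(8, 10, 40)),
                     c(1, 1, 15))
    f <- file.path(td, "stack.tif")
    writeVolume(v, f)
    v2 <- readVolume(f)
    expect_identical(voxelData(v2), voxelData(v))
    expect_equal(dim(v2)[3], 40L)
    expect_equal(spacing(v2)[3], 15)
    file.remove(paste0(f, ".json"))
    expect_error(readVolume(f), "sidecar")
})

test_that("affine text files round-trip and report malformed lines", {
    td <- withr::local_tempdir()
    f <- file.path(td, "a.txt")
    writeAffine(affineTransform(), f)
    expect_equal(readAffine(f)@matrix, diag(4))
    tr <- diag(4); tr[1, 4] <- 10
    writeAffine(affineTransform(tr), f)
    expect_equal(readAffine(f)@matrix, tr)
    set.seed(7)
    m <- diag(4); m[1:3, ] <- m[1:3, ] + rnorm(12) * 0.3
    writeAffine(affineTransform(m), f)
    expect_lt(max(abs(readAffine(f)@matrix - m)), 1e-12)
    writeLines(c("1 0 0 0", "0 1 zero 0", "0 0 1 0", "0 0 0 1"), f)
    expect_error(readAffine(f), "line 2")
})

test_that("FFD transforms round-trip through NIfTI + sidecar", {
    td <- withr::local_tempdir()
    v <- BrainVolume(array(0, c(12, 12, 12)), 12.5)
    set.seed(8)
    ffd <- identityFFD(v, 50, makeAffine(rotation = c(0, 0, 3)))
    ffd@coefficients[] <- rnorm(length(ffd@coefficients))
    f <- file.path(td, "cpp.nii")
    writeFFD(ffd, f)
    f2 <- readFFD(f)
    expect_equal(f2@coefficients, ffd@coefficients, tolerance = 1e-6)
    expect_identical(f2@refDim, ffd@refDim)
    expect_equal(f2@affine@matrix, ffd@affine@matrix)
})

test_that("mask manifests are cross-checked against files", {
    td <- withr::local_tempdir()
    set.seed(9)
    mf <- data.frame(file = sprintf("m%d.png", 1:3),
                     rater = c("A", "A", "B"), brain = "B1",
                     structure = "ACA", attempt = c(1, 2, 1),
                     z_index = c(12, 13, 12), pixel_size = 4)
    for (i in 1:3)
        writeMask(Mask2D(matrix(runif(400) > 0.5, 20), 4, mf$z_index[i]),
                  file.path(td, mf$file[i]))
    write.csv(mf, file.path(td, "manifest.csv"), row.names = FALSE)
    recs <- readMasks(td)
    expect_length(recs, 3)
    expect_equal(zIndex(recs[[1]]), 12L)
    expect_s4_class(recs[[2]], "RaterSegmentation")
    # file without row
    writeMask(Mask2D(matrix(TRUE, 4, 4), 4, 1), file.path(td, "stray.png"))
    expect_error(readMasks(td), "stray.png")
    file.remove(file.path(td, "stray.png"))
    # row without file
    file.remove(file.path(td, "m2.png"))
    expect_error(readMasks(td), "m2.png")
})

test_that("invalid-flagged manifest rows are excluded but counted", {
    td <- withr::local_tempdir()
    set.seed(10)
    n <- 22; nbad <- 5  # small-scale panel with a few known-bad entries
    mf <- data.frame(file = sprintf("m%02d.png", 1:n),
                     rater = sprintf("R%02d", 1:n), brain = "B1",
                     structure = "SSp", attempt = 1, z_index = 10,
                     pixel_size = 4,
                     invalid = rep(c(1, 0), c(nbad, n - nbad)))
    for (i in 1:n)
        writeMask(Mask2D(matrix(runif(100) > 0.4, 10), 4, 10),
                  file.path(td, mf$file[i]))
    write.csv(mf, file.path(td, "manifest.csv"), row.names = FALSE)
    recs <- readMasks(td)
    expect_length(recs, n - nbad)
    expect_equal(attr(recs, "nInvalid"), nbad)
})

test_that("landmark and score tables round-trip as CSV", {
    td <- withr::local_tempdir()
    lm <- LandmarkSet(data.frame(name = c("frontal middle", "hippocampus middle"),
                                 x = c(1.5, 2.5), y = c(3, 4), z = c(5, 6)))
    writeLandmarks(lm, file.path(td, "lm.csv"))
    expect_equal(landmarks(readLandmarks(file.path(td, "lm.csv"))),
                 landmarks(lm), ignore_attr = TRUE)
    st <- data.frame(brain_id = "B1", structure = "ACA", source = "R01",
                     comparison = "inter", metric = "dice", value = 0.91)
    writeScoreTable(st, file.path(td, "scores.csv"))
    back <- read.csv(file.path(td, "scores.csv"))
    expect_equal(names(back), c("brain_id", "structure", "source",
                                "comparison", "metric", "value"))
    expect_equal(back$value, 0.91)
})

test_that("label volumes round-trip with their label table", {
    td <- withr::local_tempdir()
    set.seed(12)
    lv <- LabelVolume(array(sample(0:3, 8^3, TRUE), c(8, 8, 8)), 12.5,
                      labelTable = data.frame(id = 1:3,
                                              acronym = c("ACA", "VPM", "SUB")))
    writeLabelVolume(lv, file.path(td, "lbl.nii"))
    lv2 <- readLabelVolume(file.path(td, "lbl.nii"))
    expect_identical(labelData(lv2), labelData(lv))
    expect_equal(labelTable(lv2)$acronym, c("ACA", "VPM", "SUB"))
})
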