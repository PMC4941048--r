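test_that("Dice score covers the documented boundary cases", {
    m <- diskMask(32, 8)
    expect_equal(diceScore(m, m), 1)
    a <- Mask2D(matrix(c(rep(TRUE, 8), rep(FALSE, 56)), 8, 8), 4)
    b <- Mask2D(matrix(c(rep(FALSE, 56), rep(TRUE, 8)), 8, 8), 4)
    expect_equal(diceScore(a, b), 0)
    empty <- Mask2D(matrix(FALSE, 8, 8), 4)
    expect_equal(diceScore(empty, empty), 1)  # agreement on absence
    expect_equal(diceScore(a, empty), 0)
    # constructed rectangles: |A| = 100, |B| = 80, |A n B| = 60
    A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
    B <- matrix(FALSE, 20, 20); B[1:10, 5:12] <- TRUE
    expect_equal(diceScore(Mask2D(A, 4), Mask2D(B, 4)), 2 * 60 / 180)
    expect_error(diceScore(m, diskMask(16, 4)), "common pixel grid")
})

test_that("Dice is symmetric and monotone in the intersection", {
    set.seed(71)
    for (i in 1:20) {
        a <- randomMask(16); b <- randomMask(16)
        expect_identical(diceScore(a, b), diceScore(b, a))
    }
    # growing intersection at fixed sizes increases Dice
    base <- matrix(FALSE, 16, 16)
    sizes <- integer(0); vals <- numeric(0)
    for (k in c(2, 4, 6, 8)) {
        A <- base; A[1:8, 1:8] <- TRUE
        B <- base; B[(9 - k):(16 - k), 1:8] <- TRUE
        vals <- c(vals, diceScore(Mask2D(A, 1), Mask2D(B, 1)))
    }
    expect_true(all(diff(vals) > 0))
})

test_that("Hausdorff distance equals hand geometry and brute force", {
    m <- diskMask(32, 8)
    expect_equal(hausdorffDistance(m, m), 0)
    # two single pixels 5 px apart at 4 um/px
    a <- matrix(FALSE, 10, 10); a[2, 2] <- TRUE
    b <- matrix(FALSE, 10, 10); b[7, 2] <- TRUE
    expect_equal(hausdorffDistance(Mask2D(a, 4), Mask2D(b, 4)), 20)
    expect_error(hausdorffDistance(Mask2D(a, 4), Mask2D(matrix(FALSE, 10, 10), 4)),
                 "non-empty")
    set.seed(72)
    for (i in 1:25) {
        x <- randomMask(sample(5:20, 1))
        y <- Mask2D(matrix(stats::runif(prod(dim(x))) < 0.3, nrow(pixels(x))),
                    pixelSize(x))
        if (x@empty || y@empty) next
        expect_equal(hausdorffDistance(x, y), bruteHausdorff(x, y))
    }
})

test_that("Hausdorff is a metric on non-empty masks", {
    set.seed(73)
    for (i in 1:10) {
        ms <- replicate(3, randomMask(12, 0.4), simplify = FALSE)
        if (any(vapply(ms, function(m) m@empty, logical(1)))) next
        d12 <- hausdorffDistance(ms[[1]], ms[[2]])
        d13 <- hausdorffDistance(ms[[1]], ms[[3]])
        d23 <- hausdorffDistance(ms[[2]], ms[[3]])
        expect_identical(d12, hausdorffDistance(ms[[2]], ms[[1]]))
        expect_lte(d13, d12 + d23 + 1e-12)
    }
})

test_that("z-distance tables enumerate all unordered pairs", {
    mk <- function(z) RaterSegmentation(Mask2D(matrix(TRUE, 2, 2), 4, z),
                                        paste0("R", z), "B1", "ACA", 1L)
    zt <- zDistanceTable(lapply(c(10L, 11L, 13L), mk), 15)
    expect_setequal(zt$pairs$distanceUm, c(15, 45, 30))
    expect_equal(zt$medianUm, 30)
    same <- zDistanceTable(lapply(c(7L, 7L, 7L, 7L), mk), 15)
    expect_equal(same$medianUm, 0)
    for (n in c(2, 5, 9))
        expect_equal(nrow(zDistanceTable(lapply(seq_len(n), mk))$pairs),
                     n * (n - 1) / 2)
    expect_error(zDistanceTable(list(mk(1L))), "two records")
    # randomized cross-check against direct double-loop enumeration
    set.seed(74)
    for (i in 1:10) {
        zs <- sample(1:40, sample(3:8, 1), replace = TRUE)
        zt <- zDistanceTable(lapply(as.integer(zs), mk), 15)
        oracle <- c()
        for (a in seq_along(zs)) for (b in seq_along(zs))
            if (a < b) oracle <- c(oracle, abs(zs[a] - zs[b]) * 15)
        expect_equal(sort(zt$pairs$distanceUm), sort(oracle))
        expect_equal(zt$medianUm, stats::median(oracle))
    }
})

test_that("z-window filtering maximizes retained records with low-z tie-break", {
    mk <- function(z) RaterSegmentation(Mask2D(matrix(TRUE, 2, 2), 4, z),
                                        paste0("R", z, stats::runif(1)), "B1",
                                        "ACA", 1L)
    zw <- zWindowFilter(lapply(c(5L, 6L, 7L, 20L), mk), 3)
    expect_equal(zw$keep, c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(zw$windowStart, 5)
    all_in <- zWindowFilter(lapply(c(8L, 9L), mk), 40)
    expect_true(all(all_in$keep))
    # two optimal windows: the lower one is chosen
    tie <- zWindowFilter(lapply(c(1L, 2L, 10L, 11L), mk), 2)
    expect_equal(tie$windowStart, 1)
    # exhaustive-scan oracle on random z-choices
    set.seed(75)
    for (i in 1:10) {
        zs <- sample(1:40, 9, replace = TRUE)
        w <- sample(c(3, 7), 1)
        zw <- zWindowFilter(lapply(as.integer(zs), mk), w)
        best <- max(vapply(1:40, function(s)
            sum(zs >= s & zs <= s + w - 1), integer(1)))
        expect_equal(sum(zw$keep), best)
    }
})

test_that("landmark distances map through transforms and support omissions", {
    pair <- makeDeformedPair(smallPhantomSpec(seed = 76))
    ld <- landmarkDistance(pair$deformedLandmarks, pair$fixedLandmarks,
                           pair$trueAffine, pair$trueFFD)
    expect_lt(max(ld$perLandmark), 1e-6)
    lm1 <- LandmarkSet(data.frame(name = c("a", "b"), x = c(0, 10),
                                  y = c(0, 0), z = c(0, 5)))
    lm2 <- LandmarkSet(data.frame(name = c("a", "b"), x = c(30, 40),
                                  y = c(40, 40), z = c(0, 5)))
    ld2 <- landmarkDistance(lm1, lm2, affineTransform())
    expect_equal(unname(ld2$perLandmark), c(50, 50))
    ld3 <- landmarkDistance(lm1, lm2, affineTransform(), omit = "a")
    expect_equal(ld3$meanUm, 50)
    expect_length(ld3$perLandmark, 1)
    lm3 <- LandmarkSet(data.frame(name = c("a", "c"), x = 1:2, y = 1:2,
                                  z = 1:2))
    expect_error(landmarkDistance(lm1, lm3, affineTransform()), "mismatch")
})

test_that("score panels produce the expected row structure", {
    truth <- diskMask(64, 15)
    sim <- simulateRaters(truth, 5, boundaryJitterPx = 2, attempts = 2L,
                          brainId = "B1", structure = "ACA", seed = 77)
    cons <- staple(lapply(sim$raters, function(r) r@mask))
    tab <- scorePanel(sim$raters, list("B1|ACA" = cons), hausdorff = FALSE)
    # k raters x 2 attempts: 2k inter rows and k intra rows
    expect_equal(sum(tab$comparison == "inter"), 10)
    expect_equal(sum(tab$comparison == "intra"), 5)
    expect_true(all(tab$value >= 0 & tab$value <= 1))
    # first-attempt-only filter halves the inter rows
    tab1 <- scorePanel(sim$raters, list("B1|ACA" = cons),
                       firstAttemptOnly = TRUE, hausdorff = FALSE)
    expect_equal(sum(tab1$comparison == "inter"), 5)
    # a rater with two identical attempts scores intra dice 1
    fixed <- list(
        RaterSegmentation(truth, "RX", "B1", "ACA", 1L),
        RaterSegmentation(truth, "RX", "B1", "ACA", 2L))
    t2 <- scorePanel(fixed, list("B1|ACA" = cons), hausdorff = FALSE)
    expect_equal(t2$value[t2$comparison == "intra"], 1)
    expect_error(scorePanel(sim$raters, list()), "missing consensus")
    # auto rows
    t3 <- scorePanel(fixed, list("B1|ACA" = cons),
                     autoMasks = list("B1|ACA" = truth), hausdorff = FALSE)
    expect_equal(t3$source[t3$comparison == "auto_vs_consensus"], "auto")
})

test_that("median inter-rater Dice decreases with boundary jitter amplitude", {
    truth <- diskMask(64, 15)
    med <- vapply(c(0, 2, 5), function(amp) {
        sim <- simulateRaters(truth, 6, pRange = c(1, 1), qRange = c(1, 1),
                              boundaryJitterPx = amp, seed = 78)
        masks <- lapply(sim$raters, function(r) r@mask)
        pairs <- utils::combn(length(masks), 2)
        stats::median(vapply(seq_len(ncol(pairs)), function(i)
            diceScore(masks[[pairs[1, i]]], masks[[pairs[2, i]]]),
            numeric(1)))
    }, numeric(1))
    expect_true(all(diff(med) < 0))
})

test_that("mask cleaning removes isolated touches only", {
    m <- matrix(FALSE, 64, 64)
    m[20:40, 20:40] <- TRUE   # 441 px structure
    m[3, 3] <- TRUE           # isolated touch
    m[60, 60:62] <- TRUE      # 3 px smudge
    cleaned <- cleanMask(Mask2D(m, 4), 50L)
    expect_equal(sum(pixels(cleaned)), 441)
    expect_true(pixels(cleaned)[25, 25])
    expect_false(pixels(cleaned)[3, 3])
})
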