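# Shared fixture builders; everything is generated in code under fixed seeds.

diskMask <- function(d = 96L, r = 25, center = c((d + 1) / 2, (d + 1) / 2),
                     px = 4, z = 1L) {
    xy <- expand.grid(seq_len(d), seq_len(d))
    Mask2D(matrix((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2 <= r^2,
                  d, d), px, z)
}

randomMask <- function(d, pFore = 0.3, px = 4) {
    Mask2D(matrix(stats::runif(d * d) < pFore, d, d), px, 1L)
}

# maximum corner-mapping discrepancy between two affines, in voxels
cornerErrorVox <- function(a, b, dims, spc, org = c(0, 0, 0)) {
    corners <- as.matrix(expand.grid(c(0, dims[1] - 1), c(0, dims[2] - 1),
                                     c(0, dims[3] - 1)))
    corners <- sweep(sweep(corners, 2, spc, "*"), 2, org, "+")
    pa <- t(a@matrix[1:3, 1:3] %*% t(corners) + a@matrix[1:3, 4])
    pb <- t(b@matrix[1:3, 1:3] %*% t(corners) + b@matrix[1:3, 4])
    max(sqrt(rowSums((pa - pb)^2))) / spc[1]
}

# brute-force Dice by explicit pixel counting (independent of diceScore)
bruteDice <- function(a, b) {
    pa <- pixels(a); pb <- pixels(b)
    inter <- 0; na <- 0; nb <- 0
    for (i in seq_len(nrow(pa))) for (j in seq_len(ncol(pa))) {
        na <- na + pa[i, j]
        nb <- nb + pb[i, j]
        inter <- inter + (pa[i, j] && pb[i, j])
    }
    if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

# brute-force all-pairs Hausdorff (independent of the compiled kernel)
bruteHausdorff <- function(a, b) {
    ca <- which(pixels(a), arr.ind = TRUE) * pixelSize(a)
    cb <- which(pixels(b), arr.ind = TRUE) * pixelSize(b)
    dd <- sqrt(outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2)
    max(max(apply(dd, 1, min)), max(apply(dd, 2, min)))
}

smallPhantomSpec <- function(seed = 1L, shape = c(32L, 32L, 32L))
    phantomSpec(shape = shape, seed = seed)

# fast FFD parameters for small-volume tests
fastFFDParams <- function(...) ffdParams(maxIterPerLevel = 50L, ...)
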