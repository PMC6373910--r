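## Small programmatic fixtures shared across test files.

## compact cell-like background for fast module tests
tinyBackground <- function(seed = 1, shape = c(96L, 96L)) {
    synthBackground(shape = shape, nBlobs = 3L, blobScale = 26,
                    seed = seed)
}

## study-scale background matching the simulation-study conditions
studyBackground <- function(seed) {
    synthBackground(shape = c(200L, 200L), nBlobs = 4L, blobScale = 50,
                    seed = seed)
}

## two-level rectangle image with known ground-truth mask
rectangleImage <- function(shape = c(80L, 80L), fgFraction = 0.7,
                           fg = 200, bg = 10, noiseSd = 2, seed = 1) {
    set.seed(seed)
    img <- matrix(bg, shape[1L], shape[2L])
    nrFg <- round(shape[1L] * fgFraction)
    img[seq_len(nrFg), ] <- fg
    truth <- matrix(FALSE, shape[1L], shape[2L])
    truth[seq_len(nrFg), ] <- TRUE
    img <- img + matrix(rnorm(prod(shape), 0, noiseSd), shape[1L])
    list(image = img, truth = truth)
}

fullMask <- function(img) matrix(TRUE, nrow(img), ncol(img))
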