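test_that("endosome sampling honours the design contract", {
    bg <- tinyBackground(3)
    roi <- segmentRoi(bg)
    set.seed(1)
    specs <- sampleEndosomes(5, 3, roi, s = 100, k = 2)
    expect_identical(nrow(specs), 15L)
    expect_true(all(specs$amplitude == 200))
    ## centers lie on roi pixels
    idx <- cbind(specs$y, specs$x)
    expect_true(all(roiMask(roi)[idx]))
    ## reproducibility under a fixed seed
    set.seed(77); a <- sampleEndosomes(4, 2, roi, 50)
    set.seed(77); b <- sampleEndosomes(4, 2, roi, 50)
    expect_identical(a, b)
    ## impossible designs refused
    tinyRoi <- new("RoiMask", mask = rbind(c(TRUE, TRUE), c(FALSE, FALSE)),
                   source = "thresholded", blurRadius = 3)
    expect_error(sampleEndosomes(5, 1, tinyRoi, 10), "invalid design")
})

test_that("sampled sizes follow the truncated normal size law", {
    set.seed(2)
    specs <- sampleEndosomes(10000, 1, matrix(TRUE, 128, 128), s = 1)
    expect_true(all(specs$gamma > 0.25))
    ## mean 2, sd 0.5 within 3 standard errors
    expect_lt(abs(mean(specs$gamma) - 2), 3 * 0.5 / sqrt(10000))
    expect_lt(abs(sd(specs$gamma) - 0.5), 3 * 0.5 / sqrt(2 * 10000))
})

test_that("rendered fields follow the 2D-Gaussian model", {
    ## pixel-centered spot: peak exactly A
    spec <- data.frame(x = 21, y = 21, gamma = 2, amplitude = 7)
    f <- renderEndosomeField(spec, c(41L, 41L))
    expect_equal(f[21, 21], 7)
    expect_equal(max(f), 7)
    ## additivity of distant spots
    s1 <- data.frame(x = 15, y = 15, gamma = 1.5, amplitude = 3)
    s2 <- data.frame(x = 50, y = 48, gamma = 2.5, amplitude = 5)
    both <- renderEndosomeField(rbind(s1, s2), c(64L, 64L))
    expect_equal(both, renderEndosomeField(s1, c(64L, 64L)) +
                       renderEndosomeField(s2, c(64L, 64L)))
    ## integrated signal matches the closed-form 2 pi A gamma^2
    spec3 <- data.frame(x = 32, y = 32, gamma = 2.2, amplitude = 4)
    f3 <- renderEndosomeField(spec3, c(64L, 64L), full = TRUE)
    expect_equal(sum(f3), 2 * pi * 4 * 2.2^2, tolerance = 0.01)
})

test_that("constant-fluorescence normalization conserves roi mean and variance", {
    set.seed(6)
    for (i in 1:5) {
        bg <- studyBackground(40 + i)
        prep <- prepareBackground(bg, gamma = 2)
        specs <- sampleEndosomes(10, 3, prep$roi, prep$s, k = 2)
        f <- renderEndosomeField(specs, dim(bg))
        sim <- normalizeSimulated(bg, f, prep$roi)
        m <- roiMask(prep$roi)
        expect_equal(mean(sim[m]), mean(bg[m]), tolerance = 1e-9)
        expect_equal(var(sim[m]) / var(bg[m]), 1, tolerance = 1e-6)
    }
    ## zero field: exact identity
    bg <- studyBackground(40)
    roi <- segmentRoi(bg)
    out <- normalizeSimulated(bg, matrix(0, nrow(bg), ncol(bg)), roi)
    expect_equal(out, unclass(bg), ignore_attr = TRUE)
    ## overwhelming field refused
    huge <- matrix(rnorm(length(bg), 0, 10 * sd(bg)), nrow(bg))
    expect_error(normalizeSimulated(bg, huge, roi), "amplitude too large")
})

test_that("synthetic backgrounds are deterministic and segmentable", {
    a <- synthBackground(shape = c(96, 96), nBlobs = 3, blobScale = 26,
                         seed = 5)
    b <- synthBackground(shape = c(96, 96), nBlobs = 3, blobScale = 26,
                         seed = 5)
    expect_identical(a, b)
    expect_true(all(a >= 0 & a <= 65535))
    expect_identical(attr(a, "cellCount"), 3L)
    ## near-noiseless single blob: two-level image recovered
    one <- synthBackground(shape = c(96, 96), nBlobs = 1, blobScale = 45,
                           noiseSd = 1, seed = 8)
    roi <- segmentRoi(one)
    expect_identical(roiSource(roi), "thresholded")
    ## default parameterization thresholds at the first blur radius
    bg <- studyBackground(9)
    expect_identical(segmentRoi(bg)@blurRadius, 3)
})

test_that("simulation study emits the full design grid with zero-count null", {
    bgs <- lapply(1:2, studyBackground)
    tab <- runSimulationStudy(bgs, nPerCell = c(0, 5), k = 2:3,
                              gamma = 2, seed = 3)
    expect_identical(nrow(tab), 2L * 2L * 2L)
    expect_true(all(tab$delta_m[tab$n == 0] == 0))
    expect_true(all(tab$delta_m[tab$n == 5] != 0))
    ## prepared backgrounds can be reused and give one row per order
    prep <- prepareBackground(studyBackground(1), orders = c(3, 4))
    tab2 <- runSimulationStudy(list(prep), nPerCell = 10, k = 2,
                               orders = c(3, 4), seed = 4)
    expect_identical(nrow(tab2), 2L)
    expect_setequal(tab2$order, c(3, 4))
})

test_that("mean response increases with amplitude at fixed count", {
    bgs <- lapply(1:6, studyBackground)
    preps <- lapply(bgs, prepareBackground, gamma = 2)
    tab <- runSimulationStudy(preps, nPerCell = 10, k = 1:3, seed = 5)
    means <- tapply(tab$delta_m, tab$k, mean)
    expect_true(all(diff(means) > 0))
})

test_that("timecourse generator follows flat and sigmoid schedules", {
    flat <- simulateTimecourse(background = studyBackground(51),
                               truth = list(mu0 = 0, Emax = 0,
                                            alpha = 0.5, tHalf = 7),
                               nT = 6, seed = 12)
    expect_true(all(vapply(flat$frames, identical, logical(1),
                           flat$frames[[1]])))
    expect_identical(flat$counts, rep(0L, 6))
    tc <- simulateTimecourse(background = studyBackground(52),
                             nT = 15, seed = 13)
    expect_identical(length(tc$frames), 15L)
    expect_identical(tc$counts[1], 0L)
    expect_true(all(diff(tc$counts) >= 0))
    ser <- computeDeltaM(tc$frames, tc$rois, gamma = 2,
                         Ropt = tc$prep$Ropt)
    ## measured response tracks the scheduled sigmoid
    expect_gt(cor(deltaM(ser), tc$target), 0.9)
})
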