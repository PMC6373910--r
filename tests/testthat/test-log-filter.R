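test_that("kernel has the prescribed size, zero sum and symmetry", {
    for (R in c(0.5, 1, 1.75, 2.5, 5, 10)) {
        k <- buildLogKernel(R)
        w <- kernelMatrix(k)
        expect_identical(nrow(w), as.integer(4 * R) * 2L + 1L)
        expect_identical(ncol(w), nrow(w))
        expect_lt(abs(sum(w)), 1e-9 * max(abs(w)))
        ## rotational / reflection symmetry
        expect_equal(w, t(w))
        expect_equal(w, w[nrow(w):1, ])
        expect_equal(w, w[, ncol(w):1])
        ## positive center lobe: bright spots map to positive peaks
        c0 <- (nrow(w) + 1L) %/% 2L
        expect_gt(w[c0, c0], 0)
    }
    expect_error(buildLogKernel(0), "positive")
    expect_error(buildLogKernel(-2), "positive")
    expect_error(buildLogKernel(NaN), "positive")
})

test_that("compensated kernel annihilates constants and gradients", {
    grad <- outer(seq_len(48), seq_len(48),
                  function(i, j) 1.5 * i - 2.25 * j + 7)
    for (R in c(1, 1.75, 2.5, 5)) {
        k <- buildLogKernel(R)
        h <- (nrow(kernelMatrix(k)) - 1L) %/% 2L
        out <- convolveLoG(matrix(123.4, 48, 48), k)
        expect_lt(max(abs(out)), 1e-9 * 123.4)
        outg <- convolveLoG(grad, k)
        interior <- outg[(h + 1):(48 - h), (h + 1):(48 - h)]
        expect_lt(max(abs(interior)), 1e-9 * max(abs(grad)))
    }
})

test_that("convolution rejects images smaller than the kernel", {
    expect_error(convolveLoG(matrix(0, 5, 5), buildLogKernel(2)),
                 "at least as large")
})

test_that("filtered peak of a rendered Gaussian spot matches the analytic gain", {
    for (g in c(1.5, 2, 3)) for (R in c(1, 1.75, 2.5)) {
        spec <- data.frame(x = 33, y = 33, gamma = g, amplitude = 10)
        spot <- renderEndosomeField(spec, c(65L, 65L), full = TRUE)
        peak <- convolveLoG(spot, buildLogKernel(R))[33, 33] / 10
        expect_equal(peak, amplitudeRatio(g, R), tolerance = 0.05)
    }
})

test_that("amplitude ratio follows 2 g^2 / (g^2 + R^2)^2", {
    expect_equal(amplitudeRatio(2, 0), 0.5)
    expect_equal(amplitudeRatio(2, 2), 0.125)
    ## strictly decreasing in R, vanishing in the limit
    r <- seq(0, 30, by = 0.5)
    v <- amplitudeRatio(2, r)
    expect_true(all(diff(v) < 0))
    expect_lt(v[length(v)], 1e-3)
    expect_error(amplitudeRatio(0, 1), "positive")
    expect_error(amplitudeRatio(-1, 1), "positive")
})

test_that("amplification is scale-invariant and positive", {
    set.seed(7)
    bg <- matrix(rnorm(64 * 64, 100, 5), 64)
    roi <- fullMask(bg)
    lam <- amplification(bg, roi, gamma = 2, R = 1.5)
    expect_gt(lam, 0)
    expect_equal(amplification(3.7 * bg, roi, gamma = 2, R = 1.5), lam)
    expect_error(amplification(matrix(5, 64, 64), roi, 2, 1.5),
                 "degenerate")
})

test_that("scale scan implements the three-decrease stopping rule", {
    set.seed(11)
    bg <- matrix(rnorm(128 * 128), 128)
    sc <- findOptimalScale(bg, fullMask(bg), gamma = 2)
    lam <- sc@lambda
    n <- length(lam)
    expect_true(sc@converged)
    ## the last three steps decrease, and no earlier triple does
    expect_true(all(diff(lam[(n - 3):n]) < 0))
    runs <- sapply(seq_len(n - 3), function(i) all(diff(lam[i:(i + 3)]) < 0))
    expect_false(any(runs[seq_len(n - 4)]))
    expect_equal(optimalScale(sc), sc@scales[which.max(lam)])
    ## grid starts at 1 with step 0.05
    expect_equal(sc@scales[1:3], c(1, 1.05, 1.10))
})

test_that("white-noise optimum matches the closed-form sqrt(3)*gamma limit", {
    set.seed(3)
    bg <- matrix(rnorm(256 * 256), 256)
    roi <- fullMask(bg)
    sc <- findOptimalScale(bg, roi, gamma = 2)
    expect_lt(abs(optimalScale(sc) / (sqrt(3) * 2) - 1), 0.10)
    ## brute-force dense scan oracle around the optimum
    dense <- seq(2.8, 4.2, by = 0.01)
    lamDense <- vapply(dense, function(R)
        amplification(bg, roi, gamma = 2, R = R), numeric(1))
    Rdense <- dense[which.max(lamDense)]
    expect_lt(abs(optimalScale(sc) - Rdense), 0.15)
})

test_that("scan is invariant under multiplicative intensity scaling", {
    set.seed(13)
    bg <- matrix(rnorm(96 * 96, 50, 4), 96)
    roi <- fullMask(bg)
    s1 <- findOptimalScale(bg, roi, gamma = 2)
    s2 <- findOptimalScale(bg * 11, roi, gamma = 2)
    expect_equal(s1@scales, s2@scales)
    expect_equal(s1@lambda, s2@lambda)
    expect_equal(optimalScale(s1), optimalScale(s2))
})
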