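test_that("linear fit matches closed-form least squares", {
    t <- 0:14
    f <- fitLinear(2 * t, t)
    expect_equal(f@slope, 2)
    expect_equal(f@intercept, 0)
    expect_equal(f@r2, 1)
    ## zero total variance: r2 defined as 0
    flat <- fitLinear(rep(3, 10), 0:9)
    expect_equal(flat@slope, 0)
    expect_equal(flat@r2, 0)
    set.seed(21)
    for (i in 1:5) {
        y <- rnorm(12); x <- sort(runif(12, 0, 20))
        mine <- fitLinear(y, x)
        ref <- naiveOLS(y, x)
        expect_equal(mine@slope, ref$slope, tolerance = 1e-10)
        expect_equal(mine@intercept, ref$intercept, tolerance = 1e-10)
        expect_equal(mine@r2, ref$r2, tolerance = 1e-10)
    }
    expect_error(fitLinear(1:2, 0:1), "3 points")
    expect_error(fitLinear(1:5, rep(2, 5)), "equal")
})

test_that("sigmoid fit recovers noiseless efficacy, half-time and slope", {
    t <- 0:14
    y <- sigmoidCurve(t, 0, 16.1, 0.53, 10.4)
    f <- fitSigmoid(y, t)
    expect_equal(f@Emax, 16.1, tolerance = 1e-4)
    expect_equal(f@tHalf, 10.4, tolerance = 1e-4)
    expect_equal(f@alpha, 0.53, tolerance = 1e-4)
    expect_equal(f@r2, 1, tolerance = 1e-8)
    ## midpoint identity of the model curve
    expect_equal(sigmoidCurve(10.4, 0, 16.1, 0.53, 10.4), 16.1 / 2)
    ## r2 recomputed from the returned parameters equals the slot
    mu <- sigmoidCurve(t, f@mu0, f@Emax, f@alpha, f@tHalf)
    r2hand <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
    expect_equal(f@r2, r2hand, tolerance = 1e-10)
    expect_lte(f@r2, 1)
})

test_that("sigmoid recovery is accurate under moderate noise", {
    t <- 0:14
    y0 <- sigmoidCurve(t, 0, 16.1, 0.53, 10.4)
    set.seed(31)
    errs <- replicate(40, {
        f <- fitSigmoid(y0 + rnorm(15, 0, 0.5), t)
        abs(f@Emax - 16.1) / 16.1
    })
    expect_lt(median(errs), 0.10)
})

test_that("time shifts move the half-time and nothing else", {
    t <- 0:14
    y <- sigmoidCurve(t, 1, 8, 0.7, 6)
    f0 <- fitSigmoid(y, t)
    f5 <- fitSigmoid(y, t + 5)
    expect_equal(f5@tHalf - f0@tHalf, 5, tolerance = 1e-5)
    expect_equal(f5@Emax, f0@Emax, tolerance = 1e-5)
    expect_equal(f5@alpha, f0@alpha, tolerance = 1e-5)
})

test_that("quality control classifies by the r2 > 0.5 rule", {
    mk <- function(r2l, r2s) {
        ser <- new("DeltaMSeries", time = 0:4, m = rep(1, 5),
                   deltaM = c(0, 1, 2, 3, 4), nPix = rep(1L, 5),
                   gamma = 2, Ropt = 2, drug = "x", condition = "y")
        qcClassify(new("ExperimentRecord", id = "e", drug = "x",
                       condition = "y", series = ser,
                       linear = new("LinearFit", slope = 0,
                                    intercept = 0, r2 = r2l),
                       sigmoid = new("SigmoidFit", mu0 = 0, Emax = 1,
                                     alpha = 1, tHalf = 1, r2 = r2s,
                                     converged = TRUE),
                       qcPass = FALSE, responderClass = "unclassified"))
    }
    expect_identical(responderClass(mk(0.9, 0.3)), "flat")
    expect_true(qcPass(mk(0.9, 0.3)))
    expect_identical(responderClass(mk(0.2, 0.2)), "excluded")
    expect_false(qcPass(mk(0.2, 0.2)))
    expect_identical(responderClass(mk(0.1, 0.95)), "sigmoid")
})

test_that("responder archetypes classify correctly under noise", {
    t <- 0:14
    damgo <- sigmoidCurve(t, 0, 16.1, 0.53, 10.4)
    set.seed(41)
    clsSig <- replicate(30, responderClass(
        fitExperiment(damgo + rnorm(15, 0, 1.0), t)))
    expect_gte(mean(clsSig == "sigmoid"), 0.9)
    ## a zero-response series must not be called a responder
    clsFlat <- replicate(30, responderClass(
        fitExperiment(rnorm(15, 0, 1.0), t)))
    expect_gte(mean(clsFlat != "sigmoid"), 0.9)
})

test_that("group summaries pool sigmoid responders with SEM", {
    t <- 0:14
    mkRec <- function(id, drug, y) fitExperiment(y, t, id = id,
                                                 drug = drug)
    y <- sigmoidCurve(t, 0, 16.1, 0.53, 10.4)
    set.seed(51)
    recs <- c(lapply(1:6, function(i)
                  mkRec(paste0("d", i), "DAMGO", y + rnorm(15, 0, 1))),
              list(mkRec("s1", "single", y)))
    tab <- summarizeGroups(recs)
    damgoRow <- tab[tab$drug == "DAMGO", ]
    expect_identical(damgoRow$n, 6L)
    ## group mean within 2 SEM of the generating efficacy
    expect_lt(abs(damgoRow$E_max_mean - 16.1), 2 * damgoRow$E_max_sem +
                  1e-9)
    ## single experiment: mean reported, SEM not available
    single <- tab[tab$drug == "single", ]
    expect_equal(single$E_max_mean, 16.1, tolerance = 1e-4)
    expect_true(is.na(single$E_max_sem))
    ## identical duplicates: SEM 0
    dup <- summarizeGroups(list(mkRec("a", "dup", y), mkRec("b", "dup", y)))
    expect_equal(dup$E_max_sem[dup$drug == "dup"], 0, tolerance = 1e-8)
    ## groups without sigmoid responders are dropped with a warning
    expect_warning(
        out <- summarizeGroups(list(mkRec("f1", "flatdrug",
                                          rnorm(15, 0, 0.1)),
                                    mkRec("ok", "good", y))),
        "omitted")
    expect_false("flatdrug" %in% out$drug)
})

test_that("two-group comparison matches the textbook Welch formula", {
    set.seed(61)
    for (i in 1:5) {
        x <- rnorm(12, 1, 2); y <- rnorm(9, 2, 3)
        mine <- compareDeltaM(x, y)
        ref <- naiveWelch(x, y)
        expect_equal(mine$statistic, ref$statistic, tolerance = 1e-10)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    }
    ## identical constant groups: p = 1 by convention
    expect_equal(compareDeltaM(rep(2, 4), rep(2, 5))$p.value, 1)
    ## clear separation
    expect_lt(compareDeltaM(rnorm(4, 0, 1e-3),
                            10 + rnorm(4, 0, 1e-3))$p.value, 1e-3)
    ## pooled variant equals Student's t-test
    x <- rnorm(8); y <- rnorm(8, 1)
    expect_equal(compareDeltaM(x, y, pooled = TRUE)$p.value,
                 t.test(x, y, var.equal = TRUE)$p.value)
})
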