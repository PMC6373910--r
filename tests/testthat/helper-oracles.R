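## Independent reference implementations used as oracles.  These are
## deliberately written as naive loops / textbook formulas, not calls
## into the package internals.

## central moment by an explicit per-pixel triple pass
naiveCentralMoment <- function(image, mask, order) {
    vals <- numeric(0)
    for (j in seq_len(ncol(image))) for (i in seq_len(nrow(image)))
        if (mask[i, j]) vals <- c(vals, image[i, j])
    mu <- sum(vals) / length(vals)
    dev <- numeric(length(vals))
    for (k in seq_along(vals)) dev[k] <- (vals[k] - mu)^order
    sum(dev) / length(vals)
}

## straight-line re-implementation of the histogram-minimum procedure
naiveMinimumThreshold <- function(counts, maxIter = 10000L) {
    h <- as.numeric(counts)
    n <- length(h)
    countMax <- function(v) {
        ## positions of maxima, plateaus once, by explicit scanning
        pos <- integer(0)
        i <- 1L
        while (i <= n) {
            j <- i
            while (j < n && v[j + 1L] == v[i]) j <- j + 1L
            leftUp <- i == 1L || v[i - 1L] < v[i]
            rightUp <- j == n || v[j + 1L] < v[i]
            if (leftUp && rightUp) pos <- c(pos, i, j)
            i <- j + 1L
        }
        matrix(pos, ncol = 2, byrow = TRUE)
    }
    for (iter in seq_len(maxIter)) {
        mx <- countMax(h)
        if (nrow(mx) == 2L) {
            lo <- mx[1L, 2L]; hi <- mx[2L, 1L]
            vals <- h[(lo + 1L):(hi - 1L)]
            return((lo:(hi - 2L))[which.min(vals)] + 1L)
        }
        if (nrow(mx) < 2L) return(NA_integer_)
        sm <- h
        for (i in seq_len(n)) {
            a <- if (i == 1L) h[1L] else h[i - 1L]
            b <- if (i == n) h[n] else h[i + 1L]
            sm[i] <- (a + h[i] + b) / 3
        }
        h <- sm
    }
    NA_integer_
}

## textbook OLS by normal equations
naiveOLS <- function(y, x) {
    xb <- mean(x); yb <- mean(y)
    slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    intercept <- yb - slope * xb
    res <- y - intercept - slope * x
    list(slope = slope, intercept = intercept,
         r2 = 1 - sum(res^2) / sum((y - yb)^2))
}

## textbook Welch statistic and two-sided p-value
naiveWelch <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(statistic = tt, p.value = 2 * pt(-abs(tt), df))
}

## per-pixel loop maximum projection
naiveMaxProject <- function(planes) {
    out <- planes[[1L]]
    for (p in planes[-1L])
        for (j in seq_len(ncol(out))) for (i in seq_len(nrow(out)))
            out[i, j] <- max(out[i, j], p[i, j])
    out
}

sigmoidCurve <- function(t, mu0, Emax, alpha, tHalf) {
    mu0 + Emax / (1 + exp(alpha * (tHalf - t)))
}
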