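#' Build a compensated discrete LoG kernel
#'
#' Samples the Laplacian-of-Gaussian function
#' \deqn{\psi(x, y) = \frac{1}{2\pi R^4}\left(2 - \frac{x^2+y^2}{R^2}\right)
#'   \exp\!\left(-\frac{x^2+y^2}{2R^2}\right)}
#' at integer pixel offsets on a square support of
#' \code{int(4R) * 2 + 1} pixels per side, then subtracts the mean
#' weight from every cell so the discrete sum is exactly zero.  The
#' compensation is what makes the filter annihilate constant and
#' linear-gradient components; the positive center lobe maps bright
#' spots to positive filter responses.
#'
#' @param R scale parameter in pixels, `R > 0`.
#' @return a [LoGKernel-class] object.
#' @examples
#' k <- buildLogKernel(1.75)
#' dim(kernelMatrix(k))   # 15 x 15
#' sum(kernelMatrix(k))   # 0 (compensated)
#' @export
buildLogKernel <- function(R) {
    if (length(R) != 1L || !is.numeric(R) || !is.finite(R) || R <= 0)
        stop("'R' must be a single finite positive number",
             call. = FALSE)
    h <- as.integer(4 * R)
    off <- seq.int(-h, h)
    r2 <- outer(off^2, off^2, `+`)
    w <- (2 - r2 / R^2) * exp(-r2 / (2 * R^2)) / (2 * pi * R^4)
    w <- w - mean(w)
    new("LoGKernel", scaleR = R, weights = w)
}

## Symmetric (half-sample) reflection padding by h pixels on each side.
padReflect <- function(x, h) {
    nr <- nrow(x); nc <- ncol(x)
    if (h >= nr || h >= nc)
        stop("image too small for the requested padding", call. = FALSE)
    ri <- c(h:1, seq_len(nr), nr:(nr - h + 1L))
    ci <- c(h:1, seq_len(nc), nc:(nc - h + 1L))
    if (h == 0L) x else x[ri, ci]
}

#' Convolve an image with a LoG kernel
#'
#' Filters the image with the compensated kernel, handling the border
#' by symmetric reflection so that no artificial edge response skews
#' the moment statistics.  The output has the same dimensions as the
#' input.
#'
#' @param image numeric matrix of pixel intensities.
#' @param kernel a [LoGKernel-class], or a numeric scale `R` from which
#'   one is built.
#' @return numeric matrix of filtered intensities, same size as
#'   `image`.
#' @examples
#' img <- matrix(5, 32, 32)
#' range(convolveLoG(img, buildLogKernel(2)))  # ~0: constants cancel
#' @export
convolveLoG <- function(image, kernel) {
    if (is.numeric(kernel)) kernel <- buildLogKernel(kernel)
    stopifnot(is(kernel, "LoGKernel"))
    image <- asImageMatrix(image)
    w <- kernel@weights
    if (nrow(image) < nrow(w) || ncol(image) < ncol(w))
        stop("image must be at least as large as the kernel",
             call. = FALSE)
    h <- (nrow(w) - 1L) %/% 2L
    padded <- padReflect(image, h)
    out <- EBImage::filter2(padded, w, boundary = "circular")
    out <- out[(h + 1L):(h + nrow(image)), (h + 1L):(h + ncol(image)),
               drop = FALSE]
    unclass(as.matrix(out))
}

#' Analytic LoG amplitude gain for a Gaussian spot
#'
#' Peak response of the continuous LoG filter at scale `R` applied to a
#' 2D-Gaussian spot of size `gamma` and unit amplitude:
#' \deqn{\frac{A'}{A} = \frac{2\gamma^2}{(\gamma^2 + R^2)^2}.}
#'
#' @param gamma spot size (Gaussian standard deviation) in pixels,
#'   `gamma > 0`.
#' @param R LoG scale in pixels, `R >= 0` (`R = 0` gives the unfiltered
#'   limit \eqn{2/\gamma^2}).
#' @return the amplitude ratio, a positive number.
#' @examples
#' amplitudeRatio(2, 0)  # 0.5
#' amplitudeRatio(2, 2)  # 0.125
#' @export
amplitudeRatio <- function(gamma, R) {
    if (any(!is.finite(gamma)) || any(gamma <= 0))
        stop("'gamma' must be positive", call. = FALSE)
    if (any(!is.finite(R)) || any(R < 0))
        stop("'R' must be non-negative", call. = FALSE)
    2 * gamma^2 / (gamma^2 + R^2)^2
}

#' Amplification of a LoG scale on a background image
#'
#' The amplification \eqn{\lambda = (A'/s') / (A/s)} measures how much
#' the filter at scale `R` boosts a Gaussian spot of size `gamma`
#' relative to the background fluctuation: `s` is the standard
#' deviation of the background restricted to the region of interest and
#' `s'` the standard deviation of the filtered background there, while
#' the amplitude gain `A'/A` comes from [amplitudeRatio()].  The scale
#' maximizing lambda gives the best spot signal-to-noise and is the one
#' used to filter every frame.
#'
#' @param background numeric matrix, the pre-drug (t = 0) frame.
#' @param roi [RoiMask-class] or logical matrix over `background`.
#' @param gamma assumed mean spot size in pixels.
#' @param R LoG scale in pixels.
#' @return lambda, a positive number.
#' @export
amplification <- function(background, roi, gamma, R) {
    background <- asImageMatrix(background)
    mask <- asRoiLogical(roi, dim(background))
    filtered <- convolveLoG(background, buildLogKernel(R))
    s <- stats::sd(background[mask])
    sp <- stats::sd(filtered[mask])
    if (!is.finite(sp) || s == 0 || sp <= 1e-12 * s)
        stop("degenerate background: filtered standard deviation is zero",
             call. = FALSE)
    amplitudeRatio(gamma, R) * s / sp
}

#' Select the amplification-optimal LoG scale
#'
#' Evaluates the amplification lambda along the scale grid
#' `R = 1.00, 1.05, 1.10, ...` and stops after three consecutive
#' decreasing lambda values (or at the hard cap `Rmax`, returning the
#' best scale seen so far with a warning).  The optimum is the scanned
#' scale with maximal lambda, the smallest such scale on ties.
#'
#' @inheritParams amplification
#' @param step scan increment in pixels (default 0.05).
#' @param Rmax hard scan cap in pixels (default 10).
#' @return a [ScaleScan-class] object.
#' @examples
#' set.seed(1)
#' bg <- matrix(rnorm(128 * 128), 128)
#' sc <- findOptimalScale(bg, matrix(TRUE, 128, 128), gamma = 2)
#' optimalScale(sc)   # close to sqrt(3) * gamma
#' @export
findOptimalScale <- function(background, roi, gamma, step = 0.05,
                             Rmax = 10) {
    background <- asImageMatrix(background)
    mask <- asRoiLogical(roi, dim(background))
    if (!is.finite(gamma) || gamma <= 0)
        stop("'gamma' must be positive", call. = FALSE)
    s <- stats::sd(background[mask])
    scales <- numeric()
    lambdas <- numeric()
    decreases <- 0L
    R <- 1
    converged <- FALSE
    i <- 0L
    while (R <= Rmax + 1e-9) {
        filtered <- convolveLoG(background, buildLogKernel(R))
        sp <- stats::sd(filtered[mask])
        if (!is.finite(sp) || s == 0 || sp <= 1e-12 * s)
            stop("degenerate background: filtered standard deviation is zero",
                 call. = FALSE)
        lam <- amplitudeRatio(gamma, R) * s / sp
        scales <- c(scales, R)
        lambdas <- c(lambdas, lam)
        n <- length(lambdas)
        if (n > 1L)
            decreases <- if (lambdas[n] < lambdas[n - 1L])
                decreases + 1L else 0L
        if (decreases >= 3L) {
            converged <- TRUE
            break
        }
        i <- i + 1L
        R <- 1 + i * step
    }
    if (!converged)
        warning("scale scan reached the hard cap R = ", Rmax,
                " without three consecutive decreasing lambda values; ",
                "returning the best scale seen", call. = FALSE)
    new("ScaleScan", gamma = gamma, scales = scales, lambda = lambdas,
        Ropt = scales[which.max(lambdas)], converged = converged)
}

## internal: coerce to a plain numeric matrix with finite entries
asImageMatrix <- function(x) {
    if (is(x, "Image")) x <- EBImage::imageData(x)
    if (!is.matrix(x) || !is.numeric(x))
        stop("image must be a numeric matrix", call. = FALSE)
    if (nrow(x) < 1L || ncol(x) < 1L || any(!is.finite(x)))
        stop("image must be non-empty with finite intensities",
             call. = FALSE)
    x
}

## internal: coerce RoiMask / logical matrix to logical mask, checked
asRoiLogical <- function(roi, dims) {
    m <- if (is(roi, "RoiMask")) roi@mask else roi
    if (!is.logical(m) || !is.matrix(m))
        stop("roi must be a RoiMask or a logical matrix", call. = FALSE)
    if (!identical(dim(m), as.integer(dims)))
        stop("roi dimensions do not match the image", call. = FALSE)
    if (!any(m))
        stop("roi is empty", call. = FALSE)
    m
}
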