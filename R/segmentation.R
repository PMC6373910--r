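#' Minimum-algorithm histogram threshold
#'
#' The classic bimodal-valley threshold: the histogram is repeatedly
#' smoothed with a 3-point moving average (edge bins replicated) until
#' exactly two local maxima remain, and the threshold is the minimum
#' bin strictly between them.  Runs of equal bins forming a plateau
#' count as a single maximum; ties in the valley take the lowest bin
#' index.  A histogram that becomes unimodal before ever being bimodal,
#' or fails to reach bimodality within `maxIter` smoothing passes,
#' yields `found = FALSE` — a signal (not an error) that drives the
#' blur-escalation loop in [segmentRoi()].
#'
#' @param counts non-negative histogram bin counts (>= 3 bins).
#' @param maxIter smoothing-iteration cap (default 10000).
#' @return list with elements `found` (logical), `index` (threshold bin
#'   index, `NA` when not found) and `iterations`.
#' @examples
#' minimumThreshold(c(0, 9, 1, 0, 1, 9, 0))$index  # bin 4 (the valley)
#' @export
minimumThreshold <- function(counts, maxIter = 10000L) {
    if (length(counts) < 3L || any(counts < 0) || any(!is.finite(counts)))
        stop("'counts' must be >= 3 finite non-negative bin counts",
             call. = FALSE)
    if (sum(counts > 0) < 2L)
        stop("histogram must have at least 2 nonzero bins", call. = FALSE)
    h <- as.numeric(counts)
    n <- length(h)
    for (iter in seq_len(maxIter)) {
        maxima <- plateauMaxima(h)
        if (length(maxima) == 2L) {
            lo <- maxima[[1L]][length(maxima[[1L]])]
            hi <- maxima[[2L]][1L]
            between <- seq.int(lo + 1L, hi - 1L)
            valley <- between[which.min(h[between])]
            return(list(found = TRUE, index = valley, iterations = iter))
        }
        if (length(maxima) < 2L)
            return(list(found = FALSE, index = NA_integer_,
                        iterations = iter))
        h <- (c(h[1L], h[-n]) + h + c(h[-1L], h[n])) / 3
    }
    list(found = FALSE, index = NA_integer_, iterations = maxIter)
}

## internal: indices of local maxima, plateau runs counted once.
## Returns a list of index runs (each run = the bins of one maximum).
plateauMaxima <- function(h) {
    r <- rle(h)
    k <- length(r$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (i in seq_len(k)) {
        leftOK <- i == 1L || r$values[i - 1L] < r$values[i]
        rightOK <- i == k || r$values[i + 1L] < r$values[i]
        if (leftOK && rightOK)
            out[[length(out) + 1L]] <- seq.int(starts[i], ends[i])
    }
    out
}

#' Segment the region of interest of a frame
#'
#' Finds the pixels covering cells.  The frame is Gaussian-blurred at
#' radius 3 px (the radius is interpreted as the Gaussian standard
#' deviation), a 256-bin histogram of the blurred intensities is
#' thresholded with [minimumThreshold()], and the region of interest is
#' the set of blurred pixels strictly above the threshold.  If no
#' threshold is found, or the region covers less than half the image,
#' the blur radius is increased by one pixel and the procedure retried
#' up to radius 10; if still unresolved the whole image is used
#' (`source = "whole_image"`).
#'
#' @param image numeric matrix.
#' @param blurStart,blurMax first and last Gaussian blur radius tried,
#'   in pixels (defaults 3 and 10).
#' @param minFraction minimum fraction of image pixels the region must
#'   cover (default 0.5).
#' @param bins histogram bin count (default 256).
#' @return a [RoiMask-class] object.
#' @export
segmentRoi <- function(image, blurStart = 3, blurMax = 10,
                       minFraction = 0.5, bins = 256L) {
    image <- asImageMatrix(image)
    npix <- length(image)
    for (r in seq(blurStart, blurMax)) {
        blurred <- gaussianBlur(image, r)
        rng <- range(blurred)
        ## guard against numerical ripple on (near-)constant images
        if (diff(rng) <= 1e-9 * max(abs(rng))) next
        breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
        idx <- .bincode(blurred, breaks, include.lowest = TRUE)
        cnt <- tabulate(idx, nbins = bins)
        if (sum(cnt > 0) < 2L) next
        thr <- minimumThreshold(cnt)
        if (!thr$found) next
        cut <- (breaks[thr$index] + breaks[thr$index + 1L]) / 2
        mask <- matrix(blurred > cut, nrow(image), ncol(image))
        if (sum(mask) >= minFraction * npix)
            return(new("RoiMask", mask = mask, source = "thresholded",
                       blurRadius = as.numeric(r)))
    }
    new("RoiMask", mask = matrix(TRUE, nrow(image), ncol(image)),
        source = "whole_image", blurRadius = NA_real_)
}

## internal: Gaussian blur with reflected borders (sigma in pixels)
gaussianBlur <- function(image, sigma) {
    h <- 2L * as.integer(ceiling(3 * sigma)) + 1L
    half <- (h - 1L) %/% 2L
    half <- min(half, nrow(image) - 1L, ncol(image) - 1L)
    g <- stats::dnorm(seq.int(-half, half), sd = sigma)
    w <- outer(g, g)
    w <- w / sum(w)
    padded <- padReflect(image, half)
    out <- EBImage::filter2(padded, w, boundary = "circular")
    unclass(as.matrix(out))[(half + 1L):(half + nrow(image)),
                            (half + 1L):(half + ncol(image)),
                            drop = FALSE]
}

#' Harmonize regions of interest across a time series
#'
#' Segmentation inconsistencies between frames would inject spurious
#' moment variation, so the per-frame regions are reconciled against
#' the minimum-area region \eqn{B_{min}} of the series: any region
#' whose symmetric difference with \eqn{B_{min}} exceeds `tolerance`
#' (default 5%) of the total image pixels is replaced by
#' \eqn{B_{min}}; the rest are kept as segmented.
#'
#' @param rois list of [RoiMask-class] objects of equal dimensions.
#' @param tolerance maximal allowed symmetric difference, as a fraction
#'   of total image pixels (default 0.05).
#' @return list of [RoiMask-class] objects, same length.
#' @export
harmonizeRois <- function(rois, tolerance = 0.05) {
    if (!is.list(rois) || length(rois) < 1L)
        stop("'rois' must be a non-empty list", call. = FALSE)
    stopifnot(all(vapply(rois, is, logical(1), "RoiMask")))
    dims <- lapply(rois, function(r) dim(r@mask))
    if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
        stop("all rois must have identical dimensions", call. = FALSE)
    areas <- vapply(rois, function(r) sum(r@mask), integer(1))
    bmin <- rois[[which.min(areas)]]
    npix <- length(bmin@mask)
    lapply(rois, function(r) {
        if (sum(xor(r@mask, bmin@mask)) > tolerance * npix)
            new("RoiMask", mask = bmin@mask,
                source = "replaced_by_Bmin", blurRadius = NA_real_)
        else r
    })
}
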