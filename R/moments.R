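#' Central moment of an image over a region of interest
#'
#' Computes \deqn{m = \frac{1}{n_{pix}} \sum_{x \in B} (I(x) - \bar I)^k}
#' where the mean \eqn{\bar I} is taken over the same region-of-interest
#' pixels.  Order 3 is the package's response statistic (bright spots
#' skew the filtered-intensity histogram to the right); orders 2 and 4
#' are provided for the moment-order comparison.
#'
#' @param image numeric matrix.
#' @param roi [RoiMask-class] or logical matrix over `image`.
#' @param order moment order, one of 2, 3 or 4 (default 3).
#' @return the central moment, a single number.
#' @examples
#' img <- matrix(c(0, 0, 0, 3), 2)
#' centralMoment(img, matrix(TRUE, 2, 2), order = 3)  # 2.53125
#' @export
centralMoment <- function(image, roi, order = 3L) {
    image <- asImageMatrix(image)
    mask <- asRoiLogical(roi, dim(image))
    if (length(order) != 1L || !order %in% 2:4)
        stop("'order' must be 2, 3 or 4", call. = FALSE)
    v <- image[mask]
    mu <- sum(v) / length(v)
    sum((v - mu)^order) / length(v)
}

#' Relative moment increment
#'
#' The response statistic \eqn{\Delta m_t = (m_t - m_0)/m_0}.  The
#' baseline moment must be bounded away from zero: a vanishing
#' \eqn{m_0} (flat or perfectly symmetric baseline) leaves the relative
#' increment undefined.
#'
#' @param m_t moment at time t.
#' @param m_0 baseline moment (t = 0).
#' @param eps degeneracy guard: an error is raised when
#'   `abs(m_0) <= eps`.  The natural scale for `eps` is 1e-12 times the
#'   cube of the image intensity scale.
#' @return `(m_t - m_0) / m_0`.
#' @export
relativeIncrement <- function(m_t, m_0, eps = 1e-12) {
    if (!is.finite(m_0) || abs(m_0) <= eps)
        stop("degenerate baseline: |m_0| <= ", format(eps),
             " (flat or symmetric baseline image)", call. = FALSE)
    (m_t - m_0) / m_0
}

#' Compute the response series of a time-course experiment
#'
#' Runs the core quantification over an ordered set of frames: the
#' amplification-optimal LoG scale is selected once on the pre-drug
#' frame (frame 1) and its region of interest, every frame is filtered
#' at that single scale, the third central moment \eqn{m_t} is taken
#' over each frame's region of interest, and the relative increments
#' \eqn{\Delta m_t} are formed against the baseline moment
#' (\eqn{\Delta m_0 = 0} exactly).
#'
#' @param frames list of numeric matrices, frame 1 = pre-drug baseline.
#' @param rois list of [RoiMask-class] (or logical matrices), one per
#'   frame, typically from [segmentRoi()] + [harmonizeRois()].
#' @param gamma assumed mean spot size in pixels (default 2).
#' @param Ropt optional fixed LoG scale; when `NULL` (default) the
#'   scale is selected with [findOptimalScale()] on frame 1.
#' @param time frame times in minutes (default `0, 1, ...`, one frame
#'   per minute).
#' @param drug,condition labels carried into the result.
#' @param order moment order (default 3, the response statistic).
#' @return a [DeltaMSeries-class] object.
#' @export
computeDeltaM <- function(frames, rois, gamma = 2, Ropt = NULL,
                          time = NULL, drug = NA_character_,
                          condition = NA_character_, order = 3L) {
    if (!is.list(frames) || length(frames) < 1L)
        stop("'frames' must be a non-empty list of matrices",
             call. = FALSE)
    if (!is.list(rois) || length(rois) != length(frames))
        stop("'rois' must be a list matching 'frames'", call. = FALSE)
    frames <- lapply(frames, asImageMatrix)
    masks <- mapply(function(r, f) asRoiLogical(r, dim(f)), rois, frames,
                    SIMPLIFY = FALSE)
    if (is.null(time)) time <- seq_along(frames) - 1
    if (is.null(Ropt)) {
        scan <- findOptimalScale(frames[[1L]], masks[[1L]], gamma)
        Ropt <- scan@Ropt
    }
    kernel <- buildLogKernel(Ropt)
    m <- vapply(seq_along(frames), function(i) {
        centralMoment(convolveLoG(frames[[i]], kernel), masks[[i]],
                      order = order)
    }, numeric(1))
    eps <- 1e-12 * max(diff(range(frames[[1L]]))^3,
                       .Machine$double.xmin)
    dm <- vapply(m, relativeIncrement, numeric(1), m_0 = m[1L],
                 eps = eps)
    dm[1L] <- 0
    new("DeltaMSeries", time = as.numeric(time), m = m, deltaM = dm,
        nPix = vapply(masks, sum, integer(1)), gamma = gamma,
        Ropt = Ropt, drug = drug, condition = condition)
}
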