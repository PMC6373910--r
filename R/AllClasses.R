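#' @import methods
NULL

#' Discrete Laplacian-of-Gaussian kernel
#'
#' A compensated (zero-sum) sample of the LoG function
#' \deqn{\psi(x, y) = \frac{1}{2\pi R^4}\left(2 - \frac{x^2+y^2}{R^2}\right)
#'   \exp\!\left(-\frac{x^2+y^2}{2R^2}\right)}
#' at integer pixel offsets, on a square support of
#' \code{int(4R) * 2 + 1} pixels per side.  The mean weight is subtracted
#' from every cell so the discrete sum is exactly zero: the filter then
#' annihilates constants and linear gradients, and amplifies centrally
#' symmetric spots.
#'
#' @slot scaleR scale parameter \eqn{R > 0} in pixels.
#' @slot weights square numeric matrix of kernel weights, odd side.
#'
#' @seealso [buildLogKernel()], [convolveLoG()]
#' @export
setClass("LoGKernel",
    representation(scaleR = "numeric", weights = "matrix"),
    validity = function(object) {
        msg <- character()
        R <- object@scaleR
        w <- object@weights
        if (length(R) != 1L || !is.finite(R) || R <= 0)
            msg <- c(msg, "scaleR must be a single finite positive number")
        if (nrow(w) != ncol(w))
            msg <- c(msg, "kernel must be square")
        if (nrow(w) %% 2L != 1L)
            msg <- c(msg, "kernel side must be odd")
        if (length(R) == 1L && is.finite(R) && R > 0 &&
            nrow(w) != as.integer(4 * R) * 2L + 1L)
            msg <- c(msg, "kernel side must equal int(4R)*2 + 1")
        if (abs(sum(w)) > 1e-9 * max(abs(w)))
            msg <- c(msg, "kernel weights must sum to zero (compensated)")
        if (length(msg)) msg else TRUE
    })

#' Amplification scan over LoG scales
#'
#' Record of the scale search: the amplification
#' \eqn{\lambda(R) = (A'/s')/(A/s)} evaluated along the grid
#' \eqn{R = 1.00, 1.05, 1.10, \ldots}, stopped after three consecutive
#' decreasing values, and the maximizing scale \eqn{R_{opt}}.
#'
#' @slot gamma assumed mean spot size in pixels.
#' @slot scales scanned scales (strictly increasing).
#' @slot lambda amplification at each scanned scale.
#' @slot Ropt scale maximizing lambda (smallest on ties).
#' @slot converged `TRUE` when the three-decrease stopping rule fired
#'   before the hard scan cap.
#'
#' @seealso [findOptimalScale()]
#' @export
setClass("ScaleScan",
    representation(gamma = "numeric", scales = "numeric",
                   lambda = "numeric", Ropt = "numeric",
                   converged = "logical"),
    validity = function(object) {
        msg <- character()
        if (length(object@scales) != length(object@lambda))
            msg <- c(msg, "scales and lambda must have equal length")
        if (length(object@scales) > 1L && any(diff(object@scales) <= 0))
            msg <- c(msg, "scales must be strictly increasing")
        if (length(object@Ropt) != 1L || !object@Ropt %in% object@scales)
            msg <- c(msg, "Ropt must be one of the scanned scales")
        if (length(msg)) msg else TRUE
    })

#' Region-of-interest mask
#'
#' Boolean mask over an image identifying the region of interest
#' \eqn{B_t} (pixels covering cells, excluding empty field).
#'
#' @slot mask logical matrix, same dimensions as the segmented image.
#' @slot source how the mask was obtained: `"thresholded"` (minimum
#'   algorithm succeeded), `"whole_image"` (fallback) or
#'   `"replaced_by_Bmin"` (harmonization replaced it).
#' @slot blurRadius Gaussian blur radius (pixels) at which segmentation
#'   succeeded; `NA` for fallback or replaced masks.
#'
#' @seealso [segmentRoi()], [harmonizeRois()]
#' @export
setClass("RoiMask",
    representation(mask = "matrix", source = "character",
                   blurRadius = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!is.logical(object@mask))
            msg <- c(msg, "mask must be a logical matrix")
        else if (sum(object@mask) < 1L)
            msg <- c(msg, "mask must contain at least one TRUE pixel")
        if (!object@source %in% c("thresholded", "whole_image",
                                  "replaced_by_Bmin"))
            msg <- c(msg, "invalid source")
        if (length(msg)) msg else TRUE
    })

#' Per-experiment moment time series
#'
#' The third central moments \eqn{m_t} of the LoG-filtered frames over
#' their regions of interest and the response statistic
#' \eqn{\Delta m_t = (m_t - m_0)/m_0}, with \eqn{\Delta m_0 = 0} by
#' construction.
#'
#' @slot time frame times in minutes.
#' @slot m third central moment per frame.
#' @slot deltaM relative increment per frame (first element exactly 0).
#' @slot nPix region-of-interest area per frame, in pixels.
#' @slot gamma assumed mean spot size used for the scale selection.
#' @slot Ropt LoG scale used for every frame.
#' @slot drug,condition free-text experiment labels.
#'
#' @seealso [computeDeltaM()]
#' @export
setClass("DeltaMSeries",
    representation(time = "numeric", m = "numeric", deltaM = "numeric",
                   nPix = "integer", gamma = "numeric", Ropt = "numeric",
                   drug = "character", condition = "character"),
    validity = function(object) {
        msg <- character()
        n <- length(object@m)
        if (length(object@deltaM) != n || length(object@time) != n ||
            length(object@nPix) != n)
            msg <- c(msg, "time, m, deltaM and nPix must have equal length")
        if (n > 0L && object@deltaM[1L] != 0)
            msg <- c(msg, "deltaM must start at exactly 0")
        if (length(msg)) msg else TRUE
    })

#' Linear time-response fit
#'
#' Ordinary least-squares fit of the response series against time, the
#' null ("flat, linear") alternative to the sigmoid model.
#'
#' @slot slope,intercept OLS coefficients (slope per minute).
#' @slot r2 coefficient of determination (0 when the series has zero
#'   total variance).
#' @export
setClass("LinearFit",
    representation(slope = "numeric", intercept = "numeric",
                   r2 = "numeric"),
    validity = function(object) {
        if (is.finite(object@r2) && object@r2 > 1 + 1e-12)
            "r2 cannot exceed 1" else TRUE
    })

#' Sigmoid time-response fit
#'
#' Nonlinear least-squares fit of
#' \deqn{\mu_t = \mu_0 + \frac{E_{max}}{1 + \exp[\alpha\,(t_{1/2} - t)]}}
#' where \eqn{E_{max}} is the efficacy (maximum response), \eqn{\alpha}
#' the slope (per minute) and \eqn{t_{1/2}} the time to half-maximal
#' response (minutes).
#'
#' @slot mu0 baseline response level.
#' @slot Emax maximum response (efficacy).
#' @slot alpha sigmoid slope, per minute.
#' @slot tHalf time to half-maximum, minutes.
#' @slot r2 coefficient of determination (\code{-Inf} when no start
#'   converged).
#' @slot converged whether any start of the optimizer converged.
#' @export
setClass("SigmoidFit",
    representation(mu0 = "numeric", Emax = "numeric", alpha = "numeric",
                   tHalf = "numeric", r2 = "numeric",
                   converged = "logical"),
    validity = function(object) {
        if (is.finite(object@r2) && object@r2 > 1 + 1e-12)
            "r2 cannot exceed 1" else TRUE
    })

#' Fitted and quality-controlled experiment
#'
#' One time-course experiment after both model fits and the
#' goodness-of-fit quality-control rule: an experiment is kept when
#' either fit reaches \eqn{r^2 > 0.5}, and counted as a sigmoid
#' responder when the sigmoid fit itself does.
#'
#' @slot id experiment identifier.
#' @slot drug,condition labels (e.g. drug name, -DOX / +DOX).
#' @slot series the [DeltaMSeries-class] measured for the experiment.
#' @slot linear the [LinearFit-class].
#' @slot sigmoid the [SigmoidFit-class].
#' @slot qcPass `TRUE` when r2_lin > 0.5 or r2_sig > 0.5.
#' @slot responderClass `"sigmoid"`, `"flat"` or `"excluded"`.
#' @export
setClass("ExperimentRecord",
    representation(id = "character", drug = "character",
                   condition = "character", series = "DeltaMSeries",
                   linear = "LinearFit", sigmoid = "SigmoidFit",
                   qcPass = "logical", responderClass = "character"),
    validity = function(object) {
        msg <- character()
        if (!object@responderClass %in% c("sigmoid", "flat", "excluded",
                                          "unclassified"))
            msg <- c(msg, "invalid responderClass")
        if (object@responderClass == "excluded" && isTRUE(object@qcPass))
            msg <- c(msg, "excluded records must have qcPass = FALSE")
        if (length(msg)) msg else TRUE
    })
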