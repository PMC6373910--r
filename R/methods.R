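#' Accessors for deltam classes
#'
#' Small accessor generics exposing the slots of the package's S4
#' containers: kernel weights and scale, scan results, mask geometry,
#' series values and classification outcomes.
#'
#' @param object an object of the corresponding class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("scaleR", "LoGKernel", function(object) object@scaleR)

#' @rdname accessors
#' @export
setMethod("kernelMatrix", "LoGKernel", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("optimalScale", "ScaleScan", function(object) object@Ropt)

#' @rdname accessors
#' @export
setMethod("roiMask", "RoiMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("roiArea", "RoiMask", function(object) sum(object@mask))

#' @rdname accessors
#' @export
setMethod("roiSource", "RoiMask", function(object) object@source)

#' @rdname accessors
#' @export
setMethod("deltaM", "DeltaMSeries", function(object) object@deltaM)

#' @rdname accessors
#' @export
setMethod("momentValues", "DeltaMSeries", function(object) object@m)

#' @rdname accessors
#' @export
setMethod("optimalScale", "DeltaMSeries", function(object) object@Ropt)

#' @rdname accessors
#' @export
setMethod("deltaM", "ExperimentRecord", function(object) object@series@deltaM)

#' @rdname accessors
#' @export
setMethod("qcPass", "ExperimentRecord", function(object) object@qcPass)

#' @rdname accessors
#' @export
setMethod("responderClass", "ExperimentRecord",
          function(object) object@responderClass)

#' @export
setMethod("show", "LoGKernel", function(object) {
    cat(sprintf("LoGKernel: R = %.3f px, %d x %d, sum = %.3e\n",
                object@scaleR, nrow(object@weights), ncol(object@weights),
                sum(object@weights)))
})

#' @export
setMethod("show", "ScaleScan", function(object) {
    cat(sprintf(
        "ScaleScan: gamma = %.2f px, %d scales in [%.2f, %.2f]\n",
        object@gamma, length(object@scales),
        min(object@scales), max(object@scales)))
    cat(sprintf("  R_opt = %.2f px (lambda = %.4f)%s\n", object@Ropt,
                object@lambda[match(object@Ropt, object@scales)],
                if (object@converged) "" else " [scan cap reached]"))
})

#' @export
setMethod("show", "RoiMask", function(object) {
    cat(sprintf("RoiMask: %d x %d, area %d px (%.1f%%), source '%s'\n",
                nrow(object@mask), ncol(object@mask), sum(object@mask),
                100 * mean(object@mask), object@source))
})

#' @export
setMethod("show", "DeltaMSeries", function(object) {
    cat(sprintf("DeltaMSeries: %d frames, gamma = %.2f, R_opt = %.2f\n",
                length(object@m), object@gamma, object@Ropt))
    if (length(object@deltaM))
        cat("  deltaM:", paste(sprintf("%.3g", object@deltaM),
                               collapse = " "), "\n")
})

#' @export
setMethod("show", "LinearFit", function(object) {
    cat(sprintf("LinearFit: slope %.4g/min, intercept %.4g, r2 = %.3f\n",
                object@slope, object@intercept, object@r2))
})

#' @export
setMethod("show", "SigmoidFit", function(object) {
    cat(sprintf(
        "SigmoidFit: mu0 %.4g, Emax %.4g, alpha %.3g/min, t1/2 %.3g min, r2 = %.3f%s\n",
        object@mu0, object@Emax, object@alpha, object@tHalf, object@r2,
        if (object@converged) "" else " [not converged]"))
})

#' @export
setMethod("show", "ExperimentRecord", function(object) {
    cat(sprintf("ExperimentRecord '%s' (%s, %s): %s%s\n", object@id,
                object@drug, object@condition, object@responderClass,
                if (object@qcPass) "" else " [QC fail]"))
    cat(sprintf("  r2_lin = %.3f, r2_sig = %.3f\n",
                object@linear@r2, object@sigmoid@r2))
})

#' @export
as.data.frame.ScaleScan <- function(x, ...) {
    data.frame(R = x@scales, lambda = x@lambda)
}

#' @export
as.data.frame.DeltaMSeries <- function(x, ...) {
    data.frame(t_min = x@time, m = x@m, delta_m = x@deltaM,
               n_pix = x@nPix)
}
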