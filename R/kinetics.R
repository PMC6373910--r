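#' Linear fit of a response series
#'
#' Ordinary least squares of the response against time — the null
#' ("flat, linear") model expected for drugs unable to induce
#' endocytosis.  The coefficient of determination is defined as 0 when
#' the series has zero total variance (a perfectly flat series has no
#' variance to explain).
#'
#' @param deltaM response values, one per frame.
#' @param times frame times in minutes.
#' @return a [LinearFit-class] object.
#' @export
fitLinear <- function(deltaM, times = seq_along(deltaM) - 1) {
    stopifnot(length(deltaM) == length(times))
    if (length(deltaM) < 3L)
        stop("need at least 3 points for a linear fit", call. = FALSE)
    if (diff(range(times)) == 0)
        stop("all times are equal", call. = FALSE)
    fit <- stats::lm(deltaM ~ times)
    sst <- sum((deltaM - mean(deltaM))^2)
    r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
    new("LinearFit", slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]), r2 = r2)
}

sigmoidMu <- function(t, mu0, Emax, alpha, tHalf) {
    mu0 + Emax / (1 + exp(alpha * (tHalf - t)))
}

#' Sigmoid fit of a response series
#'
#' Nonlinear least squares of
#' \deqn{\mu_t = \mu_0 + \frac{E_{max}}{1 + \exp[\alpha (t_{1/2} - t)]}}
#' by Levenberg-Marquardt with a deterministic multi-start grid
#' (the objective has symmetric local minima, so a single start is not
#' reliable): \eqn{\mu_0} starts at the first response value,
#' \eqn{E_{max}} at 1 and 2 times the response maximum, \eqn{t_{1/2}}
#' at 25/50/75% of the time span and \eqn{\alpha} at 0.3, 0.6 and 1.2
#' per minute.  Soft bounds keep \eqn{E_{max}} within 10 response
#' ranges, \eqn{\alpha \in [0.01, 10]} and \eqn{t_{1/2}} within one
#' span of the observed window.  The best-converged start by residual
#' sum of squares is returned, with
#' \eqn{r^2 = 1 - SS_{res}/SS_{total}}; if no start converges the fit
#' is flagged and \eqn{r^2 = -\infty}.
#'
#' @inheritParams fitLinear
#' @return a [SigmoidFit-class] object.
#' @examples
#' t <- 0:14
#' y <- 16.1 / (1 + exp(0.53 * (10.4 - t)))
#' fitSigmoid(y, t)   # recovers Emax 16.1, t1/2 10.4, alpha 0.53
#' @export
fitSigmoid <- function(deltaM, times = seq_along(deltaM) - 1) {
    stopifnot(length(deltaM) == length(times))
    if (length(deltaM) < 5L)
        stop("need at least 5 points for a sigmoid fit", call. = FALSE)
    rng <- diff(range(deltaM))
    sst <- sum((deltaM - mean(deltaM))^2)
    if (rng == 0)
        return(new("SigmoidFit", mu0 = deltaM[1L], Emax = 0,
                   alpha = 0.01, tHalf = mean(times), r2 = 0,
                   converged = TRUE))
    span <- diff(range(times))
    lower <- c(mu0 = -Inf, Emax = -10 * rng, alpha = 0.01,
               tHalf = min(times) - span)
    upper <- c(mu0 = Inf, Emax = 10 * rng, alpha = 10,
               tHalf = max(times) + span)
    starts <- expand.grid(
        mu0 = deltaM[1L],
        Emax = c(max(deltaM), 2 * max(deltaM)),
        alpha = c(0.3, 0.6, 1.2),
        tHalf = min(times) + span * c(0.25, 0.5, 0.75))
    starts$Emax[starts$Emax == 0] <- rng
    best <- NULL
    bestSS <- Inf
    dat <- data.frame(y = deltaM, t = times)
    for (i in seq_len(nrow(starts))) {
        st <- as.list(starts[i, ])
        st$tHalf <- min(max(st$tHalf, lower[["tHalf"]]), upper[["tHalf"]])
        st$Emax <- min(max(st$Emax, lower[["Emax"]]), upper[["Emax"]])
        fit <- try(suppressWarnings(minpack.lm::nlsLM(
            y ~ mu0 + Emax / (1 + exp(alpha * (tHalf - t))),
            data = dat, start = st, lower = lower, upper = upper,
            control = minpack.lm::nls.lm.control(maxiter = 200))),
            silent = TRUE)
        if (inherits(fit, "try-error")) next
        ss <- sum(stats::residuals(fit)^2)
        if (ss < bestSS) {
            bestSS <- ss
            best <- stats::coef(fit)
        }
    }
    if (is.null(best))
        return(new("SigmoidFit", mu0 = NA_real_, Emax = NA_real_,
                   alpha = NA_real_, tHalf = NA_real_, r2 = -Inf,
                   converged = FALSE))
    r2 <- if (sst == 0) 0 else 1 - bestSS / sst
    new("SigmoidFit", mu0 = unname(best[["mu0"]]),
        Emax = unname(best[["Emax"]]), alpha = unname(best[["alpha"]]),
        tHalf = unname(best[["tHalf"]]), r2 = r2, converged = TRUE)
}

#' Fit and classify one experiment
#'
#' Applies both time-response models to a measured series and the
#' quality-control rule: an experiment passes QC when either fit
#' reaches \eqn{r^2 > 0.5} (series failing both carry systematic
#' artifacts and are excluded); a QC-passing experiment is a
#' `"sigmoid"` responder when the sigmoid fit itself exceeds 0.5 and
#' `"flat"` otherwise.  Only sigmoid responders enter the parameter
#' summaries.
#'
#' @param series a [DeltaMSeries-class], or a numeric response vector.
#' @param times frame times in minutes (taken from the series when one
#'   is given).
#' @param id,drug,condition labels for the record.
#' @return an [ExperimentRecord-class] object.
#' @export
fitExperiment <- function(series, times = NULL, id = "exp1",
                          drug = NA_character_,
                          condition = NA_character_) {
    if (is(series, "DeltaMSeries")) {
        dm <- series@deltaM
        if (is.null(times)) times <- series@time
        if (!is.na(series@drug) && is.na(drug)) drug <- series@drug
        if (!is.na(series@condition) && is.na(condition))
            condition <- series@condition
        ser <- series
    } else {
        dm <- as.numeric(series)
        if (is.null(times)) times <- seq_along(dm) - 1
        ser <- new("DeltaMSeries", time = as.numeric(times), m = dm,
                   deltaM = c(0, dm[-1L] - dm[1L]),
                   nPix = rep(1L, length(dm)), gamma = NA_real_,
                   Ropt = NA_real_, drug = drug, condition = condition)
    }
    lin <- fitLinear(dm, times)
    sig <- fitSigmoid(dm, times)
    qcClassify(new("ExperimentRecord", id = id, drug = drug,
                   condition = condition, series = ser, linear = lin,
                   sigmoid = sig, qcPass = FALSE,
                   responderClass = "unclassified"))
}

#' Apply the goodness-of-fit quality-control rule
#'
#' Sets `qcPass = (r2_lin > 0.5) || (r2_sig > 0.5)` and the responder
#' class: `"sigmoid"` when QC passes and the sigmoid fit exceeds 0.5,
#' `"flat"` when QC passes on the linear fit only, `"excluded"`
#' otherwise.
#'
#' @param record an [ExperimentRecord-class] with both fits attempted.
#' @return the record with `qcPass` and `responderClass` set.
#' @export
qcClassify <- function(record) {
    stopifnot(is(record, "ExperimentRecord"))
    r2l <- record@linear@r2
    r2s <- record@sigmoid@r2
    pass <- isTRUE(r2l > 0.5) || isTRUE(r2s > 0.5)
    record@qcPass <- pass
    record@responderClass <- if (!pass) "excluded"
        else if (isTRUE(r2s > 0.5)) "sigmoid" else "flat"
    validObject(record)
    record
}

#' Per-experiment parameter table
#'
#' Flattens a list of fitted experiments into the tidy table exported
#' for downstream statistics (one row per experiment).
#'
#' @param records list of [ExperimentRecord-class] objects.
#' @return data.frame with columns `experiment_id`, `drug`,
#'   `condition`, `E_max`, `t_half`, `alpha`, `r2_sig`, `r2_lin`,
#'   `qc_pass`, `responder_class`.
#' @export
parameterTable <- function(records) {
    stopifnot(is.list(records), length(records) >= 1L)
    do.call(rbind, lapply(records, function(r) {
        stopifnot(is(r, "ExperimentRecord"))
        data.frame(experiment_id = r@id, drug = r@drug,
                   condition = r@condition, E_max = r@sigmoid@Emax,
                   t_half = r@sigmoid@tHalf, alpha = r@sigmoid@alpha,
                   r2_sig = r@sigmoid@r2, r2_lin = r@linear@r2,
                   qc_pass = r@qcPass,
                   responder_class = r@responderClass)
    }))
}

#' Group summary of sigmoid parameters
#'
#' Mean and standard error of the mean of the sigmoid parameters
#' (efficacy, half-time, slope) per drug label, pooled across
#' conditions, over sigmoid responders only.  Groups with a single
#' experiment report `NA` for the SEM; empty groups are dropped with a
#' warning.
#'
#' @param records list of [ExperimentRecord-class] objects, or a
#'   data.frame from [parameterTable()].
#' @return data.frame with one row per drug: `drug`, `n`, then mean
#'   and SEM of `E_max`, `t_half` and `alpha`.
#' @export
summarizeGroups <- function(records) {
    tab <- if (is.data.frame(records)) records
           else parameterTable(records)
    drugs <- unique(tab$drug)
    sem <- function(x) if (length(x) < 2L) NA_real_
                       else stats::sd(x) / sqrt(length(x))
    rows <- lapply(drugs, function(d) {
        sub <- tab[tab$drug == d & tab$responder_class == "sigmoid", ]
        if (nrow(sub) == 0L) {
            warning("drug group '", d,
                    "' has no sigmoid responders; omitted",
                    call. = FALSE)
            return(NULL)
        }
        data.frame(drug = d, n = nrow(sub),
                   E_max_mean = mean(sub$E_max), E_max_sem = sem(sub$E_max),
                   t_half_mean = mean(sub$t_half), t_half_sem = sem(sub$t_half),
                   alpha_mean = mean(sub$alpha), alpha_sem = sem(sub$alpha))
    })
    do.call(rbind, rows)
}

#' Two-sample comparison of response values
#'
#' Welch's two-sample t-test (Student's pooled-variance variant behind
#' `pooled = TRUE`) of two groups of response values, as used to test
#' whether the statistic separates simulation-study conditions.  When
#' both groups are constant with equal means the p-value is 1 by
#' convention.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (Student) test instead of
#'   Welch (default `FALSE`).
#' @return list with `statistic`, `p.value`, `df` and the group means.
#' @export
compareDeltaM <- function(x, y, pooled = FALSE) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y))
            return(list(statistic = 0, p.value = 1, df = NA_real_,
                        mean_x = mean(x), mean_y = mean(y)))
        return(list(statistic = Inf, p.value = 0, df = NA_real_,
                    mean_x = mean(x), mean_y = mean(y)))
    }
    ht <- stats::t.test(x, y, var.equal = pooled)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), mean_x = mean(x), mean_y = mean(y))
}
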