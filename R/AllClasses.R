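#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.REQUIRED_COVARIATES <- c("study_id", "diagnosis", "age", "sex", "icv")

#' StudyCohort: subject-level regional measures across studies
#'
#' A \linkS4class{SummarizedExperiment} holding one multi-study case-control
#' cohort: the single assay \code{"measures"} is a regions x subjects matrix
#' of regional brain measures (cortical thickness, surface area, subcortical
#' volume), and \code{colData} carries the per-subject covariates
#' \code{study_id} (factor), \code{diagnosis} (0 = control, 1 = dependent),
#' \code{age} (years), \code{sex} (0 = female, 1 = male) and \code{icv}
#' (intracranial volume). \code{metadata(x)$harmonized} records whether the
#' measures have been batch-harmonized.
#'
#' @seealso [StudyCohort()], [combatHarmonize()], [computeEffectSizes()]
#' @export
setClass("StudyCohort", contains = "SummarizedExperiment")

setValidity("StudyCohort", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(.REQUIRED_COVARIATES, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste0("missing colData column(s): ",
                             paste(missing_cols, collapse = ", ")))
    if (!"measures" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'measures' is required")
    if (!length(msg)) {
        for (cc in .REQUIRED_COVARIATES)
            if (anyNA(cd[[cc]]))
                msg <- c(msg, paste0("colData column '", cc, "' contains NA"))
        if (!all(cd$diagnosis %in% c(0, 1)))
            msg <- c(msg, "diagnosis must be coded 0 (control) / 1 (case)")
        if (!all(cd$sex %in% c(0, 1)))
            msg <- c(msg, "sex must be coded 0 (female) / 1 (male)")
        m <- SummarizedExperiment::assay(object, "measures")
        if (!all(is.finite(m)))
            msg <- c(msg, "assay 'measures' contains non-finite values")
    }
    if (length(msg)) msg else TRUE
})

#' Prior specification for the hierarchical model
#'
#' Holds the mildly informative priors of the hierarchy: the overarching mean
#' M gets a Normal(\code{m0}, variance \code{v0}) prior, and the two
#' precisions (the common effect-size precision tau = 1/sigma^2 and the
#' between-study precision T = 1/Sigma^2) get Gamma priors specified by mode
#' and standard deviation and stored as shape \code{a} / rate \code{b}.
#'
#' @slot m0 prior mean of M (Cohen's d scale).
#' @slot v0 prior variance of M.
#' @slot gammaMode,gammaSd mode and SD of the Gamma prior on the precisions.
#' @slot a,b derived Gamma shape and rate.
#' @seealso [priorSpec()], [gammaModeSdToShapeRate()]
#' @export
setClass("PriorSpec",
    representation(m0 = "numeric", v0 = "numeric",
                   gammaMode = "numeric", gammaSd = "numeric",
                   a = "numeric", b = "numeric"))

setValidity("PriorSpec", function(object) {
    msg <- character()
    for (s in c("m0", "v0", "gammaMode", "gammaSd", "a", "b"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, paste0("slot '", s, "' must be a finite scalar"))
    if (!length(msg)) {
        if (object@v0 <= 0) msg <- c(msg, "v0 must be > 0")
        if (object@gammaMode <= 0) msg <- c(msg, "gammaMode must be > 0")
        if (object@gammaSd <= 0) msg <- c(msg, "gammaSd must be > 0")
        if (object@a <= 1) msg <- c(msg, "shape a must exceed 1 (mode parameterization)")
        if (abs((object@a - 1) / object@b - object@gammaMode) > 1e-8 * max(1, object@gammaMode))
            msg <- c(msg, "(a - 1)/b must equal gammaMode")
    }
    if (length(msg)) msg else TRUE
})

#' MCMC draws for one regional fit
#'
#' Container for the Gibbs-sampler output of one region: \code{draws} is a
#' three-way array (retained iteration x chain x parameter) over the
#' parameters \code{M}, \code{mu[1] ... mu[K]}, \code{tau} and \code{T};
#' \code{meta} records the data (\code{y}, \code{omega}, study ids), sampler
#' settings (iterations, burn-in, thinning, seed, omega convention) needed to
#' interpret and reproduce the draws.
#'
#' @slot draws numeric array, dim = c(draws kept, chains, parameters).
#' @slot region region name (may be \code{NA} for free-standing fits).
#' @slot priors the \linkS4class{PriorSpec} used.
#' @slot meta list of sampler metadata.
#' @seealso [gibbsSample()], [posteriorSummary()], [extractDraws()]
#' @export
setClass("PosteriorSamples",
    representation(draws = "array", region = "character",
                   priors = "PriorSpec", meta = "list"))

setValidity("PosteriorSamples", function(object) {
    d <- object@draws
    if (length(dim(d)) != 3L)
        return("draws must be a 3-way array (draw x chain x parameter)")
    if (is.null(dimnames(d)[[3]]))
        return("draws must carry parameter names in dimnames")
    if (!all(is.finite(d)))
        return("draws contain non-finite values")
    TRUE
})

#' Adjustment-magnitude report
#'
#' Pairs each original study x region Cohen's d with its Bayesian-adjusted
#' value (a posterior point estimate of the study-level mean mu_i), the
#' absolute adjustment, the study size and the subsampled sampling SD, and
#' summarizes the adjustments: a one-sided t-test of mean adjustment > 0 and
#' Pearson correlations of the adjustment with study size and with omega.
#'
#' @slot table data.frame with columns study_id, region, d_original,
#'   d_adjusted, adjustment, n, omega.
#' @slot pointEstimate \code{"mode"} or \code{"mean"}.
#' @slot tStat,pValue one-sided t-test of mean adjustment against zero.
#' @slot rN,rOmega Pearson correlations of adjustment with n and with omega.
#' @slot flags character vector of degeneracy notes (e.g. zero-variance
#'   adjustments making the t-test undefined).
#' @seealso [adjustedEffectSizes()]
#' @export
setClass("AdjustmentReport",
    representation(table = "data.frame", pointEstimate = "character",
                   tStat = "numeric", pValue = "numeric",
                   rN = "numeric", rOmega = "numeric", flags = "character"))
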