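#' Bayesian-adjusted effect sizes and adjustment-magnitude analysis
#'
#' Replaces each study x region Cohen's d with the posterior point estimate
#' (mode by default, optionally mean) of the study-level parameter mu_i from
#' the hierarchical fit, and quantifies the recalibration: the absolute
#' adjustment per cell, a one-sided t-test of mean adjustment > 0, and
#' Pearson correlations of the adjustment magnitude with study size and with
#' the subsampled sampling SD omega. Smaller, noisier studies are expected
#' to be adjusted more (negative correlation with n, positive with omega).
#'
#' @param es effect-size table from [computeEffectSizes()].
#' @param fits named list of \linkS4class{PosteriorSamples} from
#'   [fitAllRegions()] (names are regions; study ids are carried in the fit
#'   metadata).
#' @param om omega table from [estimateOmega()] supplying the \code{omega}
#'   column.
#' @param pointEstimate \code{"mode"} (default) or \code{"mean"}. The mean
#'   typically shrinks more than the mode on skewed posteriors.
#' @return An \linkS4class{AdjustmentReport}.
#' @export
adjustedEffectSizes <- function(es, fits, om,
                                pointEstimate = c("mode", "mean")) {
    pointEstimate <- match.arg(pointEstimate)
    regions <- sort(unique(es$region))
    missing_fit <- setdiff(regions, names(fits))
    if (length(missing_fit))
        stop("no posterior fit for region(s): ",
             paste(utils::head(missing_fit, 5), collapse = ", "))
    adj <- lapply(regions, function(r) {
        ps <- fits[[r]]
        sids <- ps@meta$studyIds
        if (is.null(sids))
            stop("fit for region '", r, "' carries no study ids")
        est <- vapply(seq_along(sids), function(i) {
            pooled <- extractDraws(ps, sprintf("mu[%d]", i))
            if (pointEstimate == "mode") posteriorMode(pooled) else
                mean(pooled)
        }, numeric(1))
        data.frame(study_id = sids, region = r, d_adjusted = est,
                   stringsAsFactors = FALSE)
    })
    adj <- do.call(rbind, adj)
    tab <- merge(es[, c("study_id", "region", "y", "n1", "n2")], adj,
                 by = c("study_id", "region"))
    tab <- merge(tab, om[, c("study_id", "region", "omega")],
                 by = c("study_id", "region"))
    names(tab)[names(tab) == "y"] <- "d_original"
    tab$adjustment <- abs(tab$d_original - tab$d_adjusted)
    tab$n <- tab$n1 + tab$n2
    tab <- tab[order(tab$region, tab$study_id),
               c("study_id", "region", "d_original", "d_adjusted",
                 "adjustment", "n", "omega")]
    rownames(tab) <- NULL

    flags <- character()
    if (stats::sd(tab$adjustment) == 0) {
        flags <- c(flags, paste("zero-variance adjustments: t-test and",
                                "correlations undefined"))
        tStat <- pValue <- rN <- rOmega <- NA_real_
    } else {
        tt <- stats::t.test(tab$adjustment, mu = 0, alternative = "greater")
        tStat <- unname(tt$statistic)
        pValue <- tt$p.value
        safeCor <- function(x, label) {
            if (stats::sd(x) == 0) {
                flags <<- c(flags, paste0("constant ", label,
                                          ": correlation undefined"))
                return(NA_real_)
            }
            stats::cor(tab$adjustment, x)
        }
        rN <- safeCor(tab$n, "study size")
        rOmega <- safeCor(tab$omega, "omega")
    }
    new("AdjustmentReport", table = tab, pointEstimate = pointEstimate,
        tStat = tStat, pValue = pValue, rN = rN, rOmega = rOmega,
        flags = flags)
}

#' @describeIn adjustedEffectSizes accessor for the per-cell table.
#' @param report an \code{AdjustmentReport}.
#' @export
adjustmentTable <- function(report) {
    stopifnot(is(report, "AdjustmentReport"))
    report@table
}

#' @describeIn adjustedEffectSizes accessor for the summary statistics
#'   (list with \code{tStat}, \code{pValue}, \code{rN}, \code{rOmega},
#'   \code{flags}).
#' @export
adjustmentStats <- function(report) {
    stopifnot(is(report, "AdjustmentReport"))
    list(tStat = report@tStat, pValue = report@pValue, rN = report@rN,
         rOmega = report@rOmega, flags = report@flags)
}

setMethod("show", "AdjustmentReport", function(object) {
    tab <- object@table
    cat("AdjustmentReport: ", nrow(tab), " study x region cells ",
        "(point estimate: ", object@pointEstimate, ")\n", sep = "")
    cat("  adjustment range: [", signif(min(tab$adjustment), 3), ", ",
        signif(max(tab$adjustment), 3), "]\n", sep = "")
    cat("  one-sided t-test of mean adjustment > 0: t = ",
        signif(object@tStat, 4), ", p = ", format.pval(object@pValue),
        "\n", sep = "")
    cat("  r(adjustment, n) = ", signif(object@rN, 3),
        "; r(adjustment, omega) = ", signif(object@rOmega, 3), "\n",
        sep = "")
    if (length(object@flags)) cat("  flags:", object@flags, "\n")
})
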