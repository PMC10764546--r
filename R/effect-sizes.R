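#' Convert a regression t-statistic to Cohen's d
#'
#' Standard conversion for a two-group comparison embedded in a covariate
#' adjusted regression:
#' \deqn{d = t\,(n_1 + n_2) / (\sqrt{n_1 n_2}\,\sqrt{df}).}
#'
#' @param t t-statistic of the group (diagnosis) coefficient.
#' @param n1,n2 group sizes (cases, controls), each >= 1.
#' @param df residual degrees of freedom (> 0).
#' @return Cohen's d, same sign as \code{t}.
#' @examples
#' cohensDFromT(2, 20, 20, 36)  # 0.6667
#' @export
cohensDFromT <- function(t, n1, n2, df) {
    if (any(df <= 0)) stop("df must be > 0")
    if (any(n1 < 1) || any(n2 < 1)) stop("n1 and n2 must be >= 1")
    t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

# OLS of each column of Y on X; returns the t-statistic of column `coefIdx`
# of X for every response, plus the shared residual df. Errors on rank
# deficiency (e.g. a constant covariate).
.studyRegression <- function(X, Y, coefIdx = 2L) {
    p <- ncol(X)
    df <- nrow(X) - p
    if (df < 1L) stop("not enough subjects for the regression (df < 1)")
    XtX <- crossprod(X)
    A <- tryCatch(chol2inv(chol(XtX)),
                  error = function(e) stop("singular design matrix: ",
                                           "rank-deficient predictors", call. = FALSE))
    B <- A %*% crossprod(X, Y)
    rss <- colSums((Y - X %*% B)^2)
    se <- sqrt(pmax(rss / df, 0) * A[coefIdx, coefIdx])
    tval <- drop(B[coefIdx, ]) / se
    list(t = tval, df = df)
}

.designMatrix <- function(subjects) {
    cbind(intercept = 1, diagnosis = subjects$diagnosis, age = subjects$age,
          sex = subjects$sex, icv = subjects$icv)
}

#' Per-study covariate-adjusted group comparison for one region
#'
#' Fits \code{region ~ diagnosis + age + sex + icv} by ordinary least
#' squares on the subjects of a single study (rows with missing values are
#' dropped) and returns the diagnosis t-statistic together with the residual
#' degrees of freedom (n - 5) and the group sizes — the ingredients of
#' [cohensDFromT()].
#'
#' @param subjects data.frame of one study's rows in the subject-table
#'   schema.
#' @param region name of the region column to model.
#' @return list with elements \code{t}, \code{df}, \code{n1} (cases),
#'   \code{n2} (controls).
#' @export
fitStudyRegression <- function(subjects, region) {
    if (!region %in% colnames(subjects))
        stop("region column '", region, "' not found in subject table")
    keep <- stats::complete.cases(
        subjects[, c(.REQUIRED_COVARIATES, region)])
    subjects <- subjects[keep, , drop = FALSE]
    n1 <- sum(subjects$diagnosis == 1)
    n2 <- sum(subjects$diagnosis == 0)
    if (n1 == 0L || n2 == 0L)
        stop("study must contain both cases and controls")
    if (nrow(subjects) < 7L)
        stop("study must have >= 7 subjects (5 regression parameters)")
    fit <- .studyRegression(.designMatrix(subjects),
                            as.matrix(subjects[, region, drop = FALSE]))
    list(t = unname(fit$t), df = fit$df, n1 = n1, n2 = n2)
}

#' Observed effect sizes for every study x region
#'
#' Runs the per-study regression of each regional measure on diagnosis, age,
#' sex and ICV, and converts the diagnosis t-statistic to Cohen's d. These
#' per-study d values are the observations \code{y} entering the
#' hierarchical model. Studies lacking one of the diagnosis groups are
#' dropped with a warning, mirroring the exclusion of single-group studies.
#'
#' @param x a \linkS4class{StudyCohort} or a subject-table data.frame.
#' @return data.frame with columns \code{study_id}, \code{region}, \code{y}
#'   (Cohen's d), \code{t}, \code{df}, \code{n1}, \code{n2}; one row per
#'   retained study x region.
#' @examples
#' sim <- simulateCohort(syntheticConfig(nStudies = 2, studySizes = 60,
#'                                       seed = 3))
#' head(computeEffectSizes(sim$cohort))
#' @export
setGeneric("computeEffectSizes", function(x) standardGeneric("computeEffectSizes"))

#' @rdname computeEffectSizes
#' @export
setMethod("computeEffectSizes", "StudyCohort", function(x) {
    computeEffectSizes(asSubjectTable(x))
})

#' @rdname computeEffectSizes
#' @export
setMethod("computeEffectSizes", "data.frame", function(x) {
    if (!nrow(x)) stop("empty subject table")
    regions <- setdiff(colnames(x), .REQUIRED_COVARIATES)
    if (!length(regions)) stop("subject table has no region columns")
    out <- list()
    for (sid in unique(as.character(x$study_id))) {
        sub <- x[x$study_id == sid, , drop = FALSE]
        sub <- sub[stats::complete.cases(sub[, .REQUIRED_COVARIATES]), ,
                   drop = FALSE]
        n1 <- sum(sub$diagnosis == 1)
        n2 <- sum(sub$diagnosis == 0)
        if (n1 == 0L || n2 == 0L) {
            warning("dropping study '", sid,
                    "': only one diagnosis group present", call. = FALSE)
            next
        }
        fit <- .studyRegression(.designMatrix(sub),
                                as.matrix(sub[, regions, drop = FALSE]))
        out[[sid]] <- data.frame(
            study_id = sid, region = regions,
            y = cohensDFromT(fit$t, n1, n2, fit$df),
            t = unname(fit$t), df = fit$df, n1 = n1, n2 = n2,
            stringsAsFactors = FALSE, row.names = NULL)
    }
    if (!length(out))
        stop("no study retained: every study lacks a diagnosis group")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
})
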