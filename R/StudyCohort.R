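#' Construct a StudyCohort from a subject-level table
#'
#' Builds the central container from a subject-level \code{data.frame} with
#' one row per subject: the covariate columns \code{study_id},
#' \code{diagnosis}, \code{age}, \code{sex}, \code{icv} plus one numeric
#' column per regional measure. Region columns are transposed into the
#' regions x subjects \code{"measures"} assay.
#'
#' @param subjects data.frame in the subject-table schema.
#' @param harmonized logical flag recorded in the object metadata; newly
#'   constructed cohorts are raw (\code{FALSE}) unless stated otherwise.
#' @return A \linkS4class{StudyCohort}.
#' @examples
#' cfg <- syntheticConfig(nStudies = 3, studySizes = c(30, 40, 50), seed = 1)
#' sim <- simulateCohort(cfg)
#' sim$cohort
#' @export
StudyCohort <- function(subjects, harmonized = FALSE) {
    stopifnot(is.data.frame(subjects))
    missing_cols <- setdiff(.REQUIRED_COVARIATES, colnames(subjects))
    if (length(missing_cols))
        stop("subject table is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    region_cols <- setdiff(colnames(subjects), .REQUIRED_COVARIATES)
    if (!length(region_cols))
        stop("subject table has no region columns")
    m <- t(as.matrix(subjects[, region_cols, drop = FALSE]))
    storage.mode(m) <- "double"
    colnames(m) <- rownames(subjects) <- NULL
    cd <- S4Vectors::DataFrame(
        study_id  = factor(subjects$study_id),
        diagnosis = as.integer(subjects$diagnosis),
        age       = as.numeric(subjects$age),
        sex       = as.integer(subjects$sex),
        icv       = as.numeric(subjects$icv))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(measures = m), colData = cd,
        metadata = list(harmonized = isTRUE(harmonized)))
    new("StudyCohort", se)
}

#' @describeIn StudyCohort flatten back to the subject-table data.frame
#'   (covariates first, then one column per region).
#' @param x a \code{StudyCohort}.
#' @export
asSubjectTable <- function(x) {
    stopifnot(is(x, "StudyCohort"))
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    meas <- as.data.frame(t(SummarizedExperiment::assay(x, "measures")))
    rownames(cd) <- rownames(meas) <- NULL
    cbind(cd, meas)
}

#' Accessors for StudyCohort
#'
#' \code{regionNames()} returns the regional-measure names (assay rows);
#' \code{studyIds()} the per-subject study factor; \code{studyProfiles()} the
#' per-study diagnosis x sex composition used to drive stratified
#' subsampling; \code{isHarmonized()} the harmonization provenance flag.
#'
#' @param x a \linkS4class{StudyCohort}.
#' @return \code{studyProfiles()} returns a data.frame with one row per study
#'   and columns \code{study_id}, \code{n1} (cases), \code{n2} (controls),
#'   \code{case_m}, \code{case_f}, \code{control_m}, \code{control_f}.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
regionNames <- function(x) rownames(SummarizedExperiment::assay(x, "measures"))

#' @rdname cohort-accessors
#' @export
studyIds <- function(x) SummarizedExperiment::colData(x)$study_id

#' @rdname cohort-accessors
#' @export
isHarmonized <- function(x) isTRUE(S4Vectors::metadata(x)$harmonized)

#' @rdname cohort-accessors
#' @export
studyProfiles <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    sid <- factor(cd$study_id)
    cnt <- function(keep) as.vector(table(sid[keep])[levels(sid)])
    out <- data.frame(
        study_id  = levels(sid),
        n1        = cnt(cd$diagnosis == 1),
        n2        = cnt(cd$diagnosis == 0),
        case_m    = cnt(cd$diagnosis == 1 & cd$sex == 1),
        case_f    = cnt(cd$diagnosis == 1 & cd$sex == 0),
        control_m = cnt(cd$diagnosis == 0 & cd$sex == 1),
        control_f = cnt(cd$diagnosis == 0 & cd$sex == 0),
        stringsAsFactors = FALSE)
    out[is.na(out)] <- 0L
    out
}

setMethod("show", "StudyCohort", function(object) {
    cd <- SummarizedExperiment::colData(object)
    sid <- factor(cd$study_id)
    cat("StudyCohort with", ncol(object), "subjects,",
        nrow(object), "regions,", nlevels(sid), "studies\n")
    cat("  cases:", sum(cd$diagnosis == 1),
        " controls:", sum(cd$diagnosis == 0), "\n")
    cat("  harmonized:", isHarmonized(object), "\n")
})
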