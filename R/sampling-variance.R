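# pooled cell indices for diagnosis x sex stratification
.poolCells <- function(cd) {
    list(case_m    = which(cd$diagnosis == 1 & cd$sex == 1),
         case_f    = which(cd$diagnosis == 1 & cd$sex == 0),
         control_m = which(cd$diagnosis == 0 & cd$sex == 1),
         control_f = which(cd$diagnosis == 0 & cd$sex == 0))
}

.checkProfileFeasible <- function(cells, profile) {
    for (cell in names(cells)) {
        need <- profile[[cell]]
        if (is.null(need) || is.na(need))
            stop("profile is missing cell count '", cell, "'")
        if (length(cells[[cell]]) < need)
            stop("infeasible profile: pool has ", length(cells[[cell]]),
                 " subjects in cell '", cell, "' but ", need, " are required")
    }
}

# draw one stratified subsample (without replacement within the draw)
.drawProfile <- function(cells, profile) {
    unlist(lapply(names(cells), function(cell) {
        idx <- cells[[cell]]
        need <- profile[[cell]]
        if (need == 0L) integer() else idx[sample.int(length(idx), need)]
    }), use.names = FALSE)
}

#' Simulate a study's effect-size sampling distribution by subsampling
#'
#' Repeatedly draws, from the pooled (harmonized) data, a pseudo-study
#' matching a target study's diagnosis x sex composition — sampling without
#' replacement within each draw — refits the covariate-adjusted regression
#' for one region, and records Cohen's d. The SD of the returned vector is
#' the study's tailored sampling variability for that region.
#'
#' @param pool a \linkS4class{StudyCohort}, normally harmonized.
#' @param profile one row of [studyProfiles()] (or any list with
#'   \code{case_m}, \code{case_f}, \code{control_m}, \code{control_f}).
#' @param region region name.
#' @param reps number of subsampling repetitions (1,000 in typical use).
#' @param seed optional integer seed; the draw sequence is deterministic
#'   given it.
#' @return numeric vector of \code{reps} simulated Cohen's d values.
#' @seealso [estimateOmega()]
#' @export
subsampleEffectSizes <- function(pool, profile, region, reps = 1000,
                                 seed = NULL) {
    stopifnot(is(pool, "StudyCohort"), reps >= 1)
    if (!region %in% regionNames(pool))
        stop("region '", region, "' not found in pool")
    if (!is.null(seed)) set.seed(seed)
    cd <- SummarizedExperiment::colData(pool)
    cells <- .poolCells(cd)
    .checkProfileFeasible(cells, profile)
    y <- SummarizedExperiment::assay(pool, "measures")[region, ]
    X_all <- cbind(1, cd$diagnosis, cd$age, cd$sex, cd$icv)
    n1 <- profile$case_m + profile$case_f
    n2 <- profile$control_m + profile$control_f
    vapply(seq_len(reps), function(r) {
        idx <- .drawProfile(cells, profile)
        fit <- .studyRegression(X_all[idx, , drop = FALSE],
                                matrix(y[idx], ncol = 1))
        cohensDFromT(fit$t, n1, n2, fit$df)
    }, numeric(1))
}

#' Tailored sampling SD of Cohen's d for every study x region
#'
#' For each study profile, draws \code{reps} stratified pseudo-studies from
#' the pooled harmonized data (each draw shared across regions, so one
#' multi-response regression per draw yields every region's d) and reports
#' per region the sample SD of the simulated effect sizes — the
#' study-specific \code{omega} that weights the common variance component in
#' the hierarchical model — together with a Lilliefors normality p-value of
#' the simulated distribution.
#'
#' @param pool a \linkS4class{StudyCohort}; a warning is issued if it has
#'   not been harmonized.
#' @param profiles data.frame of study profiles, as from [studyProfiles()].
#' @param regions regions to process (default: all in the pool).
#' @param reps repetitions per study (>= 2; default 1,000).
#' @param seed master seed; per-study streams are derived from it so results
#'   do not depend on evaluation order.
#' @return data.frame with columns \code{study_id}, \code{region},
#'   \code{omega}, \code{n_reps}, \code{normality_p}.
#' @examples
#' sim <- simulateCohort(syntheticConfig(nStudies = 3, studySizes = 60,
#'                                       seed = 11))
#' om <- estimateOmega(sim$cohort, studyProfiles(sim$cohort),
#'                     reps = 50, seed = 1)
#' head(om)
#' @export
estimateOmega <- function(pool, profiles, regions = regionNames(pool),
                          reps = 1000, seed = 1L) {
    stopifnot(is(pool, "StudyCohort"), is.data.frame(profiles))
    if (reps < 2)
        stop("reps must be >= 2: the SD of a single simulated d is undefined")
    if (!isHarmonized(pool))
        warning("pool has not been harmonized; omega estimates may absorb ",
                "between-study batch effects")
    missing_r <- setdiff(regions, regionNames(pool))
    if (length(missing_r))
        stop("region(s) not in pool: ", paste(missing_r, collapse = ", "))
    cd <- SummarizedExperiment::colData(pool)
    cells <- .poolCells(cd)
    Y_all <- t(SummarizedExperiment::assay(pool, "measures")[regions, ,
                                                             drop = FALSE])
    X_all <- cbind(1, cd$diagnosis, cd$age, cd$sex, cd$icv)
    seeds <- deriveSeeds(seed, nrow(profiles))
    out <- vector("list", nrow(profiles))
    for (j in seq_len(nrow(profiles))) {
        profile <- profiles[j, ]
        .checkProfileFeasible(cells, profile)
        n1 <- profile$case_m + profile$case_f
        n2 <- profile$control_m + profile$control_f
        set.seed(seeds[j])
        d <- matrix(NA_real_, reps, length(regions))
        for (r in seq_len(reps)) {
            idx <- .drawProfile(cells, profile)
            fit <- .studyRegression(X_all[idx, , drop = FALSE],
                                    Y_all[idx, , drop = FALSE])
            d[r, ] <- cohensDFromT(fit$t, n1, n2, fit$df)
        }
        out[[j]] <- data.frame(
            study_id = as.character(profile$study_id), region = regions,
            omega = apply(d, 2, stats::sd),
            n_reps = as.integer(reps),
            normality_p = apply(d, 2, lillieforsTest),
            stringsAsFactors = FALSE, row.names = NULL)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Lilliefors (Kolmogorov-Smirnov) test of normality
#'
#' KS test against a normal distribution with mean and SD estimated from the
#' sample, using the Lilliefors null distribution of the statistic. Used to
#' check that the subsampled effect-size distributions are compatible with
#' the normality assumed by the hierarchical model.
#'
#' @param x numeric vector, length >= 5, non-constant.
#' @return p-value in [0, 1].
#' @export
lillieforsTest <- function(x) {
    if (length(x) < 5) stop("need at least 5 observations")
    if (stats::sd(x) == 0) stop("degenerate input: constant vector")
    nortest::lillie.test(x)$p.value
}
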