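#' Configuration for the multi-study synthetic cohort generator
#'
#' Describes a synthetic multi-study case-control world with known ground
#' truth: per-study sample sizes and case/sex composition, per-region true
#' standardized group differences drawn from an overarching normal
#' distribution, covariate effects, and additive/multiplicative site effects.
#' All per-study arguments are recycled from scalars to \code{nStudies}.
#'
#' True effects are injected on the standardized scale: the mean shift of a
#' case relative to a control is \code{delta * residualSd}, so the generator's
#' \code{delta} is directly comparable to the Cohen's d estimated downstream.
#'
#' @param nStudies number of studies.
#' @param studySizes integer vector of per-study subject counts (each >= 8).
#' @param caseFraction per-study proportion of cases, in (0, 1). Ignored for
#'   a study when \code{caseCounts} is given.
#' @param caseCounts optional integer vector of per-study case counts,
#'   overriding \code{caseFraction} (must leave >= 1 case and >= 1 control).
#' @param maleFraction per-study proportion of males in (0, 1), applied
#'   within each diagnosis group; cells are kept at >= 4 subjects whenever the
#'   group has >= 8 so that diagnosis x sex stratification does not
#'   degenerate.
#' @param regions character vector of region names.
#' @param MTrue mean of the overarching distribution of true standardized
#'   effects (d scale).
#' @param SigmaTrue between-study SD of true effects (d scale, >= 0).
#' @param deltaMatrix optional nStudies x length(regions) matrix of true
#'   effects, overriding the Normal(MTrue, SigmaTrue^2) draws.
#' @param betaAge,betaSex,betaIcv covariate coefficients, in measure units
#'   per year / per male indicator / per ICV unit.
#' @param siteShift per-study additive offset (measure units).
#' @param siteScale per-study multiplicative factor on the residual noise
#'   (> 0).
#' @param baseline control-group mean of every regional measure.
#' @param residualSd within-group residual SD of the measure (> 0).
#' @param seed integer seed making generation fully reproducible.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @seealso [simulateCohort()], [defaultMultistudyConfig()]
#' @export
syntheticConfig <- function(nStudies,
                            studySizes,
                            caseFraction = 0.5,
                            caseCounts = NULL,
                            maleFraction = 0.6,
                            regions = c("region_1", "region_2"),
                            MTrue = 0,
                            SigmaTrue = 0,
                            deltaMatrix = NULL,
                            betaAge = 0,
                            betaSex = 0,
                            betaIcv = 0,
                            siteShift = 0,
                            siteScale = 1,
                            baseline = 2.5,
                            residualSd = 0.15,
                            seed = 1L) {
    nStudies <- as.integer(nStudies)
    stopifnot(nStudies >= 1L, length(studySizes) %in% c(1L, nStudies))
    cfg <- list(
        nStudies = nStudies,
        studySizes = as.integer(rep_len(studySizes, nStudies)),
        caseFraction = rep_len(caseFraction, nStudies),
        caseCounts = if (!is.null(caseCounts)) as.integer(rep_len(caseCounts, nStudies)),
        maleFraction = rep_len(maleFraction, nStudies),
        regions = as.character(regions),
        MTrue = MTrue, SigmaTrue = SigmaTrue,
        deltaMatrix = deltaMatrix,
        betaAge = betaAge, betaSex = betaSex, betaIcv = betaIcv,
        siteShift = rep_len(siteShift, nStudies),
        siteScale = rep_len(siteScale, nStudies),
        baseline = baseline, residualSd = residualSd,
        seed = as.integer(seed))
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

#' @rdname syntheticConfig
#' @param config object to validate.
#' @export
validateSyntheticConfig <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    with(config, {
        if (any(studySizes < 8L))
            stop("all study sizes must be >= 8")
        if (any(caseFraction <= 0 | caseFraction >= 1))
            stop("caseFraction must lie strictly in (0, 1)")
        if (any(maleFraction <= 0 | maleFraction >= 1))
            stop("maleFraction must lie strictly in (0, 1)")
        if (any(siteScale <= 0))
            stop("siteScale must be > 0")
        if (SigmaTrue < 0)
            stop("SigmaTrue must be >= 0")
        if (residualSd <= 0)
            stop("residualSd must be > 0")
        if (!is.null(caseCounts) &&
            any(caseCounts < 1L | caseCounts > studySizes - 1L))
            stop("caseCounts must leave >= 1 case and >= 1 control per study")
        if (!is.null(deltaMatrix) &&
            !identical(dim(deltaMatrix), c(nStudies, length(regions))))
            stop("deltaMatrix must be nStudies x length(regions)")
        if (anyDuplicated(regions))
            stop("region names must be unique")
    })
    invisible(config)
}

# split a group of n subjects into male/female counts at the requested
# fraction, keeping both sexes at >= 4 whenever the group allows it
.sexCounts <- function(n, maleFrac) {
    m <- round(maleFrac * n)
    if (n >= 8L) m <- min(max(m, 4L), n - 4L) else m <- min(max(m, 0L), n)
    c(male = as.integer(m), female = as.integer(n - m))
}

#' Simulate a multi-study cohort with known ground truth
#'
#' Draws per-study, per-region true standardized effects
#' \code{delta[i, r] ~ Normal(MTrue, SigmaTrue^2)} (unless fixed via
#' \code{deltaMatrix}) and generates subject-level regional measures as
#' \deqn{baseline + \delta_{i,r}\,s\,diagnosis + \beta_{age} age +
#'   \beta_{sex} sex + \beta_{icv} icv + shift_i + scale_i\,
#'   Normal(0, s^2)}
#' with \code{s = residualSd}. Age is Uniform(18, 60) and ICV is
#' Normal(1.5e6, 1.5e5^2). Generation is deterministic given the config seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return A list with elements \code{cohort} (a
#'   \linkS4class{StudyCohort}), \code{truth} (data.frame of the true
#'   \code{delta} per study x region, with \code{MTrue}/\code{SigmaTrue}
#'   attached as attributes), and \code{config}.
#' @examples
#' sim <- simulateCohort(syntheticConfig(nStudies = 2, studySizes = 40,
#'                                       MTrue = -0.2, seed = 7))
#' head(sim$truth)
#' @export
simulateCohort <- function(config) {
    validateSyntheticConfig(config)
    set.seed(config$seed)
    K <- config$nStudies
    R <- length(config$regions)

    cases <- if (!is.null(config$caseCounts)) config$caseCounts else
        pmin(pmax(round(config$studySizes * config$caseFraction), 1L),
             config$studySizes - 1L)
    controls <- config$studySizes - cases
    if (any(cases < 1L) || any(controls < 1L))
        stop("configuration yields a study without both cases and controls")

    delta <- config$deltaMatrix
    if (is.null(delta))
        delta <- matrix(stats::rnorm(K * R, config$MTrue, config$SigmaTrue),
                        nrow = K, ncol = R)
    study_ids <- sprintf("study_%02d", seq_len(K))
    dimnames(delta) <- list(study_ids, config$regions)

    tabs <- vector("list", K)
    for (i in seq_len(K)) {
        n <- config$studySizes[i]
        diag_vec <- rep(c(1L, 0L), c(cases[i], controls[i]))
        sex_vec <- c(rep(c(1L, 0L), .sexCounts(cases[i], config$maleFraction[i])),
                     rep(c(1L, 0L), .sexCounts(controls[i], config$maleFraction[i])))
        age <- stats::runif(n, 18, 60)
        icv <- stats::rnorm(n, 1.5e6, 1.5e5)
        noise <- matrix(stats::rnorm(n * R, 0, config$residualSd), n, R)
        meas <- config$baseline +
            outer(diag_vec, delta[i, ] * config$residualSd) +
            config$betaAge * age + config$betaSex * sex_vec +
            config$betaIcv * icv +
            config$siteShift[i] + config$siteScale[i] * noise
        colnames(meas) <- config$regions
        tabs[[i]] <- cbind(
            data.frame(study_id = study_ids[i], diagnosis = diag_vec,
                       age = age, sex = sex_vec, icv = icv,
                       stringsAsFactors = FALSE),
            as.data.frame(meas))
    }
    subjects <- do.call(rbind, tabs)
    rownames(subjects) <- NULL

    truth <- data.frame(
        study_id = rep(study_ids, times = R),
        region = rep(config$regions, each = K),
        delta = as.vector(delta),
        stringsAsFactors = FALSE)
    attr(truth, "MTrue") <- config$MTrue
    attr(truth, "SigmaTrue") <- config$SigmaTrue

    list(cohort = StudyCohort(subjects), truth = truth, config = config)
}

# Desikan-Killiany cortical parcels (34 bilateral) and the seven bilateral
# subcortical segmentations
.DK_PARCELS <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
.SUBCORTICAL <- c("thalamus", "caudate", "putamen", "pallidum",
                  "hippocampus", "amygdala", "accumbens")

#' Standard regional-measure names (150 features)
#'
#' Left/right cortical thickness and surface area for the 34
#' Desikan-Killiany parcels plus left/right volumes of the seven subcortical
#' structures: 68 + 68 + 14 = 150 names.
#' @return character vector of length 150.
#' @export
standardRegionNames <- function() {
    cortical <- as.vector(outer(c("lh", "rh"), .DK_PARCELS, paste, sep = "_"))
    c(paste0(cortical, "_thickness"),
      paste0(cortical, "_area"),
      as.vector(outer(c("lh", "rh"), .SUBCORTICAL, paste, sep = "_")))
}

#' Default consortium-scale synthetic configuration
#'
#' The reference synthetic world used throughout the package: 21 studies
#' totalling 903 cases and 996 controls (1,899 subjects), per-study sizes
#' spanning roughly 20 to 250, the 150 standard regional measures, small
#' negative overarching truth (MTrue = -0.1, SigmaTrue = 0.1), mild age and
#' sex effects, and heterogeneous additive and multiplicative site effects.
#'
#' @param regions region names to simulate; defaults to all 150. Pass a
#'   subset (e.g. \code{standardRegionNames()[1:4]}) for cheaper runs.
#' @param seed integer seed.
#' @return A \code{\link{syntheticConfig}}.
#' @examples
#' cfg <- defaultMultistudyConfig()
#' cfg$nStudies
#' sum(cfg$caseCounts)
#' @export
defaultMultistudyConfig <- function(regions = standardRegionNames(),
                                    seed = 20230101L) {
    sizes <- c(20L, 26L, 32L, 38L, 44L, 50L, 57L, 63L, 69L, 75L, 81L, 87L,
               93L, 99L, 107L, 115L, 125L, 137L, 151L, 180L, 250L)
    stopifnot(sum(sizes) == 1899L)
    cases <- pmax(as.integer(floor(sizes * 903 / 1899)), 1L)
    shortfall <- 903L - sum(cases)
    if (shortfall > 0L) {
        top <- order(sizes, decreasing = TRUE)[seq_len(shortfall)]
        cases[top] <- cases[top] + 1L
    }
    K <- length(sizes)
    syntheticConfig(
        nStudies = K,
        studySizes = sizes,
        caseCounts = cases,
        maleFraction = 0.6,
        regions = regions,
        MTrue = -0.1,
        SigmaTrue = 0.1,
        betaAge = -0.005,
        betaSex = 0.02,
        betaIcv = 2e-8,
        siteShift = seq(-0.12, 0.12, length.out = K),
        siteScale = seq(0.85, 1.2, length.out = K),
        baseline = 2.5,
        residualSd = 0.15,
        seed = seed)
}
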