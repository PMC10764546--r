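#' Read / write the subject-table CSV schema
#'
#' The subject table is a plain CSV with header
#' \code{study_id,diagnosis,age,sex,icv,<region...>}, one row per subject.
#' \code{readSubjectTable()} validates the schema and returns a
#' \linkS4class{StudyCohort}; \code{writeSubjectTable()} writes a cohort (or
#' a subject-table data.frame) back out so every table round-trips
#' losslessly.
#'
#' @param path CSV file path.
#' @param harmonized provenance flag for the constructed cohort.
#' @return \code{readSubjectTable()} returns a \linkS4class{StudyCohort}.
#' @export
readSubjectTable <- function(path, harmonized = FALSE) {
    if (!file.exists(path)) stop("cannot read subject table: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    issues <- validateSubjectTable(df)
    fatal <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(fatal))
        stop("invalid subject table: ",
             paste(fatal$detail, collapse = "; "))
    StudyCohort(df, harmonized = harmonized)
}

#' @rdname readSubjectTable
#' @param x a \linkS4class{StudyCohort} or subject-table data.frame.
#' @export
writeSubjectTable <- function(x, path) {
    if (is(x, "StudyCohort")) x <- asSubjectTable(x)
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Validate a subject table
#'
#' Machine-readable schema and content checks: required columns, diagnosis
#' and sex coding, missing or non-finite values, and per-study presence of
#' both diagnosis groups (single-group studies cannot contribute an effect
#' size and are excluded downstream).
#'
#' @param x subject-table data.frame or a CSV path.
#' @return data.frame with columns \code{check}, \code{severity}
#'   (\code{"error"} or \code{"warning"}) and \code{detail}; zero rows when
#'   the table is clean.
#' @export
validateSubjectTable <- function(x) {
    if (is.character(x)) {
        if (!file.exists(x)) stop("cannot read subject table: ", x)
        x <- utils::read.csv(x, stringsAsFactors = FALSE)
    }
    issue <- function(check, severity, detail)
        data.frame(check = check, severity = severity, detail = detail,
                   stringsAsFactors = FALSE)
    issues <- list()
    missing_cols <- setdiff(.REQUIRED_COVARIATES, colnames(x))
    if (length(missing_cols))
        issues <- c(issues, lapply(missing_cols, function(cc)
            issue("missing_column", "error",
                  paste0("required column '", cc, "' is absent"))))
    present <- intersect(.REQUIRED_COVARIATES, colnames(x))
    for (cc in present)
        if (anyNA(x[[cc]]))
            issues <- c(issues, list(issue("missing_values", "error",
                paste0("column '", cc, "' contains missing values"))))
    if ("diagnosis" %in% present && !all(x$diagnosis %in% c(0, 1, NA)))
        issues <- c(issues, list(issue("coding", "error",
            "diagnosis must be coded 0 (control) / 1 (case)")))
    if ("sex" %in% present && !all(x$sex %in% c(0, 1, NA)))
        issues <- c(issues, list(issue("coding", "error",
            "sex must be coded 0 (female) / 1 (male)")))
    region_cols <- setdiff(colnames(x), .REQUIRED_COVARIATES)
    if (!length(region_cols))
        issues <- c(issues, list(issue("no_regions", "error",
            "no region columns found")))
    for (rc in region_cols)
        if (!is.numeric(x[[rc]]) || any(!is.finite(x[[rc]]) & !is.na(x[[rc]])))
            issues <- c(issues, list(issue("nonfinite_region", "error",
                paste0("region column '", rc,
                       "' is non-numeric or non-finite"))))
    if (all(c("study_id", "diagnosis") %in% present) &&
        !anyNA(x$diagnosis)) {
        for (sid in unique(as.character(x$study_id))) {
            dvals <- x$diagnosis[x$study_id == sid]
            if (length(unique(dvals)) < 2L)
                issues <- c(issues, list(issue("single_group_study",
                    "warning",
                    paste0("study '", sid, "' has only one diagnosis ",
                           "group and will be excluded from effect-size ",
                           "estimation"))))
        }
    }
    out <- if (length(issues)) do.call(rbind, issues) else
        data.frame(check = character(), severity = character(),
                   detail = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

.readSchemaCsv <- function(path, required, what) {
    if (!file.exists(path)) stop("cannot read ", what, ": ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols))
        stop(what, " is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    df
}

#' Read / write the effect-size and omega CSV schemas
#'
#' Effect-size tables use the header \code{study_id,region,y,t,df,n1,n2};
#' omega tables use \code{study_id,region,omega,n_reps,normality_p}.
#'
#' @param path CSV path.
#' @param x the table to write.
#' @name result-io
NULL

#' @rdname result-io
#' @export
readEffectSizeTable <- function(path)
    .readSchemaCsv(path, c("study_id", "region", "y", "t", "df", "n1", "n2"),
                   "effect-size table")

#' @rdname result-io
#' @export
writeEffectSizeTable <- function(x, path) {
    utils::write.csv(x[, c("study_id", "region", "y", "t", "df", "n1", "n2")],
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname result-io
#' @export
readOmegaTable <- function(path)
    .readSchemaCsv(path, c("study_id", "region", "omega", "n_reps",
                           "normality_p"), "omega table")

#' @rdname result-io
#' @export
writeOmegaTable <- function(x, path) {
    utils::write.csv(x[, c("study_id", "region", "omega", "n_reps",
                           "normality_p")],
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Persist posterior draws as long-format CSV with a JSON sidecar
#'
#' One row per retained draw (\code{region,parameter,chain,draw,value});
#' priors, seeds and sampler settings go to \code{<path>.json}.
#'
#' @param ps a \linkS4class{PosteriorSamples}.
#' @param path CSV path.
#' @export
writePosteriorSamples <- function(ps, path) {
    stopifnot(is(ps, "PosteriorSamples"))
    d <- ps@draws
    dims <- dim(d)
    long <- data.frame(
        region = ps@region,
        parameter = rep(dimnames(d)[[3]], each = dims[1] * dims[2]),
        chain = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
        draw = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
        value = as.vector(d), stringsAsFactors = FALSE)
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
    p <- ps@priors
    meta <- ps@meta[c("iters", "burnIn", "thin", "seed", "omegaConvention")]
    jsonlite::write_json(
        list(region = ps@region,
             priors = list(m0 = p@m0, v0 = p@v0, gammaMode = p@gammaMode,
                           gammaSd = p@gammaSd, a = p@a, b = p@b),
             meta = meta, studyIds = ps@meta$studyIds),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

.RUN_CONFIG_DEFAULTS <- list(
    input = NULL, outDir = NULL, harmonize = TRUE, reps = 1000,
    chains = 4, iterations = 100000, burnIn = NULL, thin = 1,
    m0 = 0, v0 = 10, gammaMode = 1, gammaSd = 10,
    pointEstimate = "mode", omegaConvention = "sd", seed = 1L,
    regions = NULL)

#' Pipeline run configuration
#'
#' Assembles and validates the settings of a full pipeline run. Unknown
#' keys are rejected; numeric settings must be positive. Defaults follow
#' routine practice: 1,000 subsampling repetitions, 4 chains of 100,000
#' iterations with the first half discarded, mode point estimates, and the
#' mild Normal(0, 10) / Gamma(mode 1, SD 10) priors.
#'
#' @param ... settings overriding the defaults (see
#'   \code{hbshrink:::.RUN_CONFIG_DEFAULTS} for the full list).
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
    override <- list(...)
    unknown <- setdiff(names(override), names(.RUN_CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(.RUN_CONFIG_DEFAULTS, override,
                             keep.null = TRUE)
    for (key in c("reps", "chains", "iterations", "thin", "v0", "gammaMode",
                  "gammaSd"))
        if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
            cfg[[key]] <= 0)
            stop("configuration key '", key, "' must be a positive scalar")
    if (!is.null(cfg$burnIn) &&
        (cfg$burnIn < 0 || cfg$burnIn >= cfg$iterations))
        stop("burnIn must lie in [0, iterations)")
    cfg$pointEstimate <- match.arg(cfg$pointEstimate, c("mode", "mean"))
    cfg$omegaConvention <- match.arg(cfg$omegaConvention,
                                     c("sd", "variance"))
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname runConfig
#' @param path YAML file of settings.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("cannot read config: ", path)
    do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full recalibration pipeline
#'
#' Chains every stage: load (or simulate) the cohort, harmonize, compute
#' per-study effect sizes, estimate the subsampled sampling SDs, fit the
#' hierarchical model per region, and summarize. Per-stage seeds are derived
#' from the master seed, and a JSON run log records the seed, configuration
#' hash and package version. If \code{config$outDir} is set, every table is
#' written there in its documented CSV schema.
#'
#' @param config a [runConfig()].
#' @return list with elements \code{cohort}, \code{harmonized}, \code{es},
#'   \code{omega}, \code{fits}, \code{summaries} (posterior summaries of M
#'   and the mu_i per region), \code{report} (the
#'   \linkS4class{AdjustmentReport}) and \code{log}.
#' @export
runPipeline <- function(config = runConfig()) {
    stopifnot(inherits(config, "RunConfig"))
    seeds <- deriveSeeds(config$seed, 3L)
    cohort <- if (is.null(config$input)) {
        cfg <- defaultMultistudyConfig(
            regions = if (is.null(config$regions)) standardRegionNames()
                      else config$regions,
            seed = seeds[1])
        simulateCohort(cfg)$cohort
    } else readSubjectTable(config$input)
    harmonized <- if (config$harmonize) combatHarmonize(cohort) else cohort
    es <- computeEffectSizes(harmonized)
    keep <- unique(es$study_id)
    profiles <- studyProfiles(harmonized)
    profiles <- profiles[profiles$study_id %in% keep, , drop = FALSE]
    om <- estimateOmega(harmonized, profiles, reps = config$reps,
                        seed = seeds[2])
    burn <- if (is.null(config$burnIn)) floor(config$iterations / 2) else
        config$burnIn
    priors <- priorSpec(config$m0, config$v0, config$gammaMode,
                        config$gammaSd)
    fits <- fitAllRegions(es, om, priors = priors, chains = config$chains,
                          iters = config$iterations, burnIn = burn,
                          thin = config$thin, seed = seeds[3],
                          omegaConvention = config$omegaConvention)
    summaries <- do.call(rbind, lapply(fits, function(ps)
        posteriorSummary(ps, grep("^(M$|mu\\[)",
                                  paramNames(ps), value = TRUE))))
    rownames(summaries) <- NULL
    report <- adjustedEffectSizes(es, fits, om,
                                  pointEstimate = config$pointEstimate)
    log <- list(seed = config$seed, stage_seeds = seeds,
                config_hash = configHash(unclass(config)),
                package_version =
                    as.character(utils::packageVersion("hbshrink")),
                harmonized = config$harmonize,
                n_studies = length(unique(es$study_id)),
                n_regions = length(fits),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        out <- function(f) file.path(config$outDir, f)
        writeSubjectTable(harmonized, out("subjects_harmonized.csv"))
        writeEffectSizeTable(es, out("effect_sizes.csv"))
        writeOmegaTable(om, out("omega.csv"))
        utils::write.csv(summaries, out("posterior_summary.csv"),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(adjustmentTable(report), out("adjustment.csv"),
                         row.names = FALSE, quote = FALSE)
        st <- adjustmentStats(report)
        jsonlite::write_json(
            list(point_estimate = report@pointEstimate,
                 t_statistic = st$tStat, p_value = st$pValue,
                 r_n = st$rN, r_omega = st$rOmega, flags = st$flags),
            out("adjustment_summary.json"), auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                             digits = NA)
    }
    invisible(list(cohort = cohort, harmonized = harmonized, es = es,
                   omega = om, fits = fits, summaries = summaries,
                   report = report, log = log))
}
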