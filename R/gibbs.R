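#' Convert a Gamma mode/SD specification to shape and rate
#'
#' Reparameterizes a Gamma distribution stated by its mode and standard
#' deviation (the natural scale for a weakly informative precision prior)
#' into shape \code{a} and rate \code{b}:
#' \deqn{b = (mode + \sqrt{mode^2 + 4 sd^2}) / (2 sd^2), \quad
#'       a = 1 + mode \cdot b,}
#' so that \code{(a - 1)/b} equals the requested mode and
#' \code{sqrt(a)/b} the requested SD exactly.
#'
#' @param mode,sd desired Gamma mode and SD (both > 0).
#' @return named numeric vector \code{c(a = shape, b = rate)}.
#' @examples
#' gammaModeSdToShapeRate(1, 10)
#' @export
gammaModeSdToShapeRate <- function(mode, sd) {
    if (mode <= 0 || sd <= 0) stop("mode and sd must be > 0")
    b <- (mode + sqrt(mode^2 + 4 * sd^2)) / (2 * sd^2)
    c(a = 1 + mode * b, b = b)
}

#' Construct a PriorSpec
#'
#' Mildly informative defaults: the overarching mean M gets a
#' Normal(0, variance 10) prior, and both precisions (1/sigma^2 and
#' 1/Sigma^2) get the Gamma prior with mode 1 and SD 10 — appropriate when
#' case-control effect sizes typically range between -1 and 1. The
#' sensitivity arms use \code{gammaSd = 0.1} (more informative) and
#' \code{gammaSd = 100} (less informative).
#'
#' @param m0 prior mean of M.
#' @param v0 prior variance of M (> 0).
#' @param gammaMode,gammaSd mode and SD of the Gamma prior on the
#'   precisions.
#' @return A \linkS4class{PriorSpec}.
#' @export
priorSpec <- function(m0 = 0, v0 = 10, gammaMode = 1, gammaSd = 10) {
    ab <- gammaModeSdToShapeRate(gammaMode, gammaSd)
    new("PriorSpec", m0 = m0, v0 = v0, gammaMode = gammaMode,
        gammaSd = gammaSd, a = unname(ab["a"]), b = unname(ab["b"]))
}

setMethod("show", "PriorSpec", function(object) {
    cat("PriorSpec: M ~ Normal(", object@m0, ", var ", object@v0, ");",
        " precisions ~ Gamma(mode ", object@gammaMode, ", sd ",
        object@gammaSd, ") [shape ", signif(object@a, 6), ", rate ",
        signif(object@b, 6), "]\n", sep = "")
})

#' Gibbs sampler for the hierarchical effect-size model
#'
#' Fits, for one region, the three-level hierarchy
#' \deqn{y_i \sim N(\mu_i, \omega_i^2 / \tau), \quad
#'       \mu_i \sim N(M, 1/T), \quad
#'       M \sim N(m_0, v_0), \quad \tau, T \sim Gamma(a, b),}
#' where \code{y_i} is study i's observed Cohen's d and \code{omega_i} its
#' subsampled sampling SD, by cycling the exact conjugate full conditionals.
#' Under the default \code{omegaConvention = "sd"}, omega multiplies the
#' study-level standard deviation, so the study-level precision is
#' \code{tau / omega_i^2} and \code{tau = 1} means the model's study-level
#' SD equals the subsampled SD; \code{"variance"} instead reads omega as a
#' variance multiplier (precision \code{tau / omega_i}).
#'
#' Chains start from independent overdispersed draws: tau and T from their
#' Gamma prior, M from Normal(m0, 4 v0), mu_i from Normal(y_i, 1).
#'
#' @param y numeric vector of K observed effect sizes (optionally named by
#'   study id).
#' @param omega numeric vector of K positive sampling SDs.
#' @param priors a [priorSpec()].
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iters iterations per chain.
#' @param burnIn iterations discarded per chain (default: first half).
#' @param thin thinning interval.
#' @param seed optional integer seed.
#' @param omegaConvention \code{"sd"} (default) or \code{"variance"}.
#' @param fixTau,fixT optional fixed values for the precisions (degenerate
#'   priors); used for closed-form validation.
#' @param region region label carried into the result.
#' @return A \linkS4class{PosteriorSamples} over parameters \code{M},
#'   \code{mu[1] ... mu[K]}, \code{tau}, \code{T}.
#' @examples
#' y <- c(-0.3, 0.1, -0.2, 0.4, -0.1)
#' om <- rep(0.3, 5)
#' ps <- gibbsSample(y, om, chains = 2, iters = 2000, seed = 1)
#' posteriorSummary(ps)[1:3, ]
#' @export
gibbsSample <- function(y, omega, priors = priorSpec(), chains = 4,
                        iters = 100000, burnIn = floor(iters / 2), thin = 1,
                        seed = NULL,
                        omegaConvention = c("sd", "variance"),
                        fixTau = NULL, fixT = NULL,
                        region = NA_character_) {
    omegaConvention <- match.arg(omegaConvention)
    K <- length(y)
    if (K < 2) stop("need at least 2 studies")
    if (length(omega) != K) stop("y and omega must have equal length")
    if (any(omega <= 0)) stop("all omega must be > 0")
    stopifnot(is(priors, "PriorSpec"), iters > burnIn, thin >= 1)
    if (chains < 2)
        warning("fewer than 2 chains: convergence diagnostics ",
                "(Gelman-Rubin) will be unavailable")
    if (!is.null(seed)) set.seed(seed)
    wpow <- if (omegaConvention == "sd") omega^2 else omega
    kept <- (iters - burnIn) %/% thin
    pnames <- c("M", sprintf("mu[%d]", seq_len(K)), "tau", "T")
    draws <- array(NA_real_, dim = c(kept, chains, K + 3),
                   dimnames = list(NULL, NULL, pnames))
    for (ch in seq_len(chains)) {
        tau0 <- if (is.null(fixTau))
            max(stats::rgamma(1, priors@a, rate = priors@b), 1e-6) else fixTau
        T0 <- if (is.null(fixT))
            max(stats::rgamma(1, priors@a, rate = priors@b), 1e-6) else fixT
        M0 <- stats::rnorm(1, priors@m0, sqrt(4 * priors@v0))
        mu0 <- stats::rnorm(K, y, 1)
        draws[, ch, ] <- gibbs_chain_cpp(
            as.numeric(y), wpow, priors@m0, priors@v0, priors@a, priors@b,
            as.integer(iters), as.integer(burnIn), as.integer(thin),
            mu0, M0, tau0, T0, !is.null(fixTau), !is.null(fixT))
    }
    new("PosteriorSamples", draws = draws, region = as.character(region),
        priors = priors,
        meta = list(y = as.numeric(y), omega = as.numeric(omega),
                    studyIds = names(y), iters = iters, burnIn = burnIn,
                    thin = thin, seed = seed,
                    omegaConvention = omegaConvention,
                    fixTau = fixTau, fixT = fixT))
}

#' Fit the hierarchical model independently for every region
#'
#' Joins the effect-size and omega tables on (study, region), checks the
#' keys match exactly, and runs [gibbsSample()] once per region. Per-region
#' seeds are derived reproducibly from the master seed via the sorted region
#' names, so results do not depend on evaluation order.
#'
#' @param es effect-size table from [computeEffectSizes()].
#' @param om omega table from [estimateOmega()].
#' @param priors a [priorSpec()].
#' @param chains,iters,burnIn,thin,omegaConvention passed to
#'   [gibbsSample()].
#' @param seed master integer seed.
#' @return named list (one \linkS4class{PosteriorSamples} per region).
#' @export
fitAllRegions <- function(es, om, priors = priorSpec(), chains = 4,
                          iters = 100000, burnIn = floor(iters / 2),
                          thin = 1, seed = 1L,
                          omegaConvention = c("sd", "variance")) {
    omegaConvention <- match.arg(omegaConvention)
    key_es <- paste(es$study_id, es$region, sep = "\r")
    key_om <- paste(om$study_id, om$region, sep = "\r")
    miss_in_om <- setdiff(key_es, key_om)
    miss_in_es <- setdiff(key_om, key_es)
    if (length(miss_in_om) || length(miss_in_es))
        stop("effect-size and omega tables do not share identical ",
             "(study, region) keys; missing from omega: ",
             paste(gsub("\r", ":", utils::head(miss_in_om, 5)), collapse = ", "),
             "; missing from effect sizes: ",
             paste(gsub("\r", ":", utils::head(miss_in_es, 5)), collapse = ", "))
    merged <- merge(es, om[, c("study_id", "region", "omega")],
                    by = c("study_id", "region"))
    regions <- sort(unique(merged$region))
    seeds <- deriveSeeds(seed, length(regions))
    names(seeds) <- regions
    fits <- vector("list", length(regions))
    names(fits) <- regions
    for (r in regions) {
        sub <- merged[merged$region == r, ]
        sub <- sub[order(sub$study_id), ]
        yr <- stats::setNames(sub$y, sub$study_id)
        fits[[r]] <- gibbsSample(yr, sub$omega, priors = priors,
                                 chains = chains, iters = iters,
                                 burnIn = burnIn, thin = thin,
                                 seed = seeds[[r]],
                                 omegaConvention = omegaConvention,
                                 region = r)
    }
    fits
}
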