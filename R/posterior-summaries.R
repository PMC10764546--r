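#' Extract draws for one parameter
#'
#' @param ps a \linkS4class{PosteriorSamples}.
#' @param parameter parameter name, e.g. \code{"M"} or \code{"mu[3]"}.
#' @param pooled if \code{TRUE} (default) return one vector pooling all
#'   chains; otherwise a draws x chains matrix.
#' @return numeric vector or matrix.
#' @export
extractDraws <- function(ps, parameter, pooled = TRUE) {
    stopifnot(is(ps, "PosteriorSamples"))
    pn <- dimnames(ps@draws)[[3]]
    if (!parameter %in% pn)
        stop("unknown parameter '", parameter, "'; available: ",
             paste(utils::head(pn, 8), collapse = ", "), ", ...")
    m <- ps@draws[, , parameter, drop = TRUE]
    m <- matrix(m, nrow = dim(ps@draws)[1])
    if (pooled) as.vector(m) else m
}

#' @rdname extractDraws
#' @export
paramNames <- function(ps) dimnames(ps@draws)[[3]]

setMethod("show", "PosteriorSamples", function(object) {
    d <- dim(object@draws)
    cat("PosteriorSamples", if (!is.na(object@region))
        paste0("for region '", object@region, "'"), "\n")
    cat(" ", d[1], "retained draws x", d[2], "chains x", d[3],
        "parameters\n")
    cat("  iterations:", object@meta$iters, " burn-in:", object@meta$burnIn,
        " thin:", object@meta$thin, "\n")
})

#' Posterior mode via kernel density estimation
#'
#' The highest-density point of the draws: a Gaussian kernel density
#' estimate with Silverman's bandwidth is evaluated on a 512-point grid
#' spanning the range of the draws, and its argmax is returned. Used as the
#' Bayesian-adjusted point estimate.
#'
#' @param draws numeric vector of pooled posterior draws (>= 1,000 for a
#'   stable mode in routine use; fewer are allowed).
#' @return scalar mode estimate. A constant vector returns the constant.
#' @export
posteriorMode <- function(draws) {
    rng <- range(draws)
    if (rng[1] == rng[2]) return(rng[1])
    dens <- stats::density(draws, bw = "nrd0", n = 512,
                           from = rng[1], to = rng[2])
    dens$x[which.max(dens$y)]
}

#' Highest-density interval
#'
#' Shortest contiguous interval containing \code{ceiling(prob * N)} of the
#' sorted draws — for unimodal posteriors, the narrowest credible interval
#' at the requested mass.
#'
#' @param draws numeric vector of pooled draws.
#' @param prob interval mass in (0, 1); 0.95 by default.
#' @return numeric vector \code{c(low, high)}.
#' @export
hdi <- function(draws, prob = 0.95) {
    stopifnot(prob > 0, prob < 1)
    n <- length(draws)
    if (n < 20) warning("fewer than 20 draws: interval is unstable")
    s <- sort(draws)
    m <- min(ceiling(prob * n), n)
    if (m == n) return(c(s[1], s[n]))
    lo <- seq_len(n - m + 1)
    width <- s[lo + m - 1] - s[lo]
    i <- which.min(width)
    c(s[i], s[i + m - 1])
}

.asChainMatrix <- function(chains) {
    if (is.list(chains)) chains <- do.call(cbind, chains)
    chains <- as.matrix(chains)
    if (ncol(chains) < 2)
        stop("need at least 2 chains of draws (one column per chain)")
    if (nrow(chains) < 100) stop("chains must have length >= 100")
    chains
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-chain PSRF: each chain is split in half, and
#' \deqn{\hat R = \sqrt{ (W (n-1)/n + B/n) / W }}
#' is computed from the within- (W) and between- (B) sequence variances of
#' the split halves. Values near 1 indicate the chains have mixed.
#'
#' @param chains draws x chains matrix (or list of equal-length vectors).
#' @return scalar PSRF.
#' @export
gelmanRubin <- function(chains) {
    x <- .asChainMatrix(chains)
    if (ncol(x) >= 2) {
        dup <- duplicated(t(x))
        if (any(dup))
            warning("some chains are identical copies; zero between-chain ",
                    "variance is suspicious")
    }
    n2 <- floor(nrow(x) / 2)
    halves <- cbind(x[seq_len(n2), , drop = FALSE],
                    x[n2 + seq_len(n2), , drop = FALSE])
    W <- mean(apply(halves, 2, stats::var))
    B <- n2 * stats::var(colMeans(halves))
    if (W == 0) {
        warning("zero within-chain variance; PSRF undefined, returning 1")
        return(1)
    }
    sqrt((W * (n2 - 1) / n2 + B / n2) / W)
}

# autocorrelation function via FFT (biased autocovariance, normalized)
.acfFFT <- function(x) {
    n <- length(x)
    xc <- x - mean(x)
    npad <- 2^ceiling(log2(2 * n))
    f <- stats::fft(c(xc, rep(0, npad - n)))
    acov <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / npad
    acov / acov[1]
}

#' Effective sample size with Geyer truncation
#'
#' Autocorrelation-adjusted count of independent-equivalent draws:
#' \deqn{ESS = C n / (1 + 2 \sum_k \rho_k)}
#' with the lagged autocorrelations averaged across the C chains and the sum
#' truncated by Geyer's initial positive sequence (consecutive lag pairs are
#' summed and the sum stops before the first negative pair). Antithetic
#' chains can legitimately yield ESS above the raw draw count; this is not
#' clipped.
#'
#' @param chains draws x chains matrix (or list of equal-length vectors).
#' @return scalar ESS. A constant chain yields 0 with a warning.
#' @export
effectiveSampleSize <- function(chains) {
    x <- .asChainMatrix(chains)
    if (all(apply(x, 2, stats::var) == 0)) {
        warning("constant chain: effective sample size reported as 0")
        return(0)
    }
    n <- nrow(x)
    rho <- rowMeans(vapply(seq_len(ncol(x)), function(c) .acfFFT(x[, c]),
                           numeric(n)))
    npairs <- floor(n / 2)
    gamma_pairs <- rho[2 * seq_len(npairs) - 1] + rho[2 * seq_len(npairs)]
    neg <- which(gamma_pairs < 0)
    keep <- if (length(neg)) neg[1] - 1L else npairs
    denom <- -1 + 2 * sum(gamma_pairs[seq_len(keep)])
    denom <- max(denom, .Machine$double.eps)
    ncol(x) * n / denom
}

#' Summarize a posterior fit
#'
#' One row per parameter: KDE posterior mode, mean, 95\% HDI bounds,
#' split-chain Gelman-Rubin PSRF and Geyer-truncated ESS. Mode and HDI are
#' computed on the draws pooled across chains; the diagnostics use the chain
#' structure. With a single chain the PSRF is \code{NA}.
#'
#' @param ps a \linkS4class{PosteriorSamples}.
#' @param parameters parameters to summarize (default: all).
#' @param prob HDI mass.
#' @return data.frame with columns \code{region}, \code{parameter},
#'   \code{mode}, \code{mean}, \code{hdi_low}, \code{hdi_high}, \code{rhat},
#'   \code{ess}.
#' @export
posteriorSummary <- function(ps, parameters = paramNames(ps), prob = 0.95) {
    stopifnot(is(ps, "PosteriorSamples"))
    single_chain <- dim(ps@draws)[2] < 2
    rows <- lapply(parameters, function(p) {
        m <- extractDraws(ps, p, pooled = FALSE)
        pooled <- as.vector(m)
        h <- hdi(pooled, prob)
        data.frame(region = ps@region, parameter = p,
                   mode = posteriorMode(pooled), mean = mean(pooled),
                   hdi_low = h[1], hdi_high = h[2],
                   rhat = if (single_chain) NA_real_ else gelmanRubin(m),
                   ess = if (single_chain) NA_real_
                         else effectiveSampleSize(m),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
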