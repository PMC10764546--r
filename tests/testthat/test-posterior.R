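test_that("the KDE posterior mode finds the highest-density point", {
    set.seed(31)
    # average over replicates: the single-draw mode estimator has KDE noise
    # of a few thousandths at this n
    errs <- replicate(10, abs(posteriorMode(rnorm(1e5, 0.3, 0.1)) - 0.3))
    expect_lt(mean(errs), 0.01)
    expect_identical(posteriorMode(rep(0.5, 100)), 0.5)
    g_errs <- replicate(5, abs(posteriorMode(rgamma(1e5, 3, 2)) - 1.0))
    expect_lt(mean(g_errs), 0.05)
})

test_that("the HDI is the shortest interval at the requested mass", {
    set.seed(32)
    x <- rnorm(2e5)
    h <- hdi(x, 0.95)
    expect_lt(abs(h[1] + 1.96), 0.03)
    expect_lt(abs(h[2] - 1.96), 0.03)
    # never wider than the equal-tailed interval
    et <- unname(quantile(x, c(0.025, 0.975)))
    expect_lte(diff(h), diff(et) + 1e-8)
    # prob -> 1 limit is the range
    expect_equal(hdi(x, 0.999999), range(x))
    u <- runif(1e5)
    expect_lt(abs(diff(hdi(u, 0.95)) - 0.95), 0.01)
    expect_warning(hdi(rnorm(10)), "unstable")
    skew <- rgamma(2e5, 2, 1)
    expect_lte(diff(hdi(skew, 0.9)),
               diff(unname(quantile(skew, c(0.05, 0.95)))))
})

test_that("the split-chain PSRF separates mixed from unmixed chains", {
    set.seed(33)
    good <- matrix(rnorm(4 * 50000), ncol = 4)
    expect_lt(gelmanRubin(good), 1.01)
    bad <- cbind(rnorm(5000), rnorm(5000) + 5)
    expect_gt(gelmanRubin(bad), 1.5)
    one <- rnorm(1000)
    expect_warning(r <- gelmanRubin(cbind(one, one)), "identical")
    expect_lt(abs(r - 1), 0.05)
    expect_error(gelmanRubin(matrix(rnorm(1000), ncol = 1)),
                 "at least 2 chains")
    expect_error(gelmanRubin(matrix(rnorm(8), ncol = 2)), ">= 100")
})

test_that("the effective sample size tracks the autocorrelation structure", {
    set.seed(34)
    iid <- matrix(rnorm(100000), ncol = 4)
    ess <- effectiveSampleSize(iid)
    expect_lt(abs(ess - 100000) / 100000, 0.10)

    phi <- 0.9
    ar <- vapply(1:2, function(i)
        as.vector(arima.sim(list(ar = phi), 50000)), numeric(50000))
    ess_ar <- effectiveSampleSize(ar)
    expected <- 100000 * (1 - phi) / (1 + phi)
    expect_lt(abs(ess_ar - expected) / expected, 0.20)
    # independent implementation agrees to the same order
    ess_coda <- sum(apply(ar, 2, function(x)
        coda::effectiveSize(coda::mcmc(x))))
    expect_lt(abs(ess_ar - ess_coda) / ess_coda, 0.25)

    anti <- vapply(1:2, function(i)
        as.vector(arima.sim(list(ar = -0.5), 50000)), numeric(50000))
    expect_gt(effectiveSampleSize(anti), 100000)  # not clipped at C*n

    expect_warning(z <- effectiveSampleSize(matrix(1, 200, 2)), "constant")
    expect_identical(z, 0)
})

test_that("posterior summaries are internally coherent", {
    w <- worldFixture()
    ps <- w$fits[[1]]
    s <- posteriorSummary(ps)
    expect_setequal(s$parameter, paramNames(ps))
    expect_true(all(s$hdi_low <= s$mode & s$mode <= s$hdi_high))
    expect_true(all(s$ess > 0))
    # split-halves PSRF can dip below 1 by O(1/n) for well-mixed chains
    expect_true(all(s$rhat >= 1 - 1e-3))
    expect_true(all(s$rhat < 1.05))
    # symmetric posterior: mode and mean agree within Monte-Carlo error
    # plus the KDE bandwidth (the mode's resolution)
    sM <- s[s$parameter == "M", ]
    pooled <- extractDraws(ps, "M")
    mcse <- sd(pooled) / sqrt(sM$ess)
    expect_lt(abs(sM$mode - sM$mean), 5 * mcse + stats::bw.nrd0(pooled))
})

test_that("every study-level posterior shrinks toward the overarching mean", {
    w <- worldFixture()
    for (r in names(w$fits)) {
        ps <- w$fits[[r]]
        y <- ps@meta$y
        M_hat <- mean(extractDraws(ps, "M"))
        for (i in seq_along(y)) {
            d <- extractDraws(ps, sprintf("mu[%d]", i), pooled = FALSE)
            mu_hat <- mean(d)
            mcse <- sd(d) / sqrt(effectiveSampleSize(d))
            expect_lte(abs(mu_hat - M_hat), abs(y[i] - M_hat) + 3 * mcse)
        }
    }
})

test_that("adjustments vanish in the no-shrinkage limit and zero variance is flagged", {
    sim <- smallCohort(nStudies = 3, studySizes = 100, seed = 61)
    es <- computeEffectSizes(sim$cohort)
    om <- data.frame(study_id = es$study_id, region = es$region,
                     omega = 1e-4, n_reps = 100L, normality_p = 0.5)
    fits <- fitAllRegions(es, om, chains = 2, iters = 3000, seed = 62)
    rep0 <- adjustedEffectSizes(es, fits, om)
    expect_true(all(adjustmentTable(rep0)$adjustment < 0.01))

    # constant draws equal to y reproduce y exactly: zero-variance flag
    fits_const <- fits
    for (r in names(fits_const)) {
        ps <- fits_const[[r]]
        K <- length(ps@meta$y)
        d <- ps@draws
        for (i in seq_len(K))
            d[, , sprintf("mu[%d]", i)] <- ps@meta$y[i]
        fits_const[[r]]@draws <- d
    }
    repc <- adjustedEffectSizes(es, fits_const, om)
    expect_true(any(grepl("zero-variance", repc@flags)))
    expect_true(is.na(adjustmentStats(repc)$tStat))
})

test_that("adjustment magnitudes correlate with size and sampling SD in the expected directions", {
    w <- worldFixture()
    rep <- adjustedEffectSizes(w$es, w$fits, w$om)
    st <- adjustmentStats(rep)
    expect_lt(st$rN, 0)
    expect_gt(st$rOmega, 0)
    expect_gt(st$tStat, 0)
    expect_lt(st$pValue, 0.05)
    tab <- adjustmentTable(rep)
    expect_setequal(paste(tab$study_id, tab$region),
                    paste(w$es$study_id, w$es$region))
    # the posterior mean shrinks at least as much as the mode on average
    rep_mean <- adjustedEffectSizes(w$es, w$fits, w$om,
                                    pointEstimate = "mean")
    expect_gte(mean(adjustmentTable(rep_mean)$adjustment),
               mean(tab$adjustment) - 0.005)
})
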