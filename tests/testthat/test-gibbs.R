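test_that("the Gamma mode/SD reparameterization is exact", {
    ab <- gammaModeSdToShapeRate(1, 10)
    expect_equal(unname(ab["a"]), 1.105125, tolerance = 1e-6)
    expect_equal(unname(ab["b"]), 0.105125, tolerance = 1e-6)
    for (sd in c(0.1, 10, 100)) {
        ab <- gammaModeSdToShapeRate(1, sd)
        expect_equal(unname((ab["a"] - 1) / ab["b"]), 1, tolerance = 1e-9)
        expect_equal(unname(sqrt(ab["a"]) / ab["b"]), sd,
                     tolerance = 1e-9 * sd)
    }
    expect_error(gammaModeSdToShapeRate(0, 1), "> 0")
    expect_error(gammaModeSdToShapeRate(1, -1), "> 0")
})

test_that("priorSpec validates and reports its derived shape/rate", {
    p <- priorSpec()
    expect_s4_class(p, "PriorSpec")
    expect_equal((p@a - 1) / p@b, 1)
    expect_error(priorSpec(v0 = -1), "v0")
    expect_error(priorSpec(gammaMode = 0), "> 0")
})

test_that("gibbsSample validates inputs and is reproducible under a seed", {
    y <- c(-0.2, 0.1, 0.3)
    expect_error(gibbsSample(0.1, 0.1), "at least 2")
    expect_error(gibbsSample(y, c(0.1, -0.1, 0.2)), "omega")
    expect_warning(gibbsSample(y, rep(0.2, 3), chains = 1, iters = 500,
                               seed = 1),
                   "fewer than 2 chains")
    p1 <- gibbsSample(y, rep(0.2, 3), chains = 2, iters = 1000, seed = 4)
    p2 <- gibbsSample(y, rep(0.2, 3), chains = 2, iters = 1000, seed = 4)
    expect_identical(p1@draws, p2@draws)
    expect_equal(dim(p1@draws), c(500L, 2L, 6L))
})

test_that("with negligible sampling SD the data dominate the posterior", {
    y <- seq(-0.5, 0.5, length.out = 21)
    ps <- gibbsSample(y, rep(1e-4, 21), chains = 2, iters = 4000, seed = 5)
    mu_means <- vapply(seq_len(21), function(i)
        mean(extractDraws(ps, sprintf("mu[%d]", i))), numeric(1))
    expect_true(all(abs(mu_means - y) < 1e-3))
})

test_that("with enormous sampling SD the posterior of M reverts to its prior", {
    y <- rep(c(-0.3, 0.4), 5)
    ps <- gibbsSample(y, rep(1e3, 10), chains = 4, iters = 20000, seed = 6)
    M <- extractDraws(ps, "M", pooled = FALSE)
    mcse <- sd(as.vector(M)) / sqrt(effectiveSampleSize(M))
    expect_lt(abs(mean(M)), 5 * mcse)                # prior mean 0
    expect_equal(sd(M), sqrt(10), tolerance = 0.15)  # prior SD sqrt(v0)
})

test_that("study order is exchangeable up to Monte-Carlo error", {
    set.seed(77)
    y <- rnorm(8, -0.1, 0.2)
    om <- runif(8, 0.15, 0.4)
    perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
    ps1 <- gibbsSample(y, om, chains = 4, iters = 20000, seed = 8)
    ps2 <- gibbsSample(y[perm], om[perm], chains = 4, iters = 20000,
                       seed = 8)
    m1 <- mean(extractDraws(ps1, "M"))
    m2 <- mean(extractDraws(ps2, "M"))
    mcse <- sd(extractDraws(ps1, "M")) /
        sqrt(effectiveSampleSize(extractDraws(ps1, "M", pooled = FALSE)))
    expect_lt(abs(m1 - m2), 4 * mcse)
    # mu summaries follow the permutation
    mu1 <- vapply(seq_len(8), function(i)
        mean(extractDraws(ps1, sprintf("mu[%d]", i))), numeric(1))
    mu2 <- vapply(seq_len(8), function(i)
        mean(extractDraws(ps2, sprintf("mu[%d]", i))), numeric(1))
    expect_equal(mu2, mu1[perm], tolerance = 0.05)
})

test_that("the omega-as-variance convention changes the effective weights as intended", {
    y <- c(-0.4, -0.1, 0.2, 0.5)
    om <- c(0.09, 0.25, 0.49, 0.81)  # < 1 vs > 1 straddle
    ps_sd <- gibbsSample(y, om, chains = 2, iters = 5000, seed = 9,
                         omegaConvention = "sd")
    ps_var <- gibbsSample(y, om, chains = 2, iters = 5000, seed = 9,
                          omegaConvention = "variance")
    expect_false(identical(ps_sd@draws, ps_var@draws))
    expect_identical(ps_var@meta$omegaConvention, "variance")
})

test_that("independent per-region fits join on exact keys and ignore evaluation order", {
    w <- worldFixture()
    expect_length(w$fits, 4L)
    expect_setequal(names(w$fits), unique(w$es$region))
    # removing one region from the omega table is a named join error
    om_miss <- w$om[w$om$region != w$om$region[1], ]
    expect_error(fitAllRegions(w$es, om_miss, iters = 200),
                 "missing from omega")
    # shuffling input rows leaves the per-region draws identical
    es_shuf <- w$es[sample(nrow(w$es)), ]
    om_shuf <- w$om[sample(nrow(w$om)), ]
    f2 <- fitAllRegions(es_shuf, om_shuf, chains = 4, iters = 6000,
                        seed = 911L)
    r <- names(w$fits)[2]
    expect_identical(f2[[r]]@draws, w$fits[[r]]@draws)
})

test_that("the hand-written Gibbs sampler agrees with an independent JAGS fit", {
    set.seed(404)
    K <- 8
    y <- rnorm(K, -0.1, 0.3)
    om <- runif(K, 0.15, 0.5)
    ps <- gibbsSample(y, om, chains = 2, iters = 20000, seed = 405)
    p <- priorSpec()
    model <- "
    model {
      for (i in 1:K) {
        y[i] ~ dnorm(mu[i], tau / (om[i] * om[i]))
        mu[i] ~ dnorm(M, T)
      }
      M ~ dnorm(m0, 1 / v0)
      tau ~ dgamma(a, b)
      T ~ dgamma(a, b)
    }"
    jm <- rjags::jags.model(textConnection(model),
                            data = list(y = y, om = om, K = K, m0 = p@m0,
                                        v0 = p@v0, a = p@a, b = p@b),
                            n.chains = 2, quiet = TRUE)
    update(jm, 5000, progress.bar = "none")
    js <- rjags::coda.samples(jm, c("M", "mu"), n.iter = 20000,
                              progress.bar = "none")
    jstats <- summary(js)$statistics
    expect_lt(abs(mean(extractDraws(ps, "M")) - jstats["M", "Mean"]), 0.02)
    expect_lt(abs(sd(extractDraws(ps, "M")) - jstats["M", "SD"]), 0.02)
    for (i in c(1, 4, 8))
        expect_lt(abs(mean(extractDraws(ps, sprintf("mu[%d]", i))) -
                      jstats[sprintf("mu[%d]", i), "Mean"]), 0.02)
})
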