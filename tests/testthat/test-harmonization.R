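test_that("a single study passes through unchanged with a warning", {
    sim <- smallCohort(nStudies = 1, studySizes = 50)
    expect_warning(h <- combatHarmonize(sim$cohort), "single study")
    expect_equal(SummarizedExperiment::assay(h, "measures"),
                 SummarizedExperiment::assay(sim$cohort, "measures"),
                 tolerance = 1e-8)
    expect_true(isHarmonized(h))
})

test_that("an additive between-study shift is removed", {
    cfg <- syntheticConfig(nStudies = 2, studySizes = 200,
                           regions = sprintf("r%d", 1:10),
                           MTrue = 0, SigmaTrue = 0,
                           siteShift = c(0, 10), seed = 8)
    sim <- simulateCohort(cfg)
    gap <- function(cohort) {
        tab <- asSubjectTable(cohort)
        abs(diff(tapply(tab$r1, tab$study_id, mean)))
    }
    gap_pre <- gap(sim$cohort)
    gap_post <- gap(combatHarmonize(sim$cohort))
    expect_lt(gap_post, 0.05 * gap_pre)
})

test_that("the diagnosis signal survives harmonization", {
    cfg <- syntheticConfig(nStudies = 4, studySizes = 800,
                           regions = sprintf("r%d", 1:10),
                           deltaMatrix = matrix(0.5, 4, 10),
                           siteShift = c(-1, 0, 1, 2),
                           siteScale = c(0.6, 1, 1.4, 1.8), seed = 9)
    sim <- simulateCohort(cfg)
    tab_h <- asSubjectTable(combatHarmonize(sim$cohort))
    tab_h$study_id <- "pooled"
    fit <- fitStudyRegression(tab_h, "r1")
    d_pooled <- cohensDFromT(fit$t, fit$n1, fit$n2, fit$df)
    expect_equal(d_pooled, 0.5, tolerance = 0.1 / 0.5)
})

test_that("re-harmonizing changes values far less than the first pass", {
    # empirical-Bayes shrinkage leaves a residual, so harmonization is only
    # approximately idempotent; the second pass must be a small perturbation
    # relative to the first, with the tail driven by the smallest studies
    cfg <- defaultMultistudyConfig(regions = standardRegionNames()[1:20],
                                   seed = 606L)
    sim <- simulateCohort(cfg)
    m0 <- SummarizedExperiment::assay(sim$cohort, "measures")
    h1 <- combatHarmonize(sim$cohort)
    h2 <- combatHarmonize(h1)
    m1 <- SummarizedExperiment::assay(h1, "measures")
    m2 <- SummarizedExperiment::assay(h2, "measures")
    rel1 <- abs(m1 - m0) / apply(m0, 1, sd)
    rel2 <- abs(m2 - m1) / apply(m1, 1, sd)
    expect_lt(median(rel2), 0.05 * median(rel1))
    expect_lt(quantile(rel2, 0.9), 0.1 * quantile(rel1, 0.9))
})

test_that("permuting subject rows permutes the harmonized output identically", {
    cfg <- syntheticConfig(nStudies = 3, studySizes = 80,
                           regions = sprintf("r%d", 1:10),
                           MTrue = -0.2, SigmaTrue = 0.1,
                           siteShift = c(-0.1, 0, 0.1), seed = 10)
    sim <- simulateCohort(cfg)
    m1 <- SummarizedExperiment::assay(combatHarmonize(sim$cohort),
                                      "measures")
    tab <- asSubjectTable(sim$cohort)
    perm <- sample(nrow(tab))
    hp <- combatHarmonize(StudyCohort(tab[perm, ]))
    expect_equal(SummarizedExperiment::assay(hp, "measures"),
                 m1[, perm], tolerance = 1e-10)
})

test_that("degenerate inputs raise explicit errors", {
    sim <- smallCohort(nStudies = 3, studySizes = 40)
    tab <- asSubjectTable(sim$cohort)
    tab$lh_hippocampus[tab$study_id == "study_01"] <- 3.1
    expect_error(combatHarmonize(StudyCohort(tab)), "zero within-study")
    tab2 <- asSubjectTable(sim$cohort)[c(1:2, 41:80, 81:120), ]
    expect_error(combatHarmonize(StudyCohort(tab2)), ">= 3 subjects")
    tab3 <- asSubjectTable(sim$cohort)[, 1:6]  # one region only
    expect_error(combatHarmonize(StudyCohort(tab3)), ">= 2 regions")
})

test_that("effect sizes are insensitive to harmonization when there is no batch effect", {
    cfg <- syntheticConfig(nStudies = 3, studySizes = 150,
                           regions = c("r1", "r2"), MTrue = -0.2,
                           SigmaTrue = 0.1, siteShift = 0, siteScale = 1,
                           seed = 12)
    sens <- harmonizationSensitivity(simulateCohort(cfg)$cohort)
    expect_equal(nrow(sens$difference), 3L * 2L)
    expect_true(all(abs(sens$difference$d_diff) < 0.05))
})

test_that("within-study effect sizes barely move even under strong site shifts", {
    cfg <- syntheticConfig(nStudies = 3, studySizes = 150,
                           regions = c("r1", "r2"), MTrue = -0.2,
                           SigmaTrue = 0.1, siteShift = c(-2, 0, 2),
                           seed = 13)
    sens <- harmonizationSensitivity(simulateCohort(cfg)$cohort)
    # within-study regressions absorb additive site intercepts
    expect_true(all(abs(sens$difference$d_diff) < 0.15))
    expect_equal(sort(paste(sens$harmonized$study_id, sens$harmonized$region)),
                 sort(paste(sens$raw$study_id, sens$raw$region)))
})
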