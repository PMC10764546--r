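# Shared synthetic-world fixture: the 21-study consortium-scale cohort on a
# handful of regions, run through the full pipeline once and cached for all
# test files in the session.
.world_cache <- new.env(parent = emptyenv())

worldFixture <- function() {
    if (!is.null(.world_cache$world)) return(.world_cache$world)
    cfg <- defaultMultistudyConfig(regions = standardRegionNames()[1:4],
                                   seed = 909L)
    sim <- simulateCohort(cfg)
    harm <- combatHarmonize(sim$cohort)
    es <- computeEffectSizes(harm)
    om <- estimateOmega(harm, studyProfiles(harm), reps = 200, seed = 910L)
    fits <- fitAllRegions(es, om, chains = 4, iters = 6000, seed = 911L)
    .world_cache$world <- list(cfg = cfg, sim = sim, harm = harm, es = es,
                               om = om, fits = fits)
    .world_cache$world
}

# small free-standing cohort for cheap schema/IO tests
smallCohort <- function(nStudies = 3, studySizes = 40, seed = 5,
                        regions = c("lh_hippocampus", "rh_hippocampus")) {
    simulateCohort(syntheticConfig(nStudies = nStudies,
                                   studySizes = studySizes,
                                   regions = regions, MTrue = -0.2,
                                   SigmaTrue = 0.1, seed = seed))
}
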