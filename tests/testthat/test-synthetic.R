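test_that("docking generator plants hub degrees and hit fraction", {
    spec <- simulationSpec(nMolecules = 10, nTargets = 80,
                           hitFraction = 0.02,
                           hubSpec = data.frame(molecule = c(1, 2),
                                                degree = c(62, 40)),
                           seed = 5)
    tab <- generateDockingTable(spec)
    expect_equal(nrow(tab), 10L * 80L)
    hits <- selectHits(tab, 6.0)
    expect_equal(sum(hits$molecule_id == "MOL001"), 62L)
    expect_equal(sum(hits$molecule_id == "MOL002"), 40L)

    ## determinism and seed sensitivity
    expect_identical(generateDockingTable(spec), tab)
    spec2 <- simulationSpec(nMolecules = 10, nTargets = 80,
                            hitFraction = 0.02,
                            hubSpec = data.frame(molecule = c(1, 2),
                                                 degree = c(62, 40)),
                            seed = 6)
    expect_false(identical(generateDockingTable(spec2), tab))

    ## no hits world
    none <- simulationSpec(nMolecules = 5, nTargets = 20, hitFraction = 0,
                           hubSpec = data.frame(molecule = integer(),
                                                degree = integer()),
                           seed = 1)
    expect_equal(nrow(selectHits(generateDockingTable(none), 6.0)), 0L)

    ## impossible hub degree is a spec error
    expect_error(simulationSpec(nTargets = 50,
                                hubSpec = data.frame(molecule = 1,
                                                     degree = 62)),
                 "exceeds n_targets")
})

test_that("annotation generator satisfies eligibility prerequisites", {
    spec <- tinySpec(seed = 2)
    ann <- generateAnnotations(spec)
    expect_true(all(lengths(forwardMap(ann$targetPathway)) >= 1L))
    expect_equal(length(ann$targetPathway), spec@nTargets)
    expect_true(all(lengths(forwardMap(ann$pathwayDisease)) >= 1L))
    expect_equal(length(ann$pathwayDisease), spec@nPathways)
    ## with every pathway diseased and every target human + annotated,
    ## all targets are eligible
    expect_equal(eligibleTargets(ann$targetMeta, ann$pathwayDisease),
                 sort(ann$targetMeta$target_id))
})

test_that("realized annotation multiplicities track the spec means", {
    spec <- simulationSpec(nPathways = 200L, nDiseases = 400L,
                           meanDiseasesPerPathway = 3, seed = 10)
    ann <- generateAnnotations(spec)
    sizes <- lengths(forwardMap(ann$pathwayDisease))
    ## 1-truncated Poisson(mean 3): sd = sqrt(2); 3 standard errors
    se <- sqrt(2) / sqrt(200)
    expect_lt(abs(mean(sizes) - 3), 3 * se)
})

test_that("ZHENG label draws match the stated proportions", {
    ## 117 labelled diseases at proportions (0.25, 0.80, 0.05): expected
    ## inclusive strata near 28 cold / 94 hot / 6 dual
    spec <- simulationSpec(nDiseases = 130L, zhengFraction = 0.9,
                           zhengProportions = c(cold = 0.25, hot = 0.80,
                                                both = 0.05),
                           seed = 8)
    ann <- generateAnnotations(spec)
    expect_equal(length(ann$zheng), 117L)
    res <- classifyZheng(ann$zheng)
    n <- 117
    tol <- function(p) 3 * sqrt(n * p * (1 - p))
    expect_lt(abs(res$summary[["cold"]] - 0.25 * n), tol(0.25))
    expect_lt(abs(res$summary[["hot"]] - 0.80 * n), tol(0.80))
    expect_lt(abs(res$summary[["both"]] - 0.05 * n), tol(0.05))
    expect_equal(res$summary[["total"]], 117L)

    ## all-cold proportions leave hotOnly empty
    allCold <- simulationSpec(nDiseases = 40L, zhengFraction = 1,
                              zhengProportions = c(cold = 1, hot = 0,
                                                   both = 0),
                              seed = 9)
    expect_length(classifyZheng(generateAnnotations(allCold)$zheng)$hotOnly,
                  0L)
})

test_that("profile generator emits valid permutations with planted roles", {
    spec <- tinySpec(seed = 12)
    sig <- generateSignature(spec)
    prof <- generateProfiles(spec, sig)
    rk <- rankingMatrix(prof)
    expect_equal(ncol(rk), spec@nPerturbagens * spec@nInstances)
    for (j in seq_len(ncol(rk)))
        expect_equal(sort(rk[, j]), seq_len(spec@nTags), ignore_attr = TRUE)

    ## near-deterministic mimic strength: mimic attains the batch maximum
    strong <- tinySpec(seed = 12, mimicStrength = 100)
    sigS <- generateSignature(strong)
    profS <- generateProfiles(strong, sigS)
    sc <- instanceScores(sigS, profS)
    expect_true(any(sc$scaled[sc$perturbagen == "mimic"] == 1))

    ## determinism under the spec seed
    expect_identical(rankingMatrix(generateProfiles(spec, sig)), rk)
})
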