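test_that("viability selection reduces to the lethal closed form", {
    for (p in c(0, 0.01, 0.1, 0.5, 0.9, 1))
        expect_equal(postSelectionFreq(p, c(0, 1, 1)), p / (1 + p))
    ## neutral fitness is the identity; p -> 1 approaches 0.5 under lethality
    ps <- seq(0, 1, by = 0.05)
    expect_equal(postSelectionFreq(ps, c(1, 1, 1)), ps)
    expect_equal(postSelectionFreq(1, c(0, 1, 1)), 0.5)
    ## general update on an asymmetric fitness scheme, checked by hand
    p <- 0.3; w <- c(0.2, 0.8, 1)
    wbar <- p^2 * 0.2 + 2 * p * 0.7 * 0.8 + 0.7^2
    expect_equal(postSelectionFreq(p, w), (p^2 * 0.2 + p * 0.7 * 0.8) / wbar)
    expect_error(postSelectionFreq(1, c(0, 0.5, 1)), "mean fitness")
})

test_that("the Wright-Fisher step is absorbing at 0 and unbiased when neutral", {
    cfg <- driftConfig(p0 = 0.5, fitness = c(1, 1, 1), seed = 1L)
    set.seed(91)
    expect_true(all(wfStep(rep(0, 1000L), cfg) == 0))
    draws <- wfStep(rep(0.3, 1e5), cfg)
    se <- sqrt(0.3 * 0.7 / cfg@twoN / 1e5)
    expect_lt(abs(mean(draws) - 0.3), 3 * se)
    ## lethal at p = 0.5: expectation 1/3
    cfgL <- driftConfig(p0 = 0.5, seed = 1L)
    drawsL <- wfStep(rep(0.5, 1e5), cfgL)
    seL <- sqrt(var(drawsL) / 1e5)
    expect_lt(abs(mean(drawsL) - 1 / 3), 3 * seL)
})

test_that("a recessive lethal can never fix", {
    res <- simulateTrajectories(driftConfig(p0 = 0.2, generations = 40L,
                                            replicates = 500L, seed = 92L))
    expect_true(all(driftSummaries(res)$fixed == 0))
    expect_true(all(trajectories(res) < 1))
})

test_that("neutral trajectories form a martingale with the textbook variance", {
    cfg <- driftConfig(p0 = 0.067, fitness = c(1, 1, 1), generations = 10L,
                       replicates = 4000L, seed = 93L)
    res <- simulateTrajectories(cfg)
    tr <- trajectories(res)
    p0 <- 0.067; twoN <- 300
    for (t in c(5L, 10L)) {
        se <- sd(tr[, t + 1L]) / sqrt(nrow(tr))
        expect_lt(abs(mean(tr[, t + 1L]) - p0), 3 * se)
        vExp <- p0 * (1 - p0) * (1 - (1 - 1 / twoN)^t)
        expect_lt(abs(var(tr[, t + 1L]) - vExp) / vExp, 0.15)
    }
})

test_that("drift results are bit-identical under a fixed seed", {
    cfg <- driftConfig(p0 = 0.1, generations = 15L, replicates = 200L,
                       seed = 94L)
    expect_identical(trajectories(simulateTrajectories(cfg)),
                     trajectories(simulateTrajectories(cfg)))
})

test_that("de novo persistence starts at 1 and decays with the horizon", {
    cfg <- driftConfig(p0 = 1 / 4100, generations = 25L,
                       replicates = 5000L, seed = 95L)
    expect_equal(as.numeric(deNovoPersistence(cfg, horizon = 0L)), 1)
    p10 <- deNovoPersistence(cfg, horizon = 10L)
    p25 <- deNovoPersistence(cfg, horizon = 25L)
    expect_lt(as.numeric(p25), as.numeric(p10))
})

test_that("purging is negligible at de novo frequencies", {
    ## neutral and lethal persistence are statistically indistinguishable
    ## when the allele is this rare
    reps <- 20000L
    pL <- deNovoPersistence(driftConfig(p0 = 1 / 4100, generations = 10L,
                                        replicates = reps, seed = 96L))
    pN <- deNovoPersistence(driftConfig(p0 = 1 / 4100, generations = 10L,
                                        fitness = c(1, 1, 1),
                                        replicates = reps, seed = 97L))
    test <- prop.test(c(as.numeric(pL), as.numeric(pN)) * reps,
                      c(reps, reps))
    expect_gt(test$p.value, 0.01)
})

test_that("de novo mutation arithmetic matches direct multiplication", {
    expect_identical(deNovoCount(0, 1e-8, 10)$perIndividual, 0)
    expect_identical(deNovoCount(3e9, 1e-8, 100),
                     list(perIndividual = 30, perGeneration = 3000))
})

test_that("equilibrium lethal load grows with the mutation rate", {
    base <- driftConfig(p0 = 0.5, generations = 60L, seed = 98L)
    counts <- vapply(c(0.005, 0.015, 0.03), function(u)
        equilibriumSegregating(u, base, burnin = 100L)$meanSegregating,
        numeric(1L))
    expect_identical(
        equilibriumSegregating(0, base, burnin = 10L)$meanSegregating, 0)
    expect_true(all(diff(counts) > 0))
})
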