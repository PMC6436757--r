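test_that("the Welch t-test matches a hand computation", {
    a <- c(1, 2, 3); b <- c(4, 5, 6)
    res <- welchT(a, b)
    se <- sqrt(var(a) / 3 + var(b) / 3)
    tHand <- (mean(a) - mean(b)) / se
    dfHand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
    expect_equal(res$statistic, tHand)
    expect_equal(res$df, dfHand)
    expect_equal(res$p.value, 2 * pt(tHand, dfHand))
    ## identical groups: no signal
    same <- welchT(a, a)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    expect_error(welchT(c(1, 1), c(2, 2)), "degenerate")
    expect_error(welchT(1, c(1, 2)), "two values")
})

test_that("the CxC vs CxNC comparison has power at realistic sample sizes", {
    cfg <- simConfig(ovulationMean = 18, litterMean = 14, seed = 1L)
    set.seed(111)
    hits <- vapply(seq_len(40L), function(r) {
        cc <- replicate(150, litterModel(1, 1, cfg)$TNB)
        nn <- replicate(600, litterModel(0, 0, cfg)$TNB)
        welchT(cc, nn)$p.value < 0.05
    }, logical(1L))
    expect_gte(mean(hits), 0.95)
})

test_that("litter-size reduction and affected-litter arithmetic are exact", {
    expect_equal(round(tnbReduction(7.33, 9.35), 3), 0.216)
    expect_equal(round(tnbReduction(11.51, 14.18), 3), 0.188)
    expect_equal(tnbReduction(5, 5), 0)
    expect_equal(affectedLitters(0.134), 0.017956)
    expect_equal(affectedLitters(0.084), 0.007056)
    expect_equal(affectedLitters(0), 0)
    expect_equal(pigletLoss(297, 11.51, 14.18), 792.99)
    expect_equal(pigletLoss(21, 7.33, 9.35), 42.42)
    expect_equal(pigletLoss(0, 3, 9), 0)
})

test_that("impact-table identities hold on every computed row", {
    tab <- impactTable(hap = c("H1", "H2"), nCxC = c(100L, 40L),
                       nCxNC = c(900L, 500L), tnbCxC = c(11.2, 12.1),
                       tnbCxNC = c(14.1, 14.3),
                       carrierFreq = c(0.12, 0.06), meanTnb = 14.2)
    expect_equal(tab$reduction, (tab$tnbCxNC - tab$tnbCxC) / tab$tnbCxNC)
    expect_equal(tab$pctDeath, tab$affected * tab$reduction)
    expect_equal(tab$populationReduction, 14.2 * tab$pctDeath)
    tot <- populationImpact(tab)
    expect_equal(tot$totalPctDeath, sum(tab$pctDeath))
    expect_equal(populationImpact(tab[0, ])$totalPctDeath, 0)
    ## explicit affected-litter override replaces the squared frequency
    tab2 <- impactTable(hap = "H1", nCxC = 10L, nCxNC = 90L,
                        tnbCxC = 11, tnbCxNC = 14, carrierFreq = 0.1,
                        meanTnb = 14, affected = 0.02)
    expect_equal(tab2$affected, 0.02)
})

test_that("genotype ratio test agrees with the chi-square survival function", {
    res <- genotypeRatioTest(3, 10, 0)
    expect_equal(round(res$p.chisq, 3), 0.076)
    oracle <- suppressWarnings(
        chisq.test(c(3, 10, 0), p = c(0.25, 0.5, 0.25)))
    expect_equal(res$chisq, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$p.chisq, oracle$p.value, tolerance = 1e-12)
    expect_lt(genotypeRatioTest(14, 24, 0)$p.chisq, 0.005)
    perfect <- genotypeRatioTest(25, 50, 25)
    expect_equal(perfect$chisq, 0)
    expect_equal(perfect$p.chisq, 1)
    ## the binomial companion is the lower tail under p = 0.25
    expect_equal(genotypeRatioTest(3, 10, 0)$p.binom.hom, 0.75^13)
})

test_that("heterosis attribution behaves like a bounded ratio", {
    expect_equal(heterosisAttribution(14.18, 14.38, 0.0739),
                 0.0739 / 0.2, tolerance = 1e-6)
    expect_equal(heterosisAttribution(14.18, 14.38, 0), 0)
    a <- heterosisAttribution(14, 14.4, 0.1)
    b <- heterosisAttribution(14, 14.4, 0.2)
    expect_lt(a, b)
    expect_warning(hi <- heterosisAttribution(14, 14.1, 0.5), "clipped")
    expect_equal(hi, 1)
    expect_error(heterosisAttribution(14, 14, 0.1), "exceed")
})

test_that("population burden follows the Hardy-Weinberg approximations", {
    b <- populationBurden(20, 0.02)
    expect_equal(b$carriedPerIndividual, 0.8)
    expect_equal(b$embryoDeathFraction, 0.008)
    expect_equal(populationBurden(0, 0.3)$carriedPerIndividual, 0)
    expect_equal(populationBurden(2, 0.1)$embryoDeathFraction, 0.02)
})

test_that("reduction estimated from simulated litters converges to 25%", {
    cfg <- simConfig(ovulationMean = 16, uterineCapacity = Inf,
                     litterMean = 12, seed = 1L)
    set.seed(112)
    cc <- replicate(8000, litterModel(1, 1, cfg)$TNB)
    nn <- replicate(8000, litterModel(0, 0, cfg)$TNB)
    red <- tnbReduction(mean(cc), mean(nn))
    expect_lt(abs(red - 0.25), 0.02)
    ## population-level death fraction approaches affected x 0.25
    aff <- affectedLitters(0.134)
    expect_lt(abs(aff * red - aff * 0.25), 0.001)
})

test_that("carrier-frequency time series tracks the live population", {
    ped <- data.frame(id = c("a", "b", "c", "d"),
                      birthdate = as.Date(c("2012-01-01", "2012-01-01",
                                            "2013-01-01", "2013-01-01")))
    status <- c(a = TRUE, b = FALSE, c = TRUE, d = TRUE)
    ts <- carrierFrequencyTimeseries(ped, status)
    expect_equal(ts$carrierFreq[1L], 0.5)
    expect_equal(ts$carrierFreq[nrow(ts)], 0.75)
    ## constant carrier set, no turnover: constant series
    ped2 <- ped[1:2, ]
    ts2 <- carrierFrequencyTimeseries(ped2, status)
    expect_true(all(ts2$carrierFreq == 0.5))
    ## all carriers
    ts3 <- carrierFrequencyTimeseries(ped, setNames(rep(TRUE, 4),
                                                    ped$id))
    expect_true(all(ts3$carrierFreq == 1))
})

test_that("the time series agrees with the generation-wise carrier counts", {
    cfg <- tinyConfig(seed = 31L, nGenerations = 3L)
    f <- simulateFounders(cfg)
    pl <- plantLethal(f, cfg)
    set.seed(31)
    sim <- simulateGenerations(pl$genotypes, cfg)
    g <- sim$genotypes
    status <- setNames(g$lethal1 + g$lethal2 >= 1L, animalIds(g))
    byGen <- tapply(status, g$generation, mean)
    ## one generation is born every 182 days; with a matching lifespan each
    ## bin holds exactly one generation cohort
    ts <- carrierFrequencyTimeseries(sim$pedigree, status,
                                     binDays = 182L, lifespanDays = 182)
    expect_equal(unname(ts$carrierFreq), unname(as.vector(byGen)),
                 tolerance = 1e-12)
})
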