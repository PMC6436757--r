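test_that("without recombination every gamete copies one parental haploid", {
    cfg <- tinyConfig(recombRate = 0)
    f <- simulateFounders(cfg)
    pl <- plantLethal(f, cfg)
    set.seed(2)
    sim <- simulateGenerations(pl$genotypes, cfg)
    g <- sim$genotypes
    ped <- sim$pedigree
    kids <- ped[!is.na(ped$sire), ]
    h1 <- hapAlleles(g, 1L); h2 <- hapAlleles(g, 2L)
    for (i in seq_len(nrow(kids))) {
        kid <- kids$id[i]
        sireCols <- cbind(h1[, kids$sire[i]], h2[, kids$sire[i]])
        damCols <- cbind(h1[, kids$dam[i]], h2[, kids$dam[i]])
        ## haploid 1 comes from the sire, haploid 2 from the dam
        expect_true(any(colSums(sireCols == h1[, kid]) == nrow(h1)))
        expect_true(any(colSums(damCols == h2[, kid]) == nrow(h1)))
    }
})

test_that("no surviving animal is ever a lethal homozygote", {
    cfg <- tinyConfig(seed = 6L)
    f <- simulateFounders(cfg)
    pl <- plantLethal(f, cfg)
    set.seed(6)
    sim <- simulateGenerations(pl$genotypes, cfg)
    g <- sim$genotypes
    expect_identical(sum(g$lethal1 + g$lethal2 == 2L), 0L)
})

test_that("the pedigree is complete, acyclic and time-consistent", {
    cfg <- tinyConfig(seed = 8L)
    f <- simulateFounders(cfg)
    set.seed(8)
    sim <- simulateGenerations(f, cfg)
    expect_true(validatePedigree(sim$pedigree))
    expect_identical(sort(sim$pedigree$id), sort(animalIds(sim$genotypes)))
})

test_that("meiosis conserves marker allele frequencies", {
    cfg <- simConfig(nBoars = 10L, nSows = 90L, nGenerations = 1L,
                     nMarkers = 150L, chromLengthBp = 1e7,
                     lethalPositionBp = 5e6, targetCarrierFreq = 0,
                     ovulationMean = 12, litterMean = 10, seed = 12L)
    f <- simulateFounders(cfg)
    set.seed(12)
    sim <- simulateGenerations(f, cfg)
    g <- sim$genotypes
    founderIdx <- g$generation == 0L
    kidIdx <- g$generation == 1L
    pf <- rowMeans(genotypeDosage(g)[, founderIdx]) / 2
    pk <- rowMeans(genotypeDosage(g)[, kidIdx]) / 2
    nHap <- 2 * sum(kidIdx)
    se <- sqrt(pmax(pf * (1 - pf), 1e-6) / nHap)
    ## transmitted frequencies stay within 3 binomial SE of the parental
    ## frequencies at (nearly) every marker; sampling of breeding parents
    ## adds extra variance, so allow a small fraction of excursions
    expect_gte(mean(abs(pk - pf) <= 3 * se), 0.9)
})

test_that("generation simulation is reproducible under a fixed seed", {
    cfg <- tinyConfig(seed = 14L)
    run <- function() {
        f <- simulateFounders(cfg)
        pl <- plantLethal(f, cfg)
        set.seed(99)
        simulateGenerations(pl$genotypes, cfg)
    }
    a <- run(); b <- run()
    expect_identical(hapAlleles(a$genotypes, 1L), hapAlleles(b$genotypes, 1L))
    expect_identical(a$litters$TNB, b$litters$TNB)
    expect_identical(a$pedigree, b$pedigree)
})

test_that("carrier frequency drifts without trend beyond lethal selection", {
    ## over short horizons the carrier frequency should change only
    ## modestly per generation (drift plus the weak selection against a
    ## rare recessive)
    set.seed(31)
    change <- replicate(15, {
        cfg <- tinyConfig(seed = sample.int(1e6, 1L), nGenerations = 2L)
        f <- simulateFounders(cfg)
        pl <- plantLethal(f, cfg)
        sim <- simulateGenerations(pl$genotypes, cfg)
        g <- sim$genotypes
        freq <- tapply(g$lethal1 + g$lethal2 >= 1L, g$generation, mean)
        (freq[length(freq)] - freq[1L]) / (length(freq) - 1L)
    })
    expect_lt(abs(median(change)), 0.1)
})
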