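test_that("Hardy-Weinberg expected homozygotes reproduce the algebraic identity", {
    set.seed(61)
    for (i in 1:20) {
        N <- sample(100:30000, 1L)
        C <- sample(0:floor(N / 2), 1L)
        expect_equal(expectedHomozygotesFreq(C, N), N * (C / (2 * N))^2)
    }
    expect_equal(expectedHomozygotesFreq(0, 500), 0)
    ## homozygous carriers add two haplotype copies each
    expect_equal(expectedHomozygotesFreq(10, 100, nHom = 5),
                 100 * (20 / 200)^2)
})

test_that("trio-based expectation counts 0.25 per carrier-x-carrier offspring", {
    ped <- data.frame(
        id = c("s1", "d1", "s2", "d2", paste0("o", 1:6)),
        sire = c(NA, NA, NA, NA, "s1", "s1", "s1", "s2", "s2", "unknownS"),
        dam = c(NA, NA, NA, NA, "d1", "d1", "d2", "d2", "d2", "d1"),
        stringsAsFactors = FALSE)
    ped$sire[ped$sire == "unknownS"] <- NA
    status <- c(s1 = TRUE, d1 = TRUE, s2 = FALSE, d2 = TRUE)
    e <- expectedHomozygotesTrio(ped, status, paste0("o", 1:6))
    ## o1-o3 are CxC (0.25 each); o4-o5 have the non-carrier sire s2;
    ## o6 lacks a sire record
    expect_equal(as.numeric(e), 0.75)
    expect_identical(attr(e, "nCxC"), 3L)
    expect_identical(attr(e, "nExcluded"), 1L)

    ## extended mode: unknown parents transmit at the haplotype frequency
    status2 <- c(s1 = TRUE, d1 = TRUE)
    e2 <- expectedHomozygotesTrio(ped, status2, c("o1", "o4"),
                                  mode = "extended", hapFreq = 0.1)
    ## o1 CxC = 0.25; o4: s2 and d2 unknown -> 0.1 * 0.1
    expect_equal(as.numeric(e2), 0.25 + 0.01)
})

test_that("the deficit test matches its closed form and a brute-force sum", {
    expect_equal(deficitTest(0, 38, 0.25), 0.75^38)
    expect_equal(deficitTest(5, 5, 0.25), 1)
    brute <- sum(choose(20, 0:2) * 0.25^(0:2) * 0.75^(20 - 0:2))
    expect_equal(deficitTest(2, 20, 0.25), brute, tolerance = 1e-12)
    ## (1 - p)^n closed form for zero observed
    set.seed(62)
    for (i in 1:10) {
        n <- sample(10:5000, 1L); p <- runif(1, 0, 0.3)
        expect_equal(deficitTest(0, n, p), (1 - p)^n)
    }
})

test_that("deficit p-value strictly decreases with carrier count at O = 0", {
    N <- 10000L
    ps <- vapply(seq(100L, 2000L, by = 100L), function(C)
        deficitTest(0, N, (C / (2 * N))^2), numeric(1L))
    expect_true(all(diff(ps) < 0))
})

test_that("window haplotype enumeration matches hand counting", {
    ## two animals with haplotypes A/B and A/A over two markers
    A <- c(0L, 1L); B <- c(1L, 0L)
    g <- handGenotypes(cbind(A, A), cbind(B, A), c(1e5, 2e5))
    tab <- enumerateWindowHaplotypes(g, "1", 1, 3e5)
    tab <- tab[order(-tab$count), ]
    expect_identical(tab$count, c(3L, 1L))
    expect_identical(tab$nHom, c(1L, 0L))
    expect_identical(attr(tab, "nGenotyped"), 2L)
    expect_identical(tab$carriers[[1L]], c("a01", "a02"))
})

test_that("windows with missing calls or too few markers degrade gracefully", {
    h <- matrix(NA_integer_, 2L, 3L)
    g <- handGenotypes(h, h, c(1e5, 2e5))
    tab <- enumerateWindowHaplotypes(g, "1", 1, 3e5)
    expect_identical(nrow(tab), 0L)
    expect_warning(enumerateWindowHaplotypes(g, "1", 1, 1.5e5), "fewer than 2")
})

test_that("the scan recovers a planted lethal haplotype", {
    pl <- plantedPopulation()
    g <- pl$genotypes
    cands <- scanHaplotypes(g, windows = scanWindowsSmall())
    pos <- pl$config@lethalPositionBp
    atLocus <- Filter(function(cd) cd@startBp <= pos && cd@endBp >= pos,
                      cands)
    expect_length(atLocus, 1L)
    cd <- atLocus[[1L]]
    expect_identical(cd@nHomObs, 0L)
    expect_lt(cd@pDeficit, 5e-3)
    planted <- animalIds(g)[g$lethal1 + g$lethal2 >= 1L]
    expect_identical(cd@carrierIds, sort(planted))
    expect_gt(attr(cands, "nTests"), 0L)
})

test_that("the scan is invariant to animal ordering", {
    pl <- plantedPopulation()
    g <- pl$genotypes
    set.seed(63)
    perm <- sample(nAnimals(g))
    gp <- g[, perm]
    a <- scanHaplotypes(g, windows = scanWindowsSmall())
    b <- scanHaplotypes(gp, windows = scanWindowsSmall())
    expect_identical(length(a), length(b))
    spanOf <- function(x) vapply(x, function(cd)
        sprintf("%s:%d-%d", cd@chrom, as.integer(cd@startBp),
                as.integer(cd@endBp)), character(1L))
    expect_setequal(spanOf(a), spanOf(b))
    expect_identical(a[[1L]]@carrierIds, b[[1L]]@carrierIds)
})

test_that("an undetectably rare lethal yields no candidate at its locus", {
    cfg <- simConfig(nBoars = 10L, nSows = 990L, nMarkers = 200L,
                     chromLengthBp = 1e7, lethalPositionBp = 5e6,
                     targetCarrierFreq = 0.02, hostWindowBp = 1e6,
                     seed = 64L)
    f <- simulateFounders(cfg)
    pl <- plantLethal(f, cfg)
    cands <- scanHaplotypes(pl$genotypes, windows = scanWindowsSmall())
    atLocus <- Filter(function(cd) cd@startBp <= 5e6 && cd@endBp >= 5e6,
                      cands)
    expect_length(atLocus, 0L)
})

test_that("unphased genotypes are refused", {
    g <- simulateFounders(tinyConfig())
    metadata(g)$phased <- FALSE
    expect_error(scanHaplotypes(g), "phased")
})

test_that("detection power rises with carrier frequency and cohort size", {
    grid <- expand.grid(freq = c(0.04, 0.1, 0.25), N = c(300L, 2000L))
    set.seed(65)
    rate <- mapply(function(freq, N) {
        hitsFound <- vapply(seq_len(8L), function(r) {
            cfg <- simConfig(nBoars = 10L, nSows = N - 10L, nMarkers = 160L,
                             chromLengthBp = 8e6, lethalPositionBp = 4e6,
                             targetCarrierFreq = freq, hostWindowBp = 1e6,
                             seed = sample.int(1e6, 1L))
            f <- simulateFounders(cfg)
            pl <- plantLethal(f, cfg)
            cands <- scanHaplotypes(pl$genotypes,
                                    windows = scanWindowsSmall())
            any(vapply(cands, function(cd)
                cd@startBp <= 4e6 && cd@endBp >= 4e6, logical(1L)))
        }, logical(1L))
        mean(hitsFound)
    }, grid$freq, grid$N)
    ## power increases along the frequency axis at both cohort sizes and
    ## along the cohort axis at the highest frequency
    expect_lte(rate[1L], rate[3L])
    expect_lte(rate[4L], rate[6L])
    expect_lte(rate[3L], rate[6L] + 0.15)
    expect_identical(rate[6L], 1)   # 25% carriers in 2000 animals: certain
})

test_that("false-positive candidates stay near the nominal test level", {
    set.seed(66)
    nCands <- vapply(seq_len(8L), function(r) {
        cfg <- simConfig(nBoars = 10L, nSows = 590L, nMarkers = 120L,
                         chromLengthBp = 6e6, lethalPositionBp = 3e6,
                         targetCarrierFreq = 0, seed = sample.int(1e6, 1L))
        g <- simulateFounders(cfg)
        cands <- scanHaplotypes(g, windows = scanWindowsSmall())
        length(cands) / max(attr(cands, "nTests"), 1L)
    }, numeric(1L))
    expect_lte(mean(nCands), 5e-3)
})
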