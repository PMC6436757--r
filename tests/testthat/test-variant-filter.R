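plantedScan <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            pl <- plantedPopulation()
            cands <- scanHaplotypes(pl$genotypes,
                                    windows = scanWindowsSmall())
            pos <- pl$config@lethalPositionBp
            cd <- Filter(function(x) x@startBp <= pos && x@endBp >= pos,
                         cands)[[1L]]
            set.seed(85)
            panel <- simulateVariantPanel(pl$genotypes, nVariants = 30L)
            cache <<- list(pl = pl, candidate = cd, panel = panel)
        }
        cache
    }
})

test_that("the planted causal variant is ranked first with r-squared 1", {
    fx <- plantedScan()
    out <- candidateVariants(fx$panel, fx$candidate, fx$pl$genotypes)
    expect_gt(nrow(out), 0L)
    causalName <- names(rowRanges(fx$panel))[
        which(mcols(rowRanges(fx$panel))$causal)]
    expect_identical(out$variant[1L], causalName)
    expect_equal(out$r2[1L], 1, tolerance = 1e-12)
    expect_identical(out$rankGroup[1L], 1L)
    expect_false(attr(out, "noHighImpact"))
})

test_that("relaxing the r2 threshold never removes a passing variant", {
    fx <- plantedScan()
    strict <- candidateVariants(fx$panel, fx$candidate, fx$pl$genotypes,
                                filterCriteria(r2Min = 0.8))
    relaxed <- candidateVariants(fx$panel, fx$candidate, fx$pl$genotypes,
                                 filterCriteria(r2Min = 0.7))
    expect_true(all(strict$variant %in% relaxed$variant))
    ## and filtering twice changes nothing (idempotence over the panel)
    again <- candidateVariants(fx$panel, fx$candidate, fx$pl$genotypes,
                               filterCriteria(r2Min = 0.8))
    expect_identical(strict, again)
})

test_that("variants outside the 5 Mb flank are excluded even in perfect LD", {
    fx <- plantedScan()
    g <- fx$pl$genotypes
    cd <- fx$candidate
    host <- as.integer(g$lethal1 + g$lethal2)
    farPos <- cd@endBp + 6e6
    gr <- GRanges(cd@chrom, IRanges(c(round(mean(c(cd@startBp, cd@endBp))),
                                      farPos), width = 1L))
    mcols(gr)$ref <- c("G", "G"); mcols(gr)$alt <- c("A", "A")
    mcols(gr)$class <- c("stop_gained", "stop_gained")
    mcols(gr)$deleterious <- c(TRUE, TRUE)
    panel <- VariantPanel(rbind(host, host), gr,
                          animalIds = animalIds(g))
    out <- candidateVariants(panel, cd, g)
    expect_identical(nrow(out), 1L)
    expect_equal(out$pos, start(gr)[1L])
})

test_that("a lone tolerated missense passes but is flagged non-high-impact", {
    fx <- plantedScan()
    g <- fx$pl$genotypes
    cd <- fx$candidate
    host <- as.integer(g$lethal1 + g$lethal2)
    gr <- GRanges(cd@chrom,
                  IRanges(round(mean(c(cd@startBp, cd@endBp))), width = 1L))
    mcols(gr)$ref <- "A"; mcols(gr)$alt <- "C"
    mcols(gr)$class <- "missense"; mcols(gr)$deleterious <- FALSE
    panel <- VariantPanel(matrix(host, nrow = 1L), gr,
                          animalIds = animalIds(g))
    out <- candidateVariants(panel, cd, g)
    expect_identical(nrow(out), 1L)
    expect_identical(out$rankGroup[1L], 3L)
    expect_true(attr(out, "noHighImpact"))
})

test_that("variants with too many homozygotes or discordant animals fail", {
    fx <- plantedScan()
    g <- fx$pl$genotypes
    cd <- fx$candidate
    host <- as.integer(g$lethal1 + g$lethal2)
    posMid <- round(mean(c(cd@startBp, cd@endBp)))
    mkPanel <- function(d) {
        gr <- GRanges(cd@chrom, IRanges(posMid, width = 1L))
        mcols(gr)$ref <- "G"; mcols(gr)$alt <- "T"
        mcols(gr)$class <- "frameshift"; mcols(gr)$deleterious <- TRUE
        VariantPanel(matrix(d, nrow = 1L), animalIds = animalIds(g),
                     variants = gr)
    }
    ## two homozygous-alternate animals exceed the tolerance of one
    dHom <- host; dHom[which(host == 0L)[1:2]] <- 2L
    expect_identical(nrow(candidateVariants(mkPanel(dHom), cd, g)), 0L)
    ## two carriers without the variant exceed the discordance tolerance
    dDisc <- host; dDisc[which(host == 1L)[1:2]] <- 0L
    expect_identical(nrow(candidateVariants(mkPanel(dDisc), cd, g)), 0L)
    ## exactly one discordant animal is tolerated
    dOne <- host; dOne[which(host == 1L)[1L]] <- 0L
    expect_identical(nrow(candidateVariants(mkPanel(dOne), cd, g)), 1L)
})
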