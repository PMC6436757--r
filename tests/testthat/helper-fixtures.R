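## Shared fixture builders. Everything is generated in code; sizes are kept
## small so the default run stays fast.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

tinyConfig <- function(seed = 1L, ...) {
    args <- list(nBoars = 5L, nSows = 45L, nGenerations = 2L,
                 nMarkers = 120L, chromLengthBp = 1e7,
                 lethalPositionBp = 5e6, targetCarrierFreq = 0.2,
                 hostWindowBp = 1e6, ovulationMean = 12, litterMean = 8,
                 seed = seed)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

## a mid-sized planted population, cached per session because several test
## files scan it
plantedPopulation <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simConfig(nBoars = 20L, nSows = 1480L, nMarkers = 300L,
                             chromLengthBp = 1.5e7, lethalPositionBp = 7.5e6,
                             targetCarrierFreq = 0.2, hostWindowBp = 1.5e6,
                             seed = 101L)
            f <- simulateFounders(cfg)
            cache <<- c(plantLethal(f, cfg), list(config = cfg))
        }
        cache
    }
})

## hand-built phased genotypes: alleles given as a markers x animals list of
## two matrices, positions in bp
handGenotypes <- function(h1, h2, positions, chrom = "1",
                          ids = sprintf("a%02d", seq_len(ncol(h1)))) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(positions, width = 1L))
    PhasedGenotypes(h1, h2, gr, ids)
}

scanWindowsSmall <- function() windowSpec(sizesBp = c(0.5, 1) * 1e6)
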