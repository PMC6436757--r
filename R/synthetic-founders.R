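#' Simulate founder genotypes for a two-tier breeding population
#'
#' Draws `nBoars + nSows` founder animals with independent phased haploid
#' allele calls at each marker. Per-marker alternate-allele frequencies are
#' uniform in `[mafLow, mafHigh]`; marker positions are sampled uniformly
#' (without replacement) along the chromosome and sorted. Founders carry no
#' lethal allele; use [plantLethal()] to introduce one.
#'
#' @param config a [SimConfig-class] object; `config@seed` seeds the RNG.
#' @param chrom chromosome name for the marker map.
#' @return a [PhasedGenotypes-class] object with per-animal `sex`,
#'   `generation` and lethal haploid indicators in `colData`.
#' @examples
#' g <- simulateFounders(simConfig(nBoars = 3, nSows = 12, nMarkers = 50,
#'                                 seed = 42))
#' nAnimals(g)
#' @export
simulateFounders <- function(config, chrom = "1") {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nBoars + config@nSows
    m <- config@nMarkers
    pos <- sort(sample.int(config@chromLengthBp, m))
    freq <- runif(m, config@mafLow, config@mafHigh)
    ## rbinom prob recycles per element; freq aligns with rows (markers)
    hap1 <- matrix(rbinom(m * n, 1L, freq), nrow = m)
    hap2 <- matrix(rbinom(m * n, 1L, freq), nrow = m)
    ids <- sprintf("F0_%05d", seq_len(n))
    sex <- rep(c("M", "F"), c(config@nBoars, config@nSows))
    markers <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(markers)$ref <- rep("A", m)
    mcols(markers)$alt <- rep("B", m)
    mcols(markers)$freq <- freq
    cd <- DataFrame(sex = sex, generation = 0L,
                    lethal1 = integer(n), lethal2 = integer(n))
    PhasedGenotypes(hap1, hap2, markers, ids, phased = TRUE, colData = cd)
}

#' Plant a recessive lethal allele on one founder haplotype
#'
#' Overwrites one haploid copy of the host window (markers within
#' `hostWindowBp` centred on `lethalPositionBp`) in a random subset of
#' animals with a single shared haplotype, and marks that haploid as
#' carrying the lethal allele. By construction every carrier is
#' heterozygous, no animal is homozygous for the host haplotype, and the
#' lethal allele is in complete LD (r-squared 1) with the host haplotype.
#' The realized carrier frequency is `round(targetCarrierFreq * N) / N`.
#'
#' @param genotypes founder [PhasedGenotypes-class].
#' @param config a [SimConfig-class]; uses `lethalPositionBp`,
#'   `targetCarrierFreq` and `hostWindowBp`.
#' @return list with elements `genotypes` (lethal planted, host haplotype
#'   recorded in `metadata(genotypes)$lethal`) and `lethal` (a one-variant
#'   [VariantPanel-class] holding the causal variant and its per-animal
#'   dosage), or the unchanged genotypes and `NULL` when
#'   `targetCarrierFreq` is zero.
#' @export
plantLethal <- function(genotypes, config) {
    stopifnot(is(genotypes, "PhasedGenotypes"), is(config, "SimConfig"))
    n <- nAnimals(genotypes)
    if (config@targetCarrierFreq == 0)
        return(list(genotypes = genotypes, lethal = NULL))
    pos <- start(rowRanges(genotypes))
    half <- config@hostWindowBp / 2
    idx <- which(pos >= config@lethalPositionBp - half &
                 pos <= config@lethalPositionBp + half)
    if (length(idx) < 2L)
        stop("host window contains fewer than 2 markers")
    nCarriers <- round(config@targetCarrierFreq * n)
    if (nCarriers < 1L)
        stop("target carrier frequency unreachable: fewer than one carrier")
    host <- rbinom(length(idx), 1L,
                   mcols(rowRanges(genotypes))$freq[idx] %||% 0.5)
    h1 <- assay(genotypes, "hap1"); h2 <- assay(genotypes, "hap2")
    carriers <- sample.int(n, nCarriers)
    side <- sample(c(1L, 2L), nCarriers, replace = TRUE)
    lethal1 <- genotypes$lethal1; lethal2 <- genotypes$lethal2
    for (k in seq_len(nCarriers)) {
        a <- carriers[k]
        if (side[k] == 1L) { h1[idx, a] <- host; lethal1[a] <- 1L }
        else               { h2[idx, a] <- host; lethal2[a] <- 1L }
    }
    ## a lethal homozygote can only arise by coincidence of the untouched
    ## haploid with the host vector; with tens of markers this is vanishing,
    ## but guarantee the invariant anyway
    hom <- which(colSums(h1[idx, , drop = FALSE] == host) == length(idx) &
                 colSums(h2[idx, , drop = FALSE] == host) == length(idx))
    for (a in hom) {
        flip <- idx[1L]
        if (lethal1[a] == 1L) h2[flip, a] <- 1L - h2[flip, a]
        else                  h1[flip, a] <- 1L - h1[flip, a]
    }
    out <- genotypes
    SummarizedExperiment::assay(out, "hap1") <- h1
    SummarizedExperiment::assay(out, "hap2") <- h2
    out$lethal1 <- lethal1
    out$lethal2 <- lethal2
    chrom <- as.character(seqnames(rowRanges(genotypes)))[idx[1L]]
    metadata(out)$lethal <- list(
        chrom = chrom, positionBp = config@lethalPositionBp,
        hostAlleles = host, hostIdx = idx,
        windowStartBp = pos[idx[1L]], windowEndBp = pos[idx[length(idx)]])
    gr <- GRanges(chrom, IRanges(config@lethalPositionBp, width = 1L))
    mcols(gr)$ref <- "G"; mcols(gr)$alt <- "A"
    mcols(gr)$class <- "splice_donor"
    mcols(gr)$deleterious <- TRUE
    mcols(gr)$causal <- TRUE
    dos <- matrix(lethal1 + lethal2, nrow = 1L)
    lethal <- VariantPanel(dos, gr, animalIds = animalIds(genotypes))
    list(genotypes = out, lethal = lethal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
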