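#' Simulate an annotated variant panel around a planted lethal
#'
#' Emits the causal variant (complete LD with the host haplotype, a
#' loss-of-function consequence class, zero homozygotes) plus background
#' variants whose LD to the host-haplotype dosage follows `ldProfile`.
#' Background allele states are generated at the haploid level: a variant
#' allele co-occurs with the host haplotype with a probability solved
#' numerically so that the squared dosage correlation hits the target.
#' Background positions are drawn half inside the 5 Mb flank around the
#' host window and half across the rest of the chromosome, with mixed
#' consequence classes dominated by non-coding and synonymous variants.
#'
#' @param genotypes [PhasedGenotypes-class] carrying a planted lethal
#'   (`metadata(genotypes)$lethal` set by [plantLethal()]).
#' @param nVariants number of background variants.
#' @param ldProfile target r-squared values, recycled across background
#'   variants (default a ladder from 0.05 to 0.9).
#' @param baselineFreq variant-allele frequency on non-host haploids.
#' @param classWeights named numeric vector of consequence-class sampling
#'   weights for background variants.
#' @return a [VariantPanel-class]; the causal variant carries
#'   `mcols()$causal == TRUE` and background variants record their target
#'   r-squared in `mcols()$targetR2`.
#' @export
simulateVariantPanel <- function(genotypes, nVariants = 50L,
                                 ldProfile = c(0.05, 0.1, 0.2, 0.3, 0.5,
                                               0.7, 0.8, 0.9),
                                 baselineFreq = 0.002,
                                 classWeights = c(intergenic = 0.5,
                                                  synonymous = 0.2,
                                                  missense = 0.2,
                                                  inframe_indel = 0.04,
                                                  frameshift = 0.02,
                                                  stop_gained = 0.02,
                                                  splice_acceptor = 0.01,
                                                  splice_donor = 0.01)) {
    info <- metadata(genotypes)$lethal
    if (is.null(info))
        stop("no planted lethal recorded in metadata(genotypes)$lethal")
    stopifnot(all(names(classWeights) %in% consequenceClasses()))
    n <- nAnimals(genotypes)
    c1 <- genotypes$lethal1; c2 <- genotypes$lethal2
    hostDosage <- c1 + c2
    pc <- mean(c(c1, c2))
    chromLen <- max(end(rowRanges(genotypes)))

    targets <- rep_len(ldProfile, nVariants)
    classes <- sample(names(classWeights), nVariants, replace = TRUE,
                      prob = classWeights)
    nearHalf <- seq_len(nVariants) %% 2L == 0L
    posNear <- round(runif(sum(nearHalf),
                           max(1, info$windowStartBp - 5e6),
                           min(chromLen, info$windowEndBp + 5e6)))
    posFar <- round(runif(sum(!nearHalf), 1, chromLen))
    pos <- integer(nVariants)
    pos[nearHalf] <- posNear; pos[!nearHalf] <- posFar

    dosage <- matrix(0L, nrow = nVariants + 1L, ncol = n)
    dosage[1L, ] <- as.integer(hostDosage)
    for (i in seq_len(nVariants)) {
        a <- .solveCooccurrence(targets[i], pc, baselineFreq)
        v1 <- rbinom(n, 1L, ifelse(c1 == 1L, a, baselineFreq))
        v2 <- rbinom(n, 1L, ifelse(c2 == 1L, a, baselineFreq))
        dosage[i + 1L, ] <- v1 + v2
    }

    gr <- GRanges(info$chrom,
                  IRanges(c(info$positionBp, pos), width = 1L))
    mcols(gr)$ref <- sample(c("A", "C", "G", "T"), nVariants + 1L,
                            replace = TRUE)
    mcols(gr)$alt <- sample(c("A", "C", "G", "T"), nVariants + 1L,
                            replace = TRUE)
    mcols(gr)$class <- c(sample(lofClasses(), 1L), classes)
    mcols(gr)$deleterious <- c(TRUE, classes == "missense" &
                                     rbinom(nVariants, 1L, 0.3) == 1L)
    mcols(gr)$causal <- c(TRUE, rep(FALSE, nVariants))
    mcols(gr)$targetR2 <- c(1, targets)
    VariantPanel(dosage, gr, animalIds = animalIds(genotypes))
}

#' Solve the haploid co-occurrence probability for a target dosage r-squared
#'
#' With host-haplotype frequency `pc` and variant baseline frequency `b` on
#' non-host haploids, the haploid-level correlation of the variant allele
#' with the host indicator is `(a - b) sqrt(pc (1 - pc)) / sqrt(pv (1 - pv))`
#' where `pv = pc a + (1 - pc) b`; for independent haploids the dosage
#' correlation equals the haploid correlation, so the target r-squared is
#' met by solving for `a` (the variant frequency on host haploids).
#' @keywords internal
.solveCooccurrence <- function(r2target, pc, b) {
    r2of <- function(a) {
        pv <- pc * a + (1 - pc) * b
        if (pv <= 0 || pv >= 1) return(0)
        ((a - b) * sqrt(pc * (1 - pc)) / sqrt(pv * (1 - pv)))^2
    }
    if (r2of(1) < r2target)
        stop("target r2 ", r2target, " unattainable at baseline frequency ", b)
    stats::uniroot(function(a) r2of(a) - r2target,
                   lower = b, upper = 1, tol = 1e-10)$root
}
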