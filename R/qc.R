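#' Marker and animal quality control
#'
#' Drops animals below the animal call-rate threshold first, then markers
#' failing minor-allele-frequency, call-rate or exact Hardy-Weinberg
#' criteria (computed on the retained animals). The HWE threshold is
#' deliberately liberal by default (1e-5): markers tagging a recessive
#' lethal haplotype show a mild heterozygote excess and must survive
#' filtering; a strict threshold (e.g. 1e-30) is available as a
#' sensitivity re-scan mode.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param thresholds a [QCThresholds-class] object.
#' @return list with `genotypes` (filtered) and `report` (counts and
#'   identifiers removed per criterion).
#' @export
qcFilter <- function(genotypes, thresholds = qcThresholds()) {
    stopifnot(is(genotypes, "PhasedGenotypes"), is(thresholds, "QCThresholds"))
    if (nMarkers(genotypes) == 0L || nAnimals(genotypes) == 0L)
        stop("empty genotype set")
    h1 <- assay(genotypes, "hap1"); h2 <- assay(genotypes, "hap2")
    miss <- is.na(h1)

    animalCallrate <- 1 - colMeans(miss)
    dropAnimal <- animalCallrate < thresholds@animalCallrateMin
    keptA <- !dropAnimal
    h1 <- h1[, keptA, drop = FALSE]; h2 <- h2[, keptA, drop = FALSE]
    miss <- miss[, keptA, drop = FALSE]

    markerCallrate <- 1 - rowMeans(miss)
    dos <- h1 + h2
    nHomRef <- rowSums(dos == 0L, na.rm = TRUE)
    nHet <- rowSums(dos == 1L, na.rm = TRUE)
    nHomAlt <- rowSums(dos == 2L, na.rm = TRUE)
    nCalled <- nHomRef + nHet + nHomAlt
    altFreq <- ifelse(nCalled > 0, (2 * nHomAlt + nHet) / (2 * nCalled), 0)
    maf <- pmin(altFreq, 1 - altFreq)

    failCall <- markerCallrate < thresholds@markerCallrateMin
    failMAF <- !failCall & maf <= thresholds@mafMin
    hweP <- rep(1, nrow(h1))
    todo <- which(!failCall & !failMAF)
    for (i in todo)
        hweP[i] <- hweExactTest(nHomRef[i], nHet[i], nHomAlt[i])
    failHWE <- !failCall & !failMAF & hweP < thresholds@hweAlpha

    keepM <- !(failCall | failMAF | failHWE)
    if (!any(keepM))
        stop("all markers removed by quality control")
    out <- genotypes[keepM, keptA]
    report <- list(
        nAnimalsRemoved = sum(dropAnimal),
        animalsRemoved = animalIds(genotypes)[dropAnimal],
        nMarkersCallrate = sum(failCall),
        nMarkersMAF = sum(failMAF),
        nMarkersHWE = sum(failHWE),
        markersRemoved = rownames(genotypes)[!keepM],
        hweP = hweP)
    list(genotypes = out, report = report)
}
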