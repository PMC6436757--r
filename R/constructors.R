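#' Build a simulation configuration
#'
#' Defaults follow the population structure of a commercial pig nucleus
#' line: 50 boars and 2000 sows (census 2050), a single 50 Mb autosome at
#' 50K-chip marker density (20 markers/Mb) with the common-variant
#' ascertainment bias of array content (founder MAF uniform on 0.1-0.5),
#' crossover rate 1 cM/Mb, a
#' lethal planted mid-chromosome at the highest carrier frequency observed
#' for such alleles (13.4%), mean litter size 14.18 absent lethals, and
#' background stillbirth/mummification rates of 7% and 1% of total born.
#' `uterineCapacity = Inf` disables compensation, so carrier-by-carrier
#' litters lose the full Mendelian 25%; a finite capacity below
#' `ovulationMean` recreates the partial compensation seen in sows, where
#' ovulated embryos outnumber uterine places.
#'
#' @param nBoars,nSows founder males and females.
#' @param nGenerations generations simulated by [simulateGenerations()].
#' @param nMarkers markers on the chromosome.
#' @param chromLengthBp chromosome length (bp).
#' @param mafLow,mafHigh founder allele-frequency bounds.
#' @param recombRate expected crossovers per Mb per meiosis.
#' @param lethalPositionBp lethal coordinate (1-based bp).
#' @param targetCarrierFreq carrier fraction aimed for by [plantLethal()].
#' @param hostWindowBp width of the haplotype in complete LD with the lethal.
#' @param ovulationMean Poisson mean of ovulated zygotes per mating.
#' @param uterineCapacity maximum embryos carried to term (`Inf` = none).
#' @param litterMean expected total born for non-carrier matings.
#' @param nsbRate,mumRate background stillborn and mummified rates.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nBoars = 5, nSows = 50, nMarkers = 200, seed = 1)
#' @export
simConfig <- function(nBoars = 50L, nSows = 2000L, nGenerations = 5L,
                      nMarkers = 1000L, chromLengthBp = 5e7,
                      mafLow = 0.1, mafHigh = 0.5, recombRate = 0.01,
                      lethalPositionBp = 2.5e7, targetCarrierFreq = 0.134,
                      hostWindowBp = 2e6, ovulationMean = 20,
                      uterineCapacity = Inf, litterMean = 14.18,
                      nsbRate = 0.07, mumRate = 0.01, seed = 1L) {
    new("SimConfig",
        nBoars = as.integer(nBoars), nSows = as.integer(nSows),
        nGenerations = as.integer(nGenerations),
        nMarkers = as.integer(nMarkers), chromLengthBp = chromLengthBp,
        mafLow = mafLow, mafHigh = mafHigh, recombRate = recombRate,
        lethalPositionBp = lethalPositionBp,
        targetCarrierFreq = targetCarrierFreq, hostWindowBp = hostWindowBp,
        ovulationMean = ovulationMean, uterineCapacity = uterineCapacity,
        litterMean = litterMean, nsbRate = nsbRate, mumRate = mumRate,
        seed = as.integer(seed))
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simConfig()]; absent keys keep their
#' defaults. A `seed` key is required.
#'
#' @param path path to a YAML file.
#' @return a [SimConfig-class] object.
#' @export
readSimConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals$seed))
        stop("simulation config must set a seed")
    known <- names(formals(simConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(simConfig, vals)
}

#' Construct a PhasedGenotypes object
#'
#' @param hap1,hap2 integer matrices (markers x animals) of 0/1 allele
#'   calls with `NA` for missing; missing calls must hit both haploids.
#' @param markers `GRanges` of marker coordinates, optionally with `ref`
#'   and `alt` metadata columns (defaults A/B array alleles).
#' @param animalIds character vector of animal identifiers.
#' @param phased logical; `FALSE` marks haploid order as arbitrary.
#' @param colData optional `DataFrame` of per-animal annotation.
#' @return a [PhasedGenotypes-class] object.
#' @export
PhasedGenotypes <- function(hap1, hap2, markers, animalIds,
                            phased = TRUE, colData = NULL) {
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
    if (is.null(mcols(markers)$ref)) {
        mcols(markers)$ref <- rep("A", length(markers))
        mcols(markers)$alt <- rep("B", length(markers))
    }
    if (is.null(names(markers)))
        names(markers) <- paste0("m", seq_along(markers))
    if (is.null(colData))
        colData <- DataFrame(row.names = animalIds)
    else
        rownames(colData) <- animalIds
    dimnames(hap1) <- dimnames(hap2) <- list(names(markers), animalIds)
    se <- SummarizedExperiment(
        assays = list(hap1 = hap1, hap2 = hap2),
        rowRanges = markers, colData = colData)
    metadata(se)$phased <- phased
    new("PhasedGenotypes", se)
}

#' Construct a VariantPanel object
#'
#' @param dosage integer matrix (variants x animals) of alternate-allele
#'   dosages 0/1/2, `NA` missing.
#' @param variants `GRanges` with metadata columns `ref`, `alt`, `class`
#'   and optionally `deleterious`.
#' @param animalIds animal identifiers (defaults to `colnames(dosage)`).
#' @return a [VariantPanel-class] object.
#' @export
VariantPanel <- function(dosage, variants, animalIds = colnames(dosage)) {
    storage.mode(dosage) <- "integer"
    if (is.null(mcols(variants)$deleterious))
        mcols(variants)$deleterious <- rep(FALSE, length(variants))
    if (is.null(names(variants)))
        names(variants) <- paste0("var", seq_along(variants))
    dimnames(dosage) <- list(names(variants), animalIds)
    se <- SummarizedExperiment(assays = list(dosage = dosage),
                               rowRanges = variants)
    new("VariantPanel", se)
}

#' @rdname QCThresholds-class
#' @param mafMin,markerCallrateMin,animalCallrateMin,hweAlpha see slots.
#' @export
qcThresholds <- function(mafMin = 0.01, markerCallrateMin = 0.85,
                         animalCallrateMin = 0.7, hweAlpha = 1e-5) {
    new("QCThresholds", mafMin = mafMin,
        markerCallrateMin = markerCallrateMin,
        animalCallrateMin = animalCallrateMin, hweAlpha = hweAlpha)
}

#' @rdname WindowSpec-class
#' @param sizesBp,stepFraction,minHapFreq,alpha see slots.
#' @export
windowSpec <- function(sizesBp = c(0.5, 1, 2, 5) * 1e6, stepFraction = 0.5,
                       minHapFreq = 0.005, alpha = 5e-3) {
    new("WindowSpec", sizesBp = sizesBp, stepFraction = stepFraction,
        minHapFreq = minHapFreq, alpha = alpha)
}

#' @rdname FilterCriteria-class
#' @param flankBp,r2Min,maxHom,maxDiscordant,requireClass see slots.
#' @export
filterCriteria <- function(flankBp = 5e6, r2Min = 0.8, maxHom = 1L,
                           maxDiscordant = 1L, requireClass = character(0)) {
    new("FilterCriteria", flankBp = flankBp, r2Min = r2Min,
        maxHom = as.integer(maxHom), maxDiscordant = as.integer(maxDiscordant),
        requireClass = requireClass)
}

#' @rdname DriftConfig-class
#' @param p0,twoN,fitness,generations,replicates,seed see slots.
#' @export
driftConfig <- function(p0, twoN = 300L, fitness = c(0, 1, 1),
                        generations = 25L, replicates = 1000L, seed = 1L) {
    new("DriftConfig", p0 = p0, twoN = as.integer(twoN), fitness = fitness,
        generations = as.integer(generations),
        replicates = as.integer(replicates), seed = as.integer(seed))
}
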