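#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic breeding population
#'
#' `SimConfig` bundles every tunable of the synthetic two-tier breeding
#' population: a small number of boars mated to many sows, biallelic phased
#' markers on one autosome, a recessive lethal allele planted on a single
#' founder haplotype, and litters in which lethal homozygotes die before
#' implantation (optionally compensated by excess ovulation relative to
#' uterine capacity).
#'
#' @slot nBoars,nSows,nGenerations,nMarkers integer counts.
#' @slot chromLengthBp chromosome length in base pairs.
#' @slot mafLow,mafHigh founder minor-allele-frequency bounds; per-marker
#'   alternate-allele frequencies are drawn uniformly in this interval.
#' @slot recombRate expected crossovers per Mb per meiosis.
#' @slot lethalPositionBp coordinate (1-based bp) of the planted lethal.
#' @slot targetCarrierFreq fraction of animals carrying the lethal haplotype.
#' @slot hostWindowBp width of the founder haplotype placed in complete LD
#'   with the lethal allele.
#' @slot ovulationMean mean number of ovulated zygotes per mating (Poisson).
#' @slot uterineCapacity maximum embryos carried to term; `Inf` disables
#'   uterine-capacity compensation.
#' @slot litterMean expected total number born for non-carrier matings.
#' @slot nsbRate,mumRate background stillbirth and mummification rates,
#'   independent of lethal carrier status.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", slots = c(
    nBoars = "integer", nSows = "integer", nGenerations = "integer",
    nMarkers = "integer", chromLengthBp = "numeric",
    mafLow = "numeric", mafHigh = "numeric", recombRate = "numeric",
    lethalPositionBp = "numeric", targetCarrierFreq = "numeric",
    hostWindowBp = "numeric", ovulationMean = "numeric",
    uterineCapacity = "numeric", litterMean = "numeric",
    nsbRate = "numeric", mumRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@nBoars < 1L || object@nSows < 1L)
        msg <- c(msg, "nBoars and nSows must be positive")
    if (object@nMarkers < 1L)
        msg <- c(msg, "nMarkers must be positive")
    if (object@mafLow < 0 || object@mafLow > object@mafHigh ||
        object@mafHigh > 0.5)
        msg <- c(msg, "need 0 <= mafLow <= mafHigh <= 0.5")
    if (object@targetCarrierFreq < 0 || object@targetCarrierFreq > 0.5)
        msg <- c(msg, "targetCarrierFreq must lie in [0, 0.5]")
    if (object@lethalPositionBp < 1 ||
        object@lethalPositionBp > object@chromLengthBp)
        msg <- c(msg, "lethalPositionBp outside the chromosome")
    if (object@recombRate < 0) msg <- c(msg, "recombRate must be >= 0")
    if (object@ovulationMean <= 0) msg <- c(msg, "ovulationMean must be > 0")
    if (object@uterineCapacity <= 0)
        msg <- c(msg, "uterineCapacity must be > 0 (use Inf to disable)")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phased genotypes
## ---------------------------------------------------------------------------

#' Phased diploid SNP genotypes
#'
#' A `RangedSummarizedExperiment` with two integer assays, `hap1` and `hap2`
#' (markers x animals, values 0/1 with `NA` for missing calls), marker
#' coordinates and ref/alt labels in `rowRanges`, and animal identifiers as
#' column names. Missing calls occur on both haploids of a site or neither.
#' The `phased` metadata flag records whether haploid order is meaningful;
#' the haplotype scan refuses unphased input.
#'
#' @export
setClass("PhasedGenotypes",
    contains = "RangedSummarizedExperiment")

setValidity("PhasedGenotypes", function(object) {
    msg <- character(0)
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("hap1", "hap2") %in% an))
        return("assays 'hap1' and 'hap2' are required")
    h1 <- assay(object, "hap1"); h2 <- assay(object, "hap2")
    if (!identical(is.na(h1), is.na(h2)))
        msg <- c(msg, "missing calls must hit both haploids of a site")
    ok <- is.na(h1) | h1 %in% c(0L, 1L)
    if (!all(ok)) msg <- c(msg, "hap1 allele calls must be 0, 1 or NA")
    ok <- is.na(h2) | h2 %in% c(0L, 1L)
    if (!all(ok)) msg <- c(msg, "hap2 allele calls must be 0, 1 or NA")
    pos <- start(rowRanges(object))
    chr <- as.character(seqnames(rowRanges(object)))
    if (length(pos) > 1L) {
        unsorted <- unlist(lapply(split(pos, chr), function(p)
            any(diff(p) <= 0)))
        if (any(unsorted))
            msg <- c(msg, "marker positions must strictly increase per chromosome")
    }
    if (is.null(metadata(object)$phased))
        msg <- c(msg, "metadata 'phased' flag is required")
    if (is.null(colnames(object)))
        msg <- c(msg, "animal identifiers (colnames) are required")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Annotated variant panel
## ---------------------------------------------------------------------------

#' Annotated sequence-variant panel with per-animal dosages
#'
#' A `RangedSummarizedExperiment` with one assay, `dosage` (variants x
#' animals, alternate-allele dosage 0/1/2 with `NA` for missing), and
#' per-variant annotation in `rowRanges` metadata columns: `ref`, `alt`,
#' `class` (consequence class from the closed vocabulary in
#' [consequenceClasses()]) and `deleterious` (SIFT-style flag, meaningful
#' for missense variants).
#'
#' @export
setClass("VariantPanel", contains = "RangedSummarizedExperiment")

#' Closed vocabulary of variant consequence classes
#'
#' The first six classes are treated as high-impact (loss-of-function)
#' throughout; deleterious missense variants rank immediately below them.
#'
#' @return character vector of admissible consequence classes.
#' @export
consequenceClasses <- function()
    c("splice_acceptor", "splice_donor", "frameshift", "stop_gained",
      "stop_lost", "start_lost", "inframe_indel", "missense", "synonymous",
      "intergenic")

#' High-impact (loss-of-function) consequence classes
#' @return character vector, a subset of [consequenceClasses()].
#' @export
lofClasses <- function()
    c("splice_acceptor", "splice_donor", "frameshift", "stop_gained",
      "stop_lost", "start_lost")

setValidity("VariantPanel", function(object) {
    msg <- character(0)
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (!all(is.na(d) | d %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    mc <- mcols(rowRanges(object))
    need <- c("ref", "alt", "class")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, "rowRanges mcols must contain ref, alt, class")
    else if (!all(mc$class %in% consequenceClasses()))
        msg <- c(msg, "unknown consequence class")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Scan products
## ---------------------------------------------------------------------------

#' A candidate lethal haplotype
#'
#' One row of a missing-homozygosity scan report: a genomic window, the
#' haplotype allele vector that defines the candidate, carrier counts, the
#' two expected-homozygote estimates (Hardy-Weinberg frequency-based and
#' trio-based), the exact-binomial deficit p-values, and carrier-by-carrier
#' progeny counts.
#'
#' @slot chrom chromosome name.
#' @slot startBp,endBp window span, 1-based inclusive.
#' @slot alleles integer 0/1 vector over the window markers.
#' @slot nGenotyped animals with complete calls over the window (N).
#' @slot nCarriers heterozygous carriers (C).
#' @slot nHomObs observed haplotype homozygotes (O).
#' @slot hapFreq haplotype frequency f among counted haploids.
#' @slot expectedFreq Hardy-Weinberg expected homozygotes, C^2/(4N) adjusted
#'   for homozygous carriers.
#' @slot expectedTrio trio-based expectation, 0.25 per genotyped
#'   carrier-x-carrier offspring (`NA` without pedigree).
#' @slot pDeficit exact binomial deficit p-value, frequency parameterization.
#' @slot pTrio exact binomial deficit p-value among CxC progeny (`NA`
#'   without pedigree).
#' @slot nCxCProgeny,nHetProgeny genotyped CxC offspring and how many of
#'   them are heterozygous carriers.
#' @slot carrierIds identifiers of carrier animals (het or hom).
#' @export
setClass("CandidateHaplotype", slots = c(
    chrom = "character", startBp = "numeric", endBp = "numeric",
    alleles = "integer",
    nGenotyped = "integer", nCarriers = "integer", nHomObs = "integer",
    hapFreq = "numeric", expectedFreq = "numeric", expectedTrio = "numeric",
    pDeficit = "numeric", pTrio = "numeric",
    nCxCProgeny = "integer", nHetProgeny = "integer",
    carrierIds = "character"))

setValidity("CandidateHaplotype", function(object) {
    msg <- character(0)
    if (object@nHomObs < 0L || object@nCarriers < 0L)
        msg <- c(msg, "counts must be non-negative")
    if (!is.na(object@pDeficit) &&
        (object@pDeficit < 0 || object@pDeficit > 1))
        msg <- c(msg, "pDeficit must be a probability")
    if (object@startBp > object@endBp)
        msg <- c(msg, "startBp must not exceed endBp")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Parameter holders
## ---------------------------------------------------------------------------

#' Marker and animal quality-control thresholds
#'
#' @slot mafMin minimum minor allele frequency (default 0.01).
#' @slot markerCallrateMin minimum per-marker call rate (default 0.85).
#' @slot animalCallrateMin minimum per-animal call rate (default 0.7).
#' @slot hweAlpha exact Hardy-Weinberg test significance level below which a
#'   marker is discarded (default 1e-5; a deliberately liberal threshold so
#'   that markers tagging a lethal haplotype, themselves mildly out of HWE,
#'   survive filtering).
#' @export
setClass("QCThresholds", slots = c(
    mafMin = "numeric", markerCallrateMin = "numeric",
    animalCallrateMin = "numeric", hweAlpha = "numeric"))

setValidity("QCThresholds", function(object) {
    v <- c(object@mafMin, object@markerCallrateMin,
           object@animalCallrateMin, object@hweAlpha)
    if (all(v >= 0 & v <= 1)) TRUE else "thresholds must lie in [0, 1]"
})

#' Sliding-window specification for the haplotype scan
#'
#' @slot sizesBp window lengths in bp (default 0.5, 1, 2 and 5 Mb).
#' @slot stepFraction step between window starts as a fraction of window
#'   length (default 0.5, i.e. half-overlapping windows).
#' @slot minHapFreq minimum haplotype frequency evaluated (default 0.005).
#' @slot alpha deficit-test significance level (default 5e-3).
#' @export
setClass("WindowSpec", slots = c(
    sizesBp = "numeric", stepFraction = "numeric",
    minHapFreq = "numeric", alpha = "numeric"))

setValidity("WindowSpec", function(object) {
    msg <- character(0)
    if (any(object@sizesBp <= 0)) msg <- c(msg, "window sizes must be > 0")
    if (object@stepFraction <= 0 || object@stepFraction > 1)
        msg <- c(msg, "stepFraction must lie in (0, 1]")
    if (object@minHapFreq < 0 || object@minHapFreq > 1)
        msg <- c(msg, "minHapFreq must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Candidate-variant co-segregation criteria
#'
#' @slot flankBp maximum distance from the haplotype boundaries (default 5 Mb).
#' @slot r2Min minimum LD r-squared with the haplotype dosage (default 0.8;
#'   0.7 is the customary relaxed alternative).
#' @slot maxHom maximum homozygous-alternate animals tolerated (default 1,
#'   allowing one false genotype assignment).
#' @slot maxDiscordant carrier/non-carrier co-segregation mismatches
#'   tolerated (default 1).
#' @slot requireClass optional consequence-class subset; empty = no
#'   class restriction.
#' @export
setClass("FilterCriteria", slots = c(
    flankBp = "numeric", r2Min = "numeric", maxHom = "integer",
    maxDiscordant = "integer", requireClass = "character"))

setValidity("FilterCriteria", function(object) {
    msg <- character(0)
    if (object@r2Min < 0 || object@r2Min > 1)
        msg <- c(msg, "r2Min must lie in [0, 1]")
    if (object@flankBp < 0) msg <- c(msg, "flankBp must be >= 0")
    if (length(object@requireClass) &&
        !all(object@requireClass %in% consequenceClasses()))
        msg <- c(msg, "unknown consequence class in requireClass")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Drift simulation
## ---------------------------------------------------------------------------

#' Wright-Fisher drift simulation configuration
#'
#' @slot p0 starting allele frequency of the focal (lethal) allele.
#' @slot twoN haploid sample size per generation; default 300, i.e. an
#'   effective population size of 150 diploids.
#' @slot fitness viability of the three genotypes `(wAA, wAa, waa)` where A
#'   is the focal allele; the lethal default is `c(0, 1, 1)`.
#' @slot generations number of generations simulated.
#' @slot replicates number of independent replicate populations.
#' @slot seed integer RNG seed.
#' @export
setClass("DriftConfig", slots = c(
    p0 = "numeric", twoN = "integer", fitness = "numeric",
    generations = "integer", replicates = "integer", seed = "integer"))

setValidity("DriftConfig", function(object) {
    msg <- character(0)
    if (object@p0 < 0 || object@p0 > 1) msg <- c(msg, "p0 must lie in [0, 1]")
    if (object@twoN < 2L) msg <- c(msg, "twoN must be >= 2")
    if (length(object@fitness) != 3L ||
        any(object@fitness < 0 | object@fitness > 1) ||
        all(object@fitness == 0))
        msg <- c(msg, "fitness must be three values in [0, 1], not all zero")
    if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Replicate allele-frequency trajectories with per-generation summaries
#'
#' @slot trajectories replicates x (generations + 1) matrix of frequencies;
#'   column g holds the frequency after g - 1 generations.
#' @slot summaries per-generation data.frame: median, 5% and 95% quantiles,
#'   fraction of replicates segregating (0 < p < 1), lost (p = 0) and fixed
#'   (p = 1).
#' @slot config the `DriftConfig` that produced the result.
#' @export
setClass("DriftResult", slots = c(
    trajectories = "matrix", summaries = "data.frame", config = "DriftConfig"))

setValidity("DriftResult", function(object) {
    tr <- object@trajectories
    if (any(tr < 0 | tr > 1)) return("frequencies must lie in [0, 1]")
    s <- object@summaries
    if (nrow(s) &&
        any(abs(s$lost + s$fixed + s$segregating - 1) > 1e-12))
        return("lost + fixed + segregating must equal 1 each generation")
    TRUE
})
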