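#' @importFrom stats median quantile rbinom rpois runif rnbinom setNames
#'   pbinom pchisq complete.cases cor t.test
#' @importFrom utils read.delim write.table head
NULL

setGeneric("animalIds", function(x) standardGeneric("animalIds"))
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
setGeneric("hapAlleles", function(x, which = 1L) standardGeneric("hapAlleles"))
setGeneric("genotypeDosage", function(x, ...) standardGeneric("genotypeDosage"))
setGeneric("isPhased", function(x) standardGeneric("isPhased"))
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
setGeneric("consequenceClass", function(x) standardGeneric("consequenceClass"))
setGeneric("variantDosage", function(x) standardGeneric("variantDosage"))
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
setGeneric("driftSummaries", function(x) standardGeneric("driftSummaries"))

#' @describeIn PhasedGenotypes-class animal identifiers.
#' @param x a `PhasedGenotypes` object.
#' @export
setMethod("animalIds", "PhasedGenotypes", function(x) colnames(x))

#' @describeIn PhasedGenotypes-class marker coordinates as a `GRanges`.
#' @export
setMethod("markerMap", "PhasedGenotypes", function(x) rowRanges(x))

#' @describeIn PhasedGenotypes-class one haploid allele matrix
#'   (markers x animals); `which` selects haploid 1 or 2.
#' @param which haploid index, 1 or 2.
#' @export
setMethod("hapAlleles", "PhasedGenotypes", function(x, which = 1L)
    assay(x, if (which == 1L) "hap1" else "hap2"))

#' @describeIn PhasedGenotypes-class alternate-allele dosage matrix
#'   (markers x animals), `hap1 + hap2`.
#' @export
setMethod("genotypeDosage", "PhasedGenotypes", function(x, ...)
    assay(x, "hap1") + assay(x, "hap2"))

#' @describeIn PhasedGenotypes-class whether haploid order is meaningful.
#' @export
setMethod("isPhased", "PhasedGenotypes", function(x)
    isTRUE(metadata(x)$phased))

#' @describeIn PhasedGenotypes-class number of animals.
#' @export
setMethod("nAnimals", "PhasedGenotypes", function(x) ncol(x))

#' @describeIn PhasedGenotypes-class number of markers.
#' @export
setMethod("nMarkers", "PhasedGenotypes", function(x) nrow(x))

setMethod("show", "PhasedGenotypes", function(object) {
    chr <- unique(as.character(seqnames(rowRanges(object))))
    cat("PhasedGenotypes:", ncol(object), "animals x", nrow(object),
        "markers on", length(chr),
        if (length(chr) == 1L) "chromosome" else "chromosomes",
        paste0("(", paste(head(chr, 3), collapse = ", "),
               if (length(chr) > 3) ", ..." else "", ")"), "\n")
    cat("  phased:", isPhased(object),
        " missing calls:", sum(is.na(assay(object, "hap1"))), "\n")
})

#' @describeIn VariantPanel-class consequence class per variant.
#' @param x a `VariantPanel` object.
#' @export
setMethod("consequenceClass", "VariantPanel", function(x)
    mcols(rowRanges(x))$class)

#' @describeIn VariantPanel-class dosage matrix (variants x animals).
#' @export
setMethod("variantDosage", "VariantPanel", function(x) assay(x, "dosage"))

setMethod("show", "VariantPanel", function(object) {
    cat("VariantPanel:", nrow(object), "variants x", ncol(object),
        "animals\n")
    print(table(consequenceClass(object)))
})

setMethod("show", "CandidateHaplotype", function(object) {
    cat(sprintf(
        "CandidateHaplotype %s:%.1f-%.1f Mb  C=%d/%d (%.1f%%)  O=%d  E(freq)=%.1f%s  p=%.3g\n",
        object@chrom, object@startBp / 1e6, object@endBp / 1e6,
        object@nCarriers, object@nGenotyped,
        100 * object@nCarriers / object@nGenotyped, object@nHomObs,
        object@expectedFreq,
        if (is.na(object@expectedTrio)) ""
        else sprintf("  E(trio)=%.2f", object@expectedTrio),
        object@pDeficit))
})

#' @describeIn DriftResult-class replicate x generation frequency matrix.
#' @param x a `DriftResult` object.
#' @export
setMethod("trajectories", "DriftResult", function(x) x@trajectories)

#' @describeIn DriftResult-class per-generation summary data.frame.
#' @export
setMethod("driftSummaries", "DriftResult", function(x) x@summaries)

setMethod("show", "DriftResult", function(object) {
    s <- object@summaries
    last <- s[nrow(s), ]
    cat("DriftResult:", nrow(object@trajectories), "replicates x",
        object@config@generations, "generations (p0 =",
        object@config@p0, ")\n")
    cat(sprintf("  generation %d: median p = %.4g, segregating %.1f%%, lost %.1f%%\n",
        last$generation, last$median, 100 * last$segregating,
        100 * last$lost))
})

#' Tabulate scan candidates
#'
#' Flattens a list of [CandidateHaplotype-class] objects into a
#' `data.frame` with the customary report columns (one row per candidate:
#' span, carrier count and frequency, trio- and frequency-based expected
#' homozygotes, observed homozygotes, deficit p-values, CxC progeny counts).
#' Coordinates are reported in Mb rounded to one decimal.
#'
#' @param candidates list of `CandidateHaplotype` objects.
#' @return a `data.frame`, zero rows if no candidates.
#' @export
candidateTable <- function(candidates) {
    if (!length(candidates))
        return(data.frame(hap = character(0), chrom = character(0),
                          startMb = numeric(0), endMb = numeric(0),
                          nCarriers = integer(0), carrierFreq = numeric(0),
                          expectedTrio = numeric(0), expectedFreq = numeric(0),
                          observed = integer(0), pDeficit = numeric(0),
                          pTrio = numeric(0), nCxCProgeny = integer(0),
                          nHetProgeny = integer(0), hetProgenyFrac = numeric(0)))
    rows <- lapply(seq_along(candidates), function(i) {
        cd <- candidates[[i]]
        data.frame(
            hap = paste0("H", i), chrom = cd@chrom,
            startMb = round(cd@startBp / 1e6, 1),
            endMb = round(cd@endBp / 1e6, 1),
            nCarriers = cd@nCarriers,
            carrierFreq = cd@nCarriers / cd@nGenotyped,
            expectedTrio = cd@expectedTrio, expectedFreq = cd@expectedFreq,
            observed = cd@nHomObs, pDeficit = cd@pDeficit, pTrio = cd@pTrio,
            nCxCProgeny = cd@nCxCProgeny, nHetProgeny = cd@nHetProgeny,
            hetProgenyFrac = if (cd@nCxCProgeny > 0)
                cd@nHetProgeny / cd@nCxCProgeny else NA_real_)
    })
    do.call(rbind, rows)
}
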