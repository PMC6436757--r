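#' Fine-map a candidate haplotype by recombinant exclusion
#'
#' Splits the candidate span into consecutive sub-haplotypes of
#' `subLengthBp` and examines whether any sub-haplotype is observed in
#' homozygous state among the candidate's carrier animals. A recombinant
#' carrier homozygous for part of the haplotype proves that part cannot
#' contain the causal recessive lethal; such sub-haplotypes are excluded
#' and the maximal remaining contiguous interval is returned.
#'
#' @param candidate a [CandidateHaplotype-class] object.
#' @param genotypes the phased [PhasedGenotypes-class] the candidate was
#'   scanned from.
#' @param subLengthBp sub-haplotype length (default 1 Mb). The candidate
#'   span must cover at least two sub-haplotypes.
#' @return list with `startBp`, `endBp` (refined interval; `NA` when every
#'   sub-haplotype is excluded), `excluded` (logical per sub-haplotype)
#'   and `subBounds` (matrix of sub-haplotype bounds).
#' @export
finemapRecombinants <- function(candidate, genotypes, subLengthBp = 1e6) {
    stopifnot(is(candidate, "CandidateHaplotype"),
              is(genotypes, "PhasedGenotypes"))
    span <- candidate@endBp - candidate@startBp + 1
    if (span < 2 * subLengthBp)
        stop("candidate span shorter than two sub-haplotypes")
    if (!length(candidate@carrierIds))
        stop("candidate has no carriers")
    starts <- seq(candidate@startBp, candidate@endBp, by = subLengthBp)
    starts <- starts[candidate@endBp - starts + 1 >= subLengthBp / 2]
    ends <- pmin(starts + subLengthBp - 1, candidate@endBp)

    rr <- rowRanges(genotypes)
    pos <- start(rr)
    sel <- which(as.character(seqnames(rr)) == candidate@chrom &
                 pos >= candidate@startBp & pos <= candidate@endBp)
    stopifnot(length(sel) == length(candidate@alleles))
    carrierIdx <- match(candidate@carrierIds, animalIds(genotypes))
    h1 <- assay(genotypes, "hap1")[sel, carrierIdx, drop = FALSE]
    h2 <- assay(genotypes, "hap2")[sel, carrierIdx, drop = FALSE]
    subPos <- pos[sel]

    excluded <- vapply(seq_along(starts), function(i) {
        inSub <- subPos >= starts[i] & subPos <= ends[i]
        if (!any(inSub)) return(FALSE)   # no markers: no evidence either way
        a <- candidate@alleles[inSub]
        hom1 <- colSums(h1[inSub, , drop = FALSE] == a) == sum(inSub)
        hom2 <- colSums(h2[inSub, , drop = FALSE] == a) == sum(inSub)
        any(hom1 & hom2, na.rm = TRUE)
    }, logical(1L))

    if (all(excluded))
        return(list(startBp = NA_real_, endBp = NA_real_,
                    excluded = excluded,
                    subBounds = cbind(start = starts, end = ends)))
    runs <- rle(!excluded)
    runEnds <- cumsum(runs$lengths)
    runStarts <- runEnds - runs$lengths + 1L
    keptRuns <- which(runs$values)
    best <- keptRuns[which.max(runs$lengths[keptRuns])]
    list(startBp = starts[runStarts[best]], endBp = ends[runEnds[best]],
         excluded = excluded, subBounds = cbind(start = starts, end = ends))
}
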