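#' Select and rank candidate causal variants for a lethal haplotype
#'
#' Applies the four co-segregation criteria for a recessive lethal
#' candidate mutation: the variant (a) lies within `flankBp` of the
#' haplotype boundaries, (b) is homozygous in at most `maxHom` animals,
#' (c) is carried (heterozygous or more) by the haplotype carriers and
#' absent from non-carriers, allowing `maxDiscordant` mismatching animals
#' for genotyping error, and (d) is in high LD with the haplotype dosage
#' (`r2 >= r2Min`). Passing variants are ranked high-impact
#' (loss-of-function) classes first, then deleterious missense, then the
#' rest, and by r-squared within rank. An empty result is a valid outcome:
#' some lethal haplotypes tag no coding candidate at all.
#'
#' @param panel a [VariantPanel-class] object.
#' @param candidate a [CandidateHaplotype-class] object.
#' @param genotypes the phased [PhasedGenotypes-class] behind the
#'   candidate; animal identifiers are matched by name between `panel` and
#'   `genotypes`.
#' @param criteria a [FilterCriteria-class] object.
#' @return `data.frame` of passing variants (columns `variant`, `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `deleterious`, `r2`, `nHetCarriers`,
#'   `nHom`, `rankGroup`), ordered by rank; attribute `noHighImpact` is
#'   `TRUE` when nothing of high impact passed.
#' @export
candidateVariants <- function(panel, candidate, genotypes,
                              criteria = filterCriteria()) {
    stopifnot(is(panel, "VariantPanel"), is(candidate, "CandidateHaplotype"),
              is(genotypes, "PhasedGenotypes"), is(criteria, "FilterCriteria"))
    shared <- intersect(colnames(panel), animalIds(genotypes))
    if (!length(shared))
        stop("panel and genotypes share no animal identifiers")
    hapDos <- haplotypeDosage(candidate, genotypes)[shared]
    carrier <- !is.na(hapDos) & hapDos >= 1L

    rr <- rowRanges(panel)
    pos <- start(rr)
    inFlank <- as.character(seqnames(rr)) == candidate@chrom &
        pos >= candidate@startBp - criteria@flankBp &
        pos <= candidate@endBp + criteria@flankBp
    dos <- variantDosage(panel)[, shared, drop = FALSE]

    rows <- lapply(which(inFlank), function(i) {
        d <- dos[i, ]
        nHom <- sum(d == 2L, na.rm = TRUE)
        if (nHom > criteria@maxHom) return(NULL)
        known <- !is.na(d) & !is.na(hapDos)
        discordant <- sum((carrier & known & d == 0L) |
                          (!carrier & known & d >= 1L))
        if (discordant > criteria@maxDiscordant) return(NULL)
        r2 <- suppressWarnings(ldR2(hapDos, d))
        if (is.na(r2) || r2 < criteria@r2Min) return(NULL)
        cls <- mcols(rr)$class[i]
        if (length(criteria@requireClass) &&
            !(cls %in% criteria@requireClass)) return(NULL)
        grp <- if (cls %in% lofClasses()) 1L
               else if (cls == "missense" && isTRUE(mcols(rr)$deleterious[i]))
                   2L
               else 3L
        data.frame(variant = names(rr)[i],
                   chrom = as.character(seqnames(rr))[i], pos = pos[i],
                   ref = mcols(rr)$ref[i], alt = mcols(rr)$alt[i],
                   class = cls, deleterious = isTRUE(mcols(rr)$deleterious[i]),
                   r2 = r2,
                   nHetCarriers = sum(carrier & !is.na(d) & d == 1L),
                   nHom = nHom, rankGroup = grp,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(variant = character(0), chrom = character(0),
                          pos = numeric(0), ref = character(0),
                          alt = character(0), class = character(0),
                          deleterious = logical(0), r2 = numeric(0),
                          nHetCarriers = integer(0), nHom = integer(0),
                          rankGroup = integer(0))
    out <- out[order(out$rankGroup, -out$r2), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, noHighImpact = !any(out$rankGroup == 1L))
}
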