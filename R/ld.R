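#' Per-animal dosage of a candidate haplotype
#'
#' Counts, per animal, how many of the two haploid sequences exactly match
#' the candidate allele vector over the candidate window. An animal with a
#' missing call anywhere in the window gets a missing dosage.
#'
#' @param candidate a [CandidateHaplotype-class] object.
#' @param genotypes the phased [PhasedGenotypes-class] the candidate was
#'   scanned from.
#' @return named integer vector (0/1/2, `NA` missing) over animals.
#' @export
haplotypeDosage <- function(candidate, genotypes) {
    stopifnot(is(candidate, "CandidateHaplotype"),
              is(genotypes, "PhasedGenotypes"))
    .haplotypeDosageIdx(genotypes, list(
        chrom = candidate@chrom, startBp = candidate@startBp,
        endBp = candidate@endBp, alleles = candidate@alleles))
}

#' Squared dosage correlation (LD r-squared)
#'
#' Squared Pearson correlation over complete pairs — the genotype-dosage
#' r-squared convention of standard association toolkits. Sign-invariant:
#' a variant in perfect repulsion scores 1 like one in perfect coupling.
#'
#' @param x,y per-animal dosage vectors (equal length).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when fewer than
#'   two complete pairs remain or either vector is constant.
#' @examples
#' ldR2(c(0, 1, 2, 1), c(2, 1, 0, 1))  # 1: sign-invariant
#' @export
ldR2 <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) {
        warning("fewer than 2 complete dosage pairs; r2 undefined")
        return(NA_real_)
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) {
        warning("constant dosage vector; r2 undefined")
        return(NA_real_)
    }
    cor(x, y)^2
}
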