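#' Welch two-sample t-test on litter phenotypes
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided) comparing, e.g., total number born of carrier-x-carrier
#' versus carrier-x-non-carrier matings.
#'
#' @param valuesA,valuesB numeric vectors, each with at least two values
#'   and nonzero variance.
#' @return list `statistic`, `df`, `p.value`, `meanA`, `meanB`.
#' @export
welchT <- function(valuesA, valuesB) {
    if (length(valuesA) < 2L || length(valuesB) < 2L)
        stop("each group needs at least two values")
    if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
        if (mean(valuesA) == mean(valuesB))
            return(list(statistic = 0, df = NA_real_, p.value = 1,
                        meanA = mean(valuesA), meanB = mean(valuesB)))
        stop("both groups degenerate (zero variance)")
    }
    tt <- t.test(valuesA, valuesB, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, meanA = mean(valuesA), meanB = mean(valuesB))
}

#' Relative litter-size reduction of carrier-x-carrier matings
#'
#' @param tnbCxC,tnbCxNC mean total number born of CxC and CxNC matings.
#' @return `(tnbCxNC - tnbCxC) / tnbCxNC`.
#' @examples
#' tnbReduction(7.33, 9.35)  # 0.216
#' @export
tnbReduction <- function(tnbCxC, tnbCxNC) {
    stopifnot(all(tnbCxNC > 0))
    (tnbCxNC - tnbCxC) / tnbCxNC
}

#' Fraction of litters from carrier-x-carrier matings
#'
#' Under random mating, both mates carry with probability equal to the
#' squared carrier frequency.
#'
#' @param carrierFreq carrier frequency in `[0, 1]`.
#' @return fraction of affected litters.
#' @examples
#' affectedLitters(0.134)  # 0.0180
#' @export
affectedLitters <- function(carrierFreq) {
    stopifnot(all(carrierFreq >= 0 & carrierFreq <= 1))
    carrierFreq^2
}

#' Piglets lost to observed carrier-x-carrier matings
#'
#' @param nCxC number of CxC litters observed.
#' @param tnbCxC,tnbCxNC mean total number born per mating type.
#' @return piglet count, `nCxC * (tnbCxNC - tnbCxC)`.
#' @examples
#' pigletLoss(297, 11.51, 14.18)  # 792.99
#' @export
pigletLoss <- function(nCxC, tnbCxC, tnbCxNC) {
    stopifnot(all(nCxC >= 0))
    nCxC * (tnbCxNC - tnbCxC)
}

#' Per-haplotype fertility-impact table
#'
#' Computes, for each lethal haplotype, the litter-size reduction, the
#' fraction of affected litters, the piglet loss over the observed CxC
#' litters, the fraction of all embryos in the population dying
#' (`affected x reduction`), and the expected per-litter piglet reduction
#' across the whole population (`meanTnb x death fraction`). The
#' `affected` argument overrides the squared-carrier-frequency estimate
#' for rows whose affected-litter fraction is known from an external
#' source at higher precision than the rounded carrier frequency.
#'
#' @param hap haplotype labels.
#' @param nCxC,nCxNC litter counts per mating type.
#' @param tnbCxC,tnbCxNC mean total number born per mating type.
#' @param carrierFreq carrier frequencies (fractions).
#' @param meanTnb population mean total number born.
#' @param affected optional per-row affected-litter fractions overriding
#'   `carrierFreq^2` (use `NA` to keep the computed value).
#' @return `data.frame` with one row per haplotype: `hap`, `nCxC`,
#'   `nCxNC`, `tnbCxC`, `tnbCxNC`, `reduction`, `affected`, `pigletLoss`,
#'   `pctDeath`, `populationReduction` (all fractions, not percentages).
#' @export
impactTable <- function(hap, nCxC, nCxNC, tnbCxC, tnbCxNC, carrierFreq,
                        meanTnb, affected = NULL) {
    red <- tnbReduction(tnbCxC, tnbCxNC)
    aff <- affectedLitters(carrierFreq)
    if (!is.null(affected)) {
        use <- !is.na(affected)
        aff[use] <- affected[use]
    }
    pctDeath <- aff * red
    data.frame(hap = hap, nCxC = nCxC, nCxNC = nCxNC,
               tnbCxC = tnbCxC, tnbCxNC = tnbCxNC,
               reduction = red, affected = aff,
               pigletLoss = pigletLoss(nCxC, tnbCxC, tnbCxNC),
               pctDeath = pctDeath,
               populationReduction = meanTnb * pctDeath,
               stringsAsFactors = FALSE)
}

#' Population-level totals of an impact table
#'
#' @param table output of [impactTable()] for one population.
#' @return list `totalAffected`, `totalPigletLoss`, `totalPctDeath`,
#'   `totalPopulationReduction` (sums over rows; fractions).
#' @export
populationImpact <- function(table) {
    if (!nrow(table))
        return(list(totalAffected = 0, totalPigletLoss = 0,
                    totalPctDeath = 0, totalPopulationReduction = 0))
    list(totalAffected = sum(table$affected),
         totalPigletLoss = sum(table$pigletLoss),
         totalPctDeath = sum(table$pctDeath),
         totalPopulationReduction = sum(table$populationReduction))
}

#' Mendelian genotype-ratio test for carrier-x-carrier litters
#'
#' Pearson chi-square goodness of fit of the observed wildtype /
#' heterozygote / homozygote counts against the Mendelian 1:2:1
#' expectation (df = 2, no continuity correction), plus the lower-tail
#' exact binomial probability of the observed homozygote count under
#' p = 0.25 — the direct test for missing homozygotes.
#'
#' @param nWt,nHet,nHom observed genotype counts.
#' @return list `chisq`, `df`, `p.chisq`, `p.binom.hom`.
#' @examples
#' genotypeRatioTest(3, 10, 0)   # p.chisq = 0.076
#' @export
genotypeRatioTest <- function(nWt, nHet, nHom) {
    n <- nWt + nHet + nHom
    if (n == 0L) stop("no genotyped progeny")
    obs <- c(nWt, nHet, nHom)
    expd <- n * c(0.25, 0.5, 0.25)
    stat <- sum((obs - expd)^2 / expd)
    list(chisq = stat, df = 2L,
         p.chisq = pchisq(stat, df = 2L, lower.tail = FALSE),
         p.binom.hom = pbinom(nHom, n, 0.25))
}

#' Share of the crossbred litter-size advantage attributable to lethals
#'
#' Crossbred litters escape recessive lethal losses when the lethals
#' segregate in only one parental line; the fraction of the observed
#' purebred-to-crossbred litter-size difference explained by the
#' identified lethals is their total population piglet reduction divided
#' by that difference.
#'
#' @param tnbPurebred,tnbCrossbred mean total number born.
#' @param totalPopulationReduction piglets per litter lost to lethals in
#'   the purebred population (see [populationImpact()]).
#' @return fraction in `[0, 1]`; values above 1 are clipped with a
#'   warning.
#' @examples
#' heterosisAttribution(14.18, 14.38, 0.0739)  # 0.370
#' @export
heterosisAttribution <- function(tnbPurebred, tnbCrossbred,
                                 totalPopulationReduction) {
    diffTnb <- tnbCrossbred - tnbPurebred
    if (diffTnb <= 0)
        stop("crossbred litters must exceed purebred litters")
    frac <- totalPopulationReduction / diffTnb
    if (frac > 1) {
        warning("attribution exceeds 1; clipped")
        frac <- 1
    }
    frac
}

#' Population burden of segregating recessive lethals
#'
#' Low-frequency Hardy-Weinberg approximations: each individual carries
#' `2 n q` lethals in heterozygous state, and a fraction `n q^2` of
#' embryos dies homozygous, for `n` independent lethals at mean allele
#' frequency `q`.
#'
#' @param nLethals number of segregating recessive lethal alleles.
#' @param meanAlleleFreq their mean allele frequency.
#' @return list `carriedPerIndividual`, `embryoDeathFraction`.
#' @examples
#' populationBurden(20, 0.02)  # ~0.8 carried, ~0.8% of embryos
#' @export
populationBurden <- function(nLethals, meanAlleleFreq) {
    stopifnot(nLethals >= 0, meanAlleleFreq >= 0)
    list(carriedPerIndividual = 2 * nLethals * meanAlleleFreq,
         embryoDeathFraction = nLethals * meanAlleleFreq^2)
}

#' Carrier-frequency time series over half-year bins
#'
#' Fraction of carriers among animals alive in each bin, where an animal
#' is alive from its birthdate for `lifespanDays` (default: indefinitely,
#' i.e. no culling information).
#'
#' @param pedigree `data.frame` with `id` and `birthdate` (Date).
#' @param carrierStatus named logical vector over animal identifiers.
#' @param from first bin start (default 2012-01-01).
#' @param binDays bin width in days (default 182, half a year).
#' @param lifespanDays days an animal stays in the live population.
#' @return `data.frame` with `binStart`, `nAlive`, `nCarriers`,
#'   `carrierFreq` (`NA` for empty bins).
#' @export
carrierFrequencyTimeseries <- function(pedigree, carrierStatus,
                                       from = as.Date("2012-01-01"),
                                       binDays = 182L,
                                       lifespanDays = Inf) {
    stopifnot(all(c("id", "birthdate") %in% colnames(pedigree)))
    birth <- as.Date(pedigree$birthdate)
    status <- carrierStatus[pedigree$id]
    last <- max(birth)
    starts <- seq(from, last, by = binDays)
    rows <- lapply(starts, function(s) {
        e <- s + binDays
        alive <- birth < e & (as.numeric(s - birth) < lifespanDays)
        nAlive <- sum(alive)
        nCar <- sum(status[alive], na.rm = TRUE)
        data.frame(binStart = s, nAlive = nAlive, nCarriers = nCar,
                   carrierFreq = if (nAlive > 0) nCar / nAlive else NA_real_)
    })
    do.call(rbind, rows)
}
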