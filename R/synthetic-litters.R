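#' Expected number of implanted embryos
#'
#' `E[min(X, cap)]` for `X ~ Poisson(lambda)`; used to calibrate the
#' embryo-to-term survival probability so that non-carrier matings average
#' `litterMean` total born regardless of the compensation regime.
#' @keywords internal
.expectedImplanted <- function(lambda, cap) {
    if (!is.finite(cap)) return(lambda)
    cap <- floor(cap)
    k <- 0:(cap - 1)
    sum(k * stats::dpois(k, lambda)) + cap * stats::ppois(cap - 1, lambda,
                                                          lower.tail = FALSE)
}

.survivalProb <- function(config) {
    s <- config@litterMean /
        .expectedImplanted(config@ovulationMean, config@uterineCapacity)
    if (s > 1)
        stop("litterMean unreachable: expected implanted embryos (",
             signif(config@litterMean / s, 4), ") below litterMean")
    s
}

#' Simulate one litter given parental lethal genotypes
#'
#' Ovulates `Poisson(ovulationMean)` zygotes; each inherits one allele per
#' parent by Mendelian segregation at the lethal locus. Homozygous-lethal
#' zygotes die before implantation; the survivors are truncated at
#' `uterineCapacity` (excess ovulation thereby partially masks the loss of
#' lethal homozygotes), and each implanted embryo survives to term with a
#' probability calibrated so non-carrier x non-carrier matings average
#' `litterMean` total born. Stillborn and mummified counts are drawn from
#' background rates independent of lethal carrier status.
#'
#' @param sireGt,damGt parental lethal-allele copy number (0, 1 or 2).
#' @param config a [SimConfig-class] object. The caller controls the RNG
#'   state (`set.seed`).
#' @return list with `TNB`, `NBA`, `NSB`, `MUM`, `nOvulated`,
#'   `nLethalZygotes` and `pigletGenotypes` (lethal-allele copy number per
#'   surviving piglet; never 2 under complete lethality).
#' @examples
#' set.seed(1)
#' litterModel(1, 1, simConfig(seed = 1))
#' @export
litterModel <- function(sireGt, damGt, config) {
    stopifnot(sireGt %in% 0:2, damGt %in% 0:2)
    s <- .survivalProb(config)
    nOv <- rpois(1L, config@ovulationMean)
    fromSire <- rbinom(nOv, 1L, sireGt / 2)
    fromDam <- rbinom(nOv, 1L, damGt / 2)
    gt <- fromSire + fromDam
    alive <- gt[gt < 2L]
    nImplanted <- min(length(alive), config@uterineCapacity)
    implanted <- alive[seq_len(nImplanted)]
    keep <- runif(nImplanted) <= s
    piglets <- implanted[keep]
    tnb <- length(piglets)
    nsb <- rbinom(1L, tnb, config@nsbRate)
    mum <- rbinom(1L, tnb, config@mumRate)
    list(TNB = tnb, NBA = tnb - nsb, NSB = nsb, MUM = mum,
         nOvulated = nOv, nLethalZygotes = sum(gt == 2L),
         pigletGenotypes = piglets)
}

#' Simulate many litters of one mating type
#'
#' Convenience wrapper around [litterModel()] returning a litter-record
#' `data.frame` (one row per litter).
#'
#' @param n number of litters.
#' @inheritParams litterModel
#' @return `data.frame` with columns `sire`, `dam`, `date`, `TNB`, `NBA`,
#'   `NSB`, `MUM`.
#' @export
simulateLitters <- function(n, sireGt, damGt, config) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
        l <- litterModel(sireGt, damGt, config)
        out[[i]] <- data.frame(sire = sprintf("S%04d", i),
                               dam = sprintf("D%04d", i),
                               date = as.Date("2012-01-01"),
                               TNB = l$TNB, NBA = l$NBA, NSB = l$NSB,
                               MUM = l$MUM)
    }
    do.call(rbind, out)
}
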