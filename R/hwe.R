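#' Exact test of Hardy-Weinberg equilibrium for one biallelic marker
#'
#' Conditional on the observed allele counts, computes the two-sided exact
#' probability of a heterozygote count at least as improbable as the one
#' observed (the standard exact HWE formulation: sum of the conditional
#' probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count). Monomorphic markers return 1.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts.
#' @return exact p-value in `[0, 1]`.
#' @examples
#' hweExactTest(25, 50, 25)   # perfect HWE proportions -> 1
#' hweExactTest(50, 0, 50)    # total heterozygote deficit -> ~0
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
    stopifnot(nHomRef >= 0, nHet >= 0, nHomAlt >= 0)
    n <- nHomRef + nHet + nHomAlt
    if (n == 0L) stop("no genotypes")
    nAlt <- 2L * nHomAlt + nHet
    nMinor <- min(nAlt, 2L * n - nAlt)
    if (nMinor == 0L) return(1)
    ## heterozygote counts share the parity of the minor allele count
    hs <- seq(nMinor %% 2L, nMinor, by = 2L)
    rare <- (nMinor - hs) %/% 2L
    common <- n - hs - rare
    logp <- lfactorial(n) - lfactorial(rare) - lfactorial(hs) -
        lfactorial(common) + hs * log(2) +
        lfactorial(nMinor) + lfactorial(2L * n - nMinor) - lfactorial(2L * n)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    pObs <- p[match(nHet, hs)]
    min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}
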