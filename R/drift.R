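#' Expected allele frequency after one round of viability selection
#'
#' Standard deterministic viability-selection update for a biallelic locus
#' with the focal allele A at frequency `p` and genotype fitnesses
#' `(wAA, wAa, waa)`:
#' `p* = (p^2 wAA + p(1-p) wAa) / (p^2 wAA + 2 p(1-p) wAa + (1-p)^2 waa)`.
#' For a fully recessive lethal (`wAA = 0`, others 1) this reduces to the
#' closed form `p* = p / (1 + p)`.
#'
#' @param p focal-allele frequency in `[0, 1]`.
#' @param fitness numeric triple `(wAA, wAa, waa)`.
#' @return post-selection expected frequency; errors if mean fitness is 0.
#' @examples
#' postSelectionFreq(0.1, c(0, 1, 1))  # 0.1 / 1.1
#' @export
postSelectionFreq <- function(p, fitness = c(0, 1, 1)) {
    stopifnot(all(p >= 0 & p <= 1), length(fitness) == 3L)
    w <- fitness
    ## fully recessive lethal: the p = 1 singularity of the general update
    ## is removable, so use the closed form directly
    if (w[1L] == 0 && w[2L] == w[3L] && w[2L] > 0)
        return(p / (1 + p))
    num <- p^2 * w[1L] + p * (1 - p) * w[2L]
    wbar <- p^2 * w[1L] + 2 * p * (1 - p) * w[2L] + (1 - p)^2 * w[3L]
    if (any(wbar == 0))
        stop("mean fitness is zero; population inviable")
    num / wbar
}

#' One Wright-Fisher generation with viability selection
#'
#' Binomial sampling of `twoN` haploid draws with success probability
#' equal to the post-selection expected frequency. Vectorized over
#' replicate populations.
#'
#' @param p frequency (scalar or vector over replicates).
#' @param config a [DriftConfig-class] object (`twoN`, `fitness`).
#' @return next-generation frequencies, same length as `p`.
#' @export
wfStep <- function(p, config) {
    stopifnot(is(config, "DriftConfig"))
    ps <- postSelectionFreq(p, config@fitness)
    rbinom(length(p), config@twoN, ps) / config@twoN
}

#' Simulate replicate Wright-Fisher allele-frequency trajectories
#'
#' Independent replicate populations evolve for `generations` rounds of
#' viability selection plus binomial drift. Per-generation summaries
#' report the median, the 5% and 95% quantiles, and the fractions of
#' replicates segregating (0 < p < 1), lost (p = 0) and fixed (p = 1).
#' Reproducible: the configured seed initializes the RNG.
#'
#' @param config a [DriftConfig-class] object.
#' @return a [DriftResult-class] object.
#' @examples
#' res <- simulateTrajectories(driftConfig(p0 = 0.067, replicates = 100,
#'                                         seed = 7))
#' head(driftSummaries(res))
#' @export
simulateTrajectories <- function(config) {
    stopifnot(is(config, "DriftConfig"))
    validObject(config)
    set.seed(config@seed)
    reps <- config@replicates
    gens <- config@generations
    tr <- matrix(NA_real_, reps, gens + 1L)
    tr[, 1L] <- config@p0
    p <- rep(config@p0, reps)
    for (g in seq_len(gens)) {
        p <- wfStep(p, config)
        tr[, g + 1L] <- p
    }
    colnames(tr) <- paste0("gen", 0:gens)
    summaries <- data.frame(
        generation = 0:gens,
        median = apply(tr, 2L, median),
        q05 = apply(tr, 2L, quantile, probs = 0.05),
        q95 = apply(tr, 2L, quantile, probs = 0.95),
        segregating = colMeans(tr > 0 & tr < 1),
        lost = colMeans(tr == 0),
        fixed = colMeans(tr == 1))
    rownames(summaries) <- NULL
    new("DriftResult", trajectories = tr, summaries = summaries,
        config = config)
}

#' Persistence of de novo mutations
#'
#' Fraction of replicate populations in which an allele starting at the
#' de novo frequency (one copy among the census diploids, e.g.
#' 1/4100 = 0.024% for a census of 2050) is still segregating
#' (0 < p < 1) at the horizon generation.
#'
#' @param config a [DriftConfig-class]; `p0` should be the de novo start
#'   frequency and `generations` at least `horizon`.
#' @param horizon generation at which persistence is evaluated (defaults
#'   to `config@generations`).
#' @return fraction of replicates segregating at the horizon, with the
#'   full [DriftResult-class] as attribute `result`.
#' @export
deNovoPersistence <- function(config, horizon = config@generations) {
    stopifnot(horizon >= 0, horizon <= config@generations)
    if (config@p0 <= 0) stop("p0 must be positive")
    res <- simulateTrajectories(config)
    p <- trajectories(res)[, horizon + 1L]
    structure(mean(p > 0 & p < 1), result = res)
}

#' De novo lethal mutation arithmetic
#'
#' Number of new mutations per individual (genome size times per-bp
#' mutation rate, rounded) and per generation (per-individual count times
#' the number of replacement animals).
#'
#' @param genomeSizeBp genome size in bp.
#' @param muPerBp mutation rate per bp per generation.
#' @param nReplacements replacement animals per generation.
#' @return named list `perIndividual`, `perGeneration`.
#' @examples
#' deNovoCount(4915.82e6, 1.2e-8, 1025)  # 59 and 60475
#' @export
deNovoCount <- function(genomeSizeBp, muPerBp, nReplacements) {
    stopifnot(genomeSizeBp >= 0, muPerBp >= 0, nReplacements >= 0)
    perInd <- round(genomeSizeBp * muPerBp)
    list(perIndividual = perInd, perGeneration = nReplacements * perInd)
}

#' Equilibrium number of segregating recessive lethals
#'
#' Simulation-based estimate of the mutation-drift-selection balance:
#' each generation, `Poisson(2 * nCensus * uLethal)` new independent
#' lethal loci arise at the de novo start frequency `1 / (2 * nCensus)`
#' and every extant locus evolves by one Wright-Fisher generation with
#' viability selection. After burn-in, the number of loci segregating at
#' or above `detectionFreq` and their mean frequency are averaged over
#' generations.
#'
#' @param uLethal recessive lethal mutations per gamete per generation.
#' @param config a [DriftConfig-class]; `twoN` and `fitness` drive the
#'   per-locus dynamics, `generations` is the post-burn-in observation
#'   span and `seed` seeds the RNG.
#' @param nCensus census population size (sets both the mutation influx
#'   and the de novo start frequency).
#' @param detectionFreq minimum frequency for a locus to count as
#'   segregating (default 0.02, roughly the detection floor of a
#'   large-cohort haplotype scan).
#' @param burnin generations discarded before averaging.
#' @return named list `meanSegregating`, `meanFreq` (mean frequency of
#'   counted loci), `perGeneration` (counts per observed generation).
#' @export
equilibriumSegregating <- function(uLethal, config = driftConfig(p0 = 0),
                                   nCensus = 2050, detectionFreq = 0.02,
                                   burnin = 200L) {
    stopifnot(uLethal >= 0)
    if (uLethal == 0)
        return(list(meanSegregating = 0, meanFreq = NA_real_,
                    perGeneration = numeric(0)))
    set.seed(config@seed)
    p0 <- 1 / (2 * nCensus)
    influx <- 2 * nCensus * uLethal
    p <- numeric(0)
    counts <- numeric(config@generations)
    freqSum <- 0; freqN <- 0L
    total <- burnin + config@generations
    for (g in seq_len(total)) {
        nNew <- rpois(1L, influx)
        p <- c(p, rep(p0, nNew))
        if (length(p)) {
            ps <- postSelectionFreq(p, config@fitness)
            p <- rbinom(length(p), config@twoN, ps) / config@twoN
        }
        p <- p[p > 0]            # lost loci leave the pool
        if (g > burnin) {
            above <- p[p >= detectionFreq & p < 1]
            counts[g - burnin] <- length(above)
            freqSum <- freqSum + sum(above)
            freqN <- freqN + length(above)
        }
    }
    list(meanSegregating = mean(counts),
         meanFreq = if (freqN > 0) freqSum / freqN else NA_real_,
         perGeneration = counts)
}
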