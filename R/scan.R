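#' Expected haplotype homozygotes under Hardy-Weinberg
#'
#' With `C` heterozygous carriers among `N` genotyped animals the
#' haplotype frequency is `f = C / (2N)` and the expected homozygote count
#' `N f^2 = C^2 / (4N)`. Homozygous carriers, if any, contribute two
#' haplotype copies each to the allele count before squaring.
#'
#' @param C heterozygous carrier count.
#' @param N genotyped animals.
#' @param nHom observed homozygous carriers (default 0).
#' @return expected homozygote count.
#' @examples
#' expectedHomozygotesFreq(3763, 28085)  # 126.05
#' @export
expectedHomozygotesFreq <- function(C, N, nHom = 0L) {
    stopifnot(C >= 0, N >= 1, C + nHom <= N)
    f <- (C + 2 * nHom) / (2 * N)
    N * f^2
}

#' Expected haplotype homozygotes from parental (trio) information
#'
#' Sums Mendelian transmission probabilities over genotyped offspring:
#' a heterozygous-carrier parent transmits the haplotype with probability
#' 0.5, a known non-carrier with probability 0. In the default mode only
#' offspring of two carrier parents are counted, each contributing
#' 0.25; the extended mode additionally counts offspring with one carrier
#' parent and one parent of unknown status, the latter transmitting at the
#' population haplotype frequency `hapFreq`.
#'
#' @param pedigree `data.frame` with `id`, `sire`, `dam` columns.
#' @param carrierStatus named logical vector: `TRUE` carrier, `FALSE`
#'   non-carrier; animals absent from the vector have unknown status.
#' @param genotypedOffspring identifiers of offspring with genotypes.
#' @param mode `"cxc"` (default) or `"extended"`.
#' @param hapFreq population haplotype frequency, used for unknown-status
#'   parents in extended mode.
#' @return expected homozygote count, with attributes `nCxC` (genotyped
#'   carrier-x-carrier offspring) and `nExcluded` (offspring with an
#'   unrecorded parent).
#' @examples
#' ped <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                   dam = c(NA, NA, "d"))
#' expectedHomozygotesTrio(ped, c(s = TRUE, d = TRUE), "o")  # 0.25
#' @export
expectedHomozygotesTrio <- function(pedigree, carrierStatus,
                                    genotypedOffspring,
                                    mode = c("cxc", "extended"),
                                    hapFreq = NA_real_) {
    mode <- match.arg(mode)
    rows <- pedigree[match(genotypedOffspring, pedigree$id), , drop = FALSE]
    known <- !is.na(rows$sire) & !is.na(rows$dam)
    nExcluded <- sum(!known)
    rows <- rows[known, , drop = FALSE]
    transm <- function(parent) {
        status <- carrierStatus[parent]
        p <- ifelse(is.na(status), NA_real_, ifelse(status, 0.5, 0))
        if (mode == "extended") p[is.na(p)] <- hapFreq
        p
    }
    ps <- transm(rows$sire); pd <- transm(rows$dam)
    contrib <- ps * pd
    if (mode == "cxc") contrib[is.na(contrib)] <- 0
    expected <- sum(contrib, na.rm = TRUE)
    structure(expected,
              nCxC = sum(!is.na(ps) & !is.na(pd) & ps == 0.5 & pd == 0.5),
              nExcluded = nExcluded)
}

#' One-sided exact binomial deficit test
#'
#' Lower-tail probability `P(X <= observed)` for
#' `X ~ Binomial(n, p)` — the probability of seeing as few or fewer
#' homozygotes than observed if the haplotype were harmless. The scan
#' applies it with `n = N, p = f^2` (Hardy-Weinberg parameterization) and,
#' when trio data exist, with `n` the genotyped carrier-x-carrier progeny
#' and `p = 0.25`.
#'
#' @param observed observed homozygote count.
#' @param n number of trials.
#' @param p homozygote probability per trial.
#' @return exact lower-tail p-value.
#' @examples
#' deficitTest(0, 38, 0.25)  # 0.75^38
#' @export
deficitTest <- function(observed, n, p) {
    stopifnot(observed >= 0, observed <= n, p >= 0, p <= 1)
    pbinom(observed, n, p)
}

## Encode one haploid matrix (markers x animals) as per-animal character
## strings, "N" marking missing calls, so window haplotypes are substrings.
.hapStrings <- function(m) {
    ch <- matrix("N", nrow(m), ncol(m))
    ch[!is.na(m) & m == 0L] <- "0"
    ch[!is.na(m) & m == 1L] <- "1"
    apply(ch, 2L, paste, collapse = "")
}

#' Enumerate haplotypes in one genomic window
#'
#' Haplotype identity is exact allele-vector match over the window
#' markers; an animal missing any call in the window is excluded from the
#' window's counts (both haploids).
#'
#' @param genotypes a phased [PhasedGenotypes-class] object.
#' @param chrom chromosome name.
#' @param startBp,endBp window bounds (1-based, inclusive).
#' @return `data.frame` with one row per distinct haplotype: `haplotype`
#'   (character of 0/1), `count` (haploid copies), `nHom` (animals
#'   homozygous for it), `freq`, and a list-column `carriers` of animal
#'   identifiers carrying at least one copy. Attribute `nGenotyped` gives
#'   the number of animals counted. Windows with fewer than two markers
#'   are skipped with a warning (zero-row result).
#' @export
enumerateWindowHaplotypes <- function(genotypes, chrom, startBp, endBp) {
    pos <- start(rowRanges(genotypes))
    sel <- which(as.character(seqnames(rowRanges(genotypes))) == chrom &
                 pos >= startBp & pos <= endBp)
    empty <- data.frame(haplotype = character(0), count = integer(0),
                        nHom = integer(0), freq = numeric(0))
    empty$carriers <- list()
    if (length(sel) < 2L) {
        warning("window ", chrom, ":", startBp, "-", endBp,
                " contains fewer than 2 markers; skipped")
        return(empty)
    }
    s1 <- .hapStrings(assay(genotypes, "hap1")[sel, , drop = FALSE])
    s2 <- .hapStrings(assay(genotypes, "hap2")[sel, , drop = FALSE])
    ok <- !grepl("N", s1, fixed = TRUE) & !grepl("N", s2, fixed = TRUE)
    if (!any(ok)) return(structure(empty, nGenotyped = 0L))
    s1 <- s1[ok]; s2 <- s2[ok]
    ids <- animalIds(genotypes)[ok]
    counts <- table(c(s1, s2))
    haps <- names(counts)
    nHom <- vapply(haps, function(h) sum(s1 == h & s2 == h), integer(1L))
    carriers <- lapply(haps, function(h) sort(ids[s1 == h | s2 == h]))
    out <- data.frame(haplotype = haps, count = as.integer(counts),
                      nHom = nHom, freq = as.integer(counts) / (2 * sum(ok)),
                      row.names = NULL)
    out$carriers <- carriers
    structure(out, nGenotyped = sum(ok))
}

## window start coordinates for one size over the marker span
.windowStarts <- function(minPos, maxPos, sizeBp, stepFraction) {
    step <- sizeBp * stepFraction
    first <- floor((minPos - 1) / step) * step
    starts <- seq(first, max(first, maxPos - 1), by = step)
    starts[starts + sizeBp >= minPos]
}

#' Scan phased genotypes for haplotypes with missing or deficit homozygosity
#'
#' Slides windows of the configured sizes (half-overlapping by default)
#' along each chromosome; within each window every haplotype above the
#' frequency floor is tested for a deficit of homozygotes by the exact
#' binomial test against its Hardy-Weinberg expectation. Significant
#' window-haplotypes whose spans intersect and whose carrier sets overlap
#' strongly (Jaccard >= 0.8) are merged into one candidate, represented by
#' its most significant window. When a pedigree is supplied each candidate
#' additionally reports the trio-based expectation (0.25 per genotyped
#' carrier-x-carrier offspring), the corresponding exact binomial
#' p-value, and the heterozygote fraction among those offspring.
#'
#' @param genotypes a phased, QC-filtered [PhasedGenotypes-class] object.
#' @param pedigree optional pedigree `data.frame` (`id`, `sire`, `dam`).
#' @param windows a [WindowSpec-class] object.
#' @return list of [CandidateHaplotype-class] objects ordered by
#'   significance, with attributes `nTests` (number of haplotype-window
#'   pairs evaluated) and `bonferroniAlpha` (`alpha / nTests`, advisory).
#' @export
scanHaplotypes <- function(genotypes, pedigree = NULL,
                           windows = windowSpec()) {
    stopifnot(is(genotypes, "PhasedGenotypes"), is(windows, "WindowSpec"))
    if (!isPhased(genotypes))
        stop("scan requires phased genotypes")
    validObject(windows)
    ids <- animalIds(genotypes)
    rr <- rowRanges(genotypes)
    chroms <- unique(as.character(seqnames(rr)))
    nTests <- 0L
    hits <- list()

    for (chrom in chroms) {
        onChr <- which(as.character(seqnames(rr)) == chrom)
        pos <- start(rr)[onChr]
        s1 <- .hapStrings(assay(genotypes, "hap1")[onChr, , drop = FALSE])
        s2 <- .hapStrings(assay(genotypes, "hap2")[onChr, , drop = FALSE])
        for (size in windows@sizesBp) {
            for (ws in .windowStarts(min(pos), max(pos), size,
                                     windows@stepFraction)) {
                we <- ws + size
                sel <- which(pos > ws & pos <= we)
                if (length(sel) < 2L) next
                i <- sel[1L]; j <- sel[length(sel)]
                w1 <- substr(s1, i, j); w2 <- substr(s2, i, j)
                ok <- !grepl("N", w1, fixed = TRUE) &
                      !grepl("N", w2, fixed = TRUE)
                N <- sum(ok)
                if (N == 0L) next
                counts <- table(c(w1[ok], w2[ok]))
                freq <- as.integer(counts) / (2 * N)
                test <- freq > windows@minHapFreq
                nTests <- nTests + sum(test)
                for (k in which(test)) {
                    key <- names(counts)[k]
                    hom <- ok & w1 == key & w2 == key
                    O <- sum(hom)
                    f <- freq[k]
                    p <- pbinom(O, N, f^2)
                    if (p >= windows@alpha) next
                    carrier <- ok & (w1 == key | w2 == key)
                    C <- sum(carrier) - O
                    hits[[length(hits) + 1L]] <- list(
                        chrom = chrom, startBp = ws + 1, endBp = we,
                        alleles = as.integer(strsplit(key, "")[[1L]]),
                        N = N, C = C, O = O, f = f,
                        Ef = N * f^2, p = p,
                        carriers = sort(ids[carrier]))
                }
            }
        }
    }

    cands <- .mergeHits(hits)
    cands <- lapply(cands, .extendAcrossSpan, genotypes = genotypes)
    out <- lapply(cands, .asCandidate, genotypes = genotypes,
                  pedigree = pedigree)
    out <- out[order(vapply(out, function(x) x@pDeficit, numeric(1L)))]
    structure(out, nTests = nTests,
              bonferroniAlpha = if (nTests > 0) windows@alpha / nTests
                                else NA_real_)
}

## Merge significant window-haplotypes into candidates: connected
## components of the graph joining hits with intersecting spans and
## carrier-set overlap coefficient (intersection over the smaller set)
## >= 0.8. The overlap coefficient, rather than the Jaccard index, keeps
## nested windows of the same lethal haplotype together: a short window
## inside the haplotype picks up coincidental exact-match carriers that
## dilute a Jaccard comparison against the full-length window.
.mergeHits <- function(hits, overlapMin = 0.8) {
    n <- length(hits)
    if (n == 0L) return(list())
    comp <- seq_len(n)
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        ha <- hits[[a]]; hb <- hits[[b]]
        if (ha$chrom != hb$chrom) next
        if (ha$startBp > hb$endBp || hb$startBp > ha$endBp) next
        inter <- length(intersect(ha$carriers, hb$carriers))
        small <- min(length(ha$carriers), length(hb$carriers))
        if (small == 0L || inter / small < overlapMin) next
        old <- comp[b]; comp[comp == old] <- comp[a]
    }
    lapply(unique(comp), function(cc) {
        members <- hits[comp == cc]
        rep <- members[[which.min(vapply(members, `[[`, numeric(1L), "p"))]]
        rep$spanStartBp <- min(vapply(members, `[[`, numeric(1L), "startBp"))
        rep$spanEndBp <- max(vapply(members, `[[`, numeric(1L), "endBp"))
        rep
    })
}

## Extend a merged hit's haplotype across the union span of its component
## windows. The carrier-defining haploids of the representative window are
## followed outwards and their consensus allele vector over the union span
## becomes the candidate haplotype; counts and the deficit test are then
## recomputed for that full-length haplotype. The longer vector is far
## more specific than any single window, so coincidental exact-match
## carriers drop out.
.extendAcrossSpan <- function(hit, genotypes, agreementMin = 0.9) {
    if (hit$spanStartBp >= hit$startBp && hit$spanEndBp <= hit$endBp) {
        hit$spanStartBp <- hit$spanEndBp <- NULL
        return(hit)
    }
    rr <- rowRanges(genotypes)
    pos <- start(rr)
    onChr <- as.character(seqnames(rr)) == hit$chrom
    selRep <- which(onChr & pos >= hit$startBp & pos <= hit$endBp)
    selAll <- which(onChr & pos >= hit$spanStartBp & pos <= hit$spanEndBp)
    h1 <- assay(genotypes, "hap1")[selAll, , drop = FALSE]
    h2 <- assay(genotypes, "hap2")[selAll, , drop = FALSE]
    inRep <- selAll %in% selRep
    m1 <- colSums(h1[inRep, , drop = FALSE] == hit$alleles) == sum(inRep)
    m2 <- colSums(h2[inRep, , drop = FALSE] == hit$alleles) == sum(inRep)
    m1[is.na(m1)] <- FALSE; m2[is.na(m2)] <- FALSE
    ext <- cbind(h1[, m1, drop = FALSE], h2[, m2, drop = FALSE])
    keep <- !apply(is.na(ext), 2L, any)
    ext <- ext[, keep, drop = FALSE]
    if (ncol(ext) == 0L) {         # nothing to extend from; keep window
        hit$spanStartBp <- hit$spanEndBp <- NULL
        return(hit)
    }
    ## per-marker consensus among the carrier-defining haploids; the shared
    ## haplotype ends where the haploids stop agreeing (the random flank),
    ## so trim the span to the contiguous high-agreement run containing
    ## the representative window
    consensus <- as.integer(rowMeans(ext) >= 0.5)
    agree <- rowMeans(ext == consensus)
    good <- agree >= agreementMin
    repIdx <- which(inRep)
    lo <- repIdx[1L]; hi <- repIdx[length(repIdx)]
    while (lo > 1L && good[lo - 1L]) lo <- lo - 1L
    while (hi < length(good) && good[hi + 1L]) hi <- hi + 1L
    use <- lo:hi
    key <- paste(consensus[use], collapse = "")
    s1 <- .hapStrings(h1[use, , drop = FALSE])
    s2 <- .hapStrings(h2[use, , drop = FALSE])
    ok <- !grepl("N", s1, fixed = TRUE) & !grepl("N", s2, fixed = TRUE)
    N <- sum(ok)
    hom <- ok & s1 == key & s2 == key
    carrier <- ok & (s1 == key | s2 == key)
    O <- sum(hom)
    k <- sum(s1[ok] == key) + sum(s2[ok] == key)
    f <- k / (2 * N)
    usePos <- pos[selAll][use]
    list(chrom = hit$chrom,
         startBp = min(hit$startBp, usePos[1L]),
         endBp = max(hit$endBp, usePos[length(usePos)]),
         alleles = consensus[use],
         N = N, C = sum(carrier) - O, O = O, f = f, Ef = N * f^2,
         p = pbinom(O, N, f^2),
         carriers = sort(animalIds(genotypes)[carrier]))
}

.asCandidate <- function(hit, genotypes, pedigree) {
    expTrio <- NA_real_; pTrio <- NA_real_
    nCxC <- NA_integer_; nHet <- NA_integer_
    if (!is.null(pedigree)) {
        status <- setNames(rep(FALSE, nAnimals(genotypes)),
                           animalIds(genotypes))
        status[hit$carriers] <- TRUE
        et <- expectedHomozygotesTrio(pedigree, status,
                                      animalIds(genotypes))
        expTrio <- as.numeric(et)
        nCxC <- attr(et, "nCxC")
        if (nCxC > 0L) {
            rows <- pedigree[match(animalIds(genotypes), pedigree$id), ]
            isCxC <- !is.na(rows$sire) & !is.na(rows$dam) &
                rows$sire %in% hit$carriers & rows$dam %in% hit$carriers
            cxcIds <- animalIds(genotypes)[isCxC]
            dos <- .haplotypeDosageIdx(genotypes, hit)
            dCxC <- dos[cxcIds]
            dCxC <- dCxC[!is.na(dCxC)]
            nHet <- sum(dCxC == 1L)
            pTrio <- pbinom(sum(dCxC == 2L), length(dCxC), 0.25)
        }
    }
    new("CandidateHaplotype",
        chrom = hit$chrom, startBp = hit$startBp, endBp = hit$endBp,
        alleles = hit$alleles, nGenotyped = as.integer(hit$N),
        nCarriers = as.integer(hit$C), nHomObs = as.integer(hit$O),
        hapFreq = hit$f, expectedFreq = hit$Ef,
        expectedTrio = expTrio, pDeficit = hit$p, pTrio = pTrio,
        nCxCProgeny = if (is.na(nCxC)) NA_integer_ else as.integer(nCxC),
        nHetProgeny = nHet, carrierIds = hit$carriers)
}

## haplotype dosage for a hit/candidate given as list or CandidateHaplotype
.haplotypeDosageIdx <- function(genotypes, hit) {
    rr <- rowRanges(genotypes)
    pos <- start(rr)
    sel <- which(as.character(seqnames(rr)) == hit$chrom &
                 pos >= hit$startBp & pos <= hit$endBp)
    stopifnot(length(sel) == length(hit$alleles))
    h1 <- assay(genotypes, "hap1")[sel, , drop = FALSE]
    h2 <- assay(genotypes, "hap2")[sel, , drop = FALSE]
    m1 <- colSums(h1 == hit$alleles) == length(sel)
    m2 <- colSums(h2 == hit$alleles) == length(sel)
    d <- as.integer(m1) + as.integer(m2)
    d[is.na(m1) | is.na(m2)] <- NA_integer_
    setNames(d, animalIds(genotypes))
}
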