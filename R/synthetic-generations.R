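#' Form one gamete by meiosis with Poisson-distributed crossovers
#'
#' Crossover count ~ Poisson(recombRate x chromosome length in Mb),
#' breakpoints uniform on the chromosome; the starting haploid is chosen at
#' random. Returns marker alleles plus the lethal allele of the haploid
#' contributing at the lethal position (the lethal rides the segment that
#' contains it).
#' @keywords internal
.gamete <- function(h1, h2, lethal1, lethal2, positions, lethalPos, config) {
    lenMb <- config@chromLengthBp / 1e6
    nX <- rpois(1L, config@recombRate * lenMb)
    startSide <- sample(c(1L, 2L), 1L)
    if (nX == 0L) {
        if (startSide == 1L) return(list(alleles = h1, lethal = lethal1))
        return(list(alleles = h2, lethal = lethal2))
    }
    breaks <- sort(runif(nX, 0, config@chromLengthBp))
    sideAt <- function(x) {
        flips <- findInterval(x, breaks)
        ifelse((flips %% 2L) == 0L, startSide, 3L - startSide)
    }
    side <- sideAt(positions)
    alleles <- as.integer(ifelse(side == 1L, h1, h2))
    lethal <- if (sideAt(lethalPos) == 1L) lethal1 else lethal2
    list(alleles = alleles, lethal = lethal)
}

#' Simulate breeding generations with litter records and pedigree
#'
#' Advances the founder population `nGenerations` generations. Each
#' generation every sow is mated to one random boar; litters follow the
#' [litterModel()] zygote process but with full gametes (Poisson crossovers
#' at uniform positions), so offspring genotypes are phased by construction
#' (parental origin known) and the lethal allele is transmitted with the
#' chromosome segment carrying it. Homozygous-lethal zygotes die before
#' implantation, so no surviving animal is ever a lethal homozygote.
#' Roughly half of the boars and half of the sows are replaced each
#' generation by randomly chosen surviving offspring of matching sex;
#' replacements are genotyped and enter the pedigree, emulating a nucleus
#' population in which breeding animals are genotyped but commercial
#' offspring are not.
#'
#' @param founders [PhasedGenotypes-class] from [simulateFounders()],
#'   optionally with a lethal from [plantLethal()]. The RNG state is taken
#'   as-is (seed it, or call directly after the seeded founder/plant steps).
#' @param config a [SimConfig-class] object.
#' @return list with `genotypes` (founders plus all replacement animals),
#'   `pedigree` (`data.frame`: `id`, `sire`, `dam`, `sex`, `birthdate`;
#'   founder parents are `NA`) and `litters` (`data.frame` of litter
#'   records: `sire`, `dam`, `date`, `TNB`, `NBA`, `NSB`, `MUM`,
#'   `generation`).
#' @export
simulateGenerations <- function(founders, config) {
    stopifnot(is(founders, "PhasedGenotypes"), is(config, "SimConfig"))
    positions <- start(rowRanges(founders))
    lethalPos <- config@lethalPositionBp
    s <- .survivalProb(config)

    ids <- animalIds(founders)
    sex <- founders$sex
    hap1 <- lapply(seq_len(ncol(founders)), function(i)
        assay(founders, "hap1")[, i])
    hap2 <- lapply(seq_len(ncol(founders)), function(i)
        assay(founders, "hap2")[, i])
    l1 <- founders$lethal1; l2 <- founders$lethal2
    gen <- founders$generation
    sire <- rep(NA_character_, length(ids))
    dam <- rep(NA_character_, length(ids))
    birth <- rep(as.Date("2012-01-01"), length(ids))

    boars <- which(sex == "M"); sows <- which(sex == "F")
    litters <- vector("list", 0L)

    for (g in seq_len(config@nGenerations)) {
        date <- as.Date("2012-01-01") + 182L * g
        offspring <- list()
        for (d in sows) {
            b <- boars[sample.int(length(boars), 1L)]
            nOv <- rpois(1L, config@ovulationMean)
            alive <- list()
            for (z in seq_len(nOv)) {
                gs <- .gamete(hap1[[b]], hap2[[b]], l1[b], l2[b],
                              positions, lethalPos, config)
                gd <- .gamete(hap1[[d]], hap2[[d]], l1[d], l2[d],
                              positions, lethalPos, config)
                if (gs$lethal + gd$lethal == 2L) next  # dies pre-implantation
                alive[[length(alive) + 1L]] <- list(gs = gs, gd = gd)
            }
            nImplanted <- min(length(alive), config@uterineCapacity)
            implanted <- alive[seq_len(nImplanted)]
            keep <- implanted[runif(nImplanted) <= s]
            tnb <- length(keep)
            nsb <- rbinom(1L, tnb, config@nsbRate)
            litters[[length(litters) + 1L]] <- data.frame(
                sire = ids[b], dam = ids[d], date = date,
                TNB = tnb, NBA = tnb - nsb, NSB = nsb,
                MUM = rbinom(1L, tnb, config@mumRate), generation = g,
                stringsAsFactors = FALSE)
            for (p in keep)
                offspring[[length(offspring) + 1L]] <-
                    list(sire = ids[b], dam = ids[d],
                         h1 = p$gs$alleles, h2 = p$gd$alleles,
                         l1 = p$gs$lethal, l2 = p$gd$lethal,
                         sex = sample(c("M", "F"), 1L))
        }
        if (!length(offspring))
            stop("population extinct at generation ", g)
        offSex <- vapply(offspring, `[[`, character(1L), "sex")
        used <- logical(length(offspring))

        registerReplacements <- function(slots, wantSex) {
            nRep <- floor(length(slots) / 2)
            avail <- which(offSex == wantSex & !used)
            nRep <- min(nRep, length(avail))
            if (nRep == 0L) return(slots)
            pick <- avail[sample.int(length(avail), nRep)]
            used[pick] <<- TRUE
            vacate <- sample.int(length(slots), nRep)
            for (j in seq_len(nRep)) {
                o <- offspring[[pick[j]]]
                newIdx <- length(ids) + 1L
                ids[newIdx] <<- sprintf("G%d_%05d", g, newIdx)
                hap1[[newIdx]] <<- o$h1; hap2[[newIdx]] <<- o$h2
                l1[newIdx] <<- o$l1; l2[newIdx] <<- o$l2
                sex[newIdx] <<- wantSex; gen[newIdx] <<- g
                sire[newIdx] <<- o$sire; dam[newIdx] <<- o$dam
                birth[newIdx] <<- date
                slots[vacate[j]] <- newIdx
            }
            slots
        }
        boars <- registerReplacements(boars, "M")
        sows <- registerReplacements(sows, "F")
    }

    h1 <- do.call(cbind, hap1); h2 <- do.call(cbind, hap2)
    colnames(h1) <- colnames(h2) <- ids
    cd <- DataFrame(sex = sex, generation = gen, lethal1 = l1, lethal2 = l2)
    gt <- PhasedGenotypes(h1, h2, rowRanges(founders), ids,
                          phased = TRUE, colData = cd)
    metadata(gt)$lethal <- metadata(founders)$lethal
    ped <- data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                      birthdate = birth, stringsAsFactors = FALSE)
    list(genotypes = gt, pedigree = ped, litters = do.call(rbind, litters))
}

#' Validate a pedigree
#'
#' Checks that the pedigree is acyclic, that every non-founder's parents
#' are themselves recorded, and that parents predate their offspring.
#'
#' @param pedigree `data.frame` with columns `id`, `sire`, `dam`, `sex`,
#'   `birthdate`.
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validatePedigree <- function(pedigree) {
    stopifnot(all(c("id", "sire", "dam", "sex", "birthdate") %in%
                  colnames(pedigree)))
    if (anyDuplicated(pedigree$id))
        stop("duplicated animal identifiers")
    known <- pedigree$id
    parents <- c(pedigree$sire, pedigree$dam)
    missing <- setdiff(parents[!is.na(parents)], known)
    if (length(missing))
        stop("parents absent from pedigree: ",
             paste(head(missing, 5), collapse = ", "))
    bd <- setNames(pedigree$birthdate, pedigree$id)
    for (col in c("sire", "dam")) {
        p <- pedigree[[col]]
        has <- !is.na(p)
        if (any(bd[p[has]] >= pedigree$birthdate[has]))
            stop("some parents do not predate their offspring")
    }
    ## birthdate ordering + parents-predate-offspring implies acyclicity
    invisible(TRUE)
}
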