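#' Write phased genotypes to VCF
#'
#' Emits a minimal VCF 4.2 with `##contig` headers and phased `GT` calls
#' (`0|1`; missing sites as `.|.`). Unphased objects are written with `/`
#' separators.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writePhasedVCF <- function(genotypes, path) {
    stopifnot(is(genotypes, "PhasedGenotypes"))
    rr <- rowRanges(genotypes)
    chr <- as.character(seqnames(rr))
    sepc <- if (isPhased(genotypes)) "|" else "/"
    h1 <- assay(genotypes, "hap1"); h2 <- assay(genotypes, "hap2")
    gt <- matrix(paste(h1, h2, sep = sepc), nrow = nrow(h1))
    gt[is.na(h1)] <- paste(".", ".", sep = sepc)
    contigs <- vapply(split(end(rr), chr), max, numeric(1L))
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                        as.integer(contigs)),
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", animalIds(genotypes)),
                      collapse = "\t"))
    body <- paste(chr, start(rr), names(rr), mcols(rr)$ref, mcols(rr)$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read phased genotypes from VCF
#'
#' Parses with `vcfR`; the `phased` flag is taken from the separator of
#' the first genotype call.
#'
#' @param path VCF path (plain or gzipped).
#' @return a [PhasedGenotypes-class] object.
#' @export
readPhasedVCF <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    phased <- grepl("|", gt[!is.na(gt)][1L], fixed = TRUE)
    a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
    h1 <- matrix(a1, nrow = nrow(gt), dimnames = dimnames(gt))
    h2 <- matrix(a2, nrow = nrow(gt), dimnames = dimnames(gt))
    fix <- vcfR::getFIX(v)
    gr <- GRanges(fix[, "CHROM"],
                  IRanges(as.integer(fix[, "POS"]), width = 1L))
    mcols(gr)$ref <- fix[, "REF"]; mcols(gr)$alt <- fix[, "ALT"]
    names(gr) <- fix[, "ID"]
    PhasedGenotypes(h1, h2, gr, colnames(gt), phased = phased)
}

#' Write an annotated variant panel to VCF
#'
#' Consequence classes go into the INFO field as `CLASS=<class>`, with
#' `DELETERIOUS` as a flag; per-animal dosages are written as unphased
#' genotypes.
#'
#' @param panel a [VariantPanel-class] object.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writeVariantVCF <- function(panel, path) {
    stopifnot(is(panel, "VariantPanel"))
    rr <- rowRanges(panel)
    chr <- as.character(seqnames(rr))
    d <- variantDosage(panel)
    gtOf <- c("0/0", "0/1", "1/1")
    gt <- matrix(gtOf[d + 1L], nrow = nrow(d))
    gt[is.na(d)] <- "./."
    del <- mcols(rr)$deleterious %in% TRUE
    info <- paste0("CLASS=", mcols(rr)$class,
                   ifelse(del, ";DELETERIOUS", ""))
    contigs <- vapply(split(end(rr), chr), max, numeric(1L))
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                        as.integer(contigs)),
                "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
                "##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description=\"Predicted deleterious\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(panel)),
                      collapse = "\t"))
    body <- paste(chr, start(rr), names(rr), mcols(rr)$ref, mcols(rr)$alt,
                  ".", "PASS", info, "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read an annotated variant panel from VCF
#'
#' Expects a `CLASS=` INFO key (consequence class) and an optional
#' `DELETERIOUS` flag; genotypes are converted to dosages.
#'
#' @param path VCF path.
#' @return a [VariantPanel-class] object.
#' @export
readVariantVCF <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
    d <- matrix(a1 + a2, nrow = nrow(gt), dimnames = dimnames(gt))
    fix <- vcfR::getFIX(v)
    info <- v@fix[, "INFO"]
    cls <- sub(".*CLASS=([^;]+).*", "\\1", info)
    gr <- GRanges(fix[, "CHROM"],
                  IRanges(as.integer(fix[, "POS"]), width = 1L))
    mcols(gr)$ref <- fix[, "REF"]; mcols(gr)$alt <- fix[, "ALT"]
    mcols(gr)$class <- cls
    mcols(gr)$deleterious <- grepl("DELETERIOUS", info, fixed = TRUE)
    names(gr) <- fix[, "ID"]
    VariantPanel(d, gr, animalIds = colnames(gt))
}

#' Write / read pedigree TSV
#'
#' Columns `id`, `sire`, `dam`, `sex`, `birthdate`; founders have empty
#' parent fields.
#'
#' @param pedigree pedigree `data.frame`.
#' @param path file path.
#' @return `writePedigree` invisibly returns `path`; `readPedigree`
#'   returns the pedigree `data.frame`.
#' @export
writePedigree <- function(pedigree, path) {
    write.table(pedigree, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(path) {
    ped <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    ped$birthdate <- as.Date(ped$birthdate)
    ped
}

#' Write / read litter records CSV
#'
#' Columns `sire`, `dam`, `date`, `TNB`, `NBA`, `NSB`, `MUM`.
#'
#' @param litters litter `data.frame`.
#' @param path file path.
#' @return `writeLitters` invisibly returns `path`; `readLitters` returns
#'   the litter `data.frame`.
#' @export
writeLitters <- function(litters, path) {
    utils::write.csv(litters, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeLitters
#' @export
readLitters <- function(path) {
    l <- utils::read.csv(path, stringsAsFactors = FALSE)
    l$date <- as.Date(l$date)
    l
}
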