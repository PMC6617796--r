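#' Construct a GenotypeMatrix
#'
#' Builds the container from a set of width-1 variant sites and an
#' integer matrix of genotype classes.  Most users will obtain one from
#' [readVCF()] or [simulateCohort()] instead.
#'
#' @param sites `GRanges` of variant positions (width 1), ordered by
#'   position within each chromosome; an optional metadata column `id`
#'   carries variant identifiers.
#' @param calls integer matrix, `length(sites)` rows, one column per
#'   sample (`0` = HOM, `1` = HET, `NA` = missing).  Column names are the
#'   sample identifiers.
#' @param dosage optional integer matrix of ALT allele counts (0/1/2,
#'   `NA` = missing), same shape as `calls`; retained as a second assay
#'   and used by [writeVCF()].
#' @return a [GenotypeMatrix-class].
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' gm <- GenotypeMatrix(sites, matrix(c(0L, 1L), ncol = 1,
#'                                    dimnames = list(NULL, "s1")))
#' genotypeCalls(gm)
#' @export
GenotypeMatrix <- function(sites, calls, dosage = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("sample", seq_len(ncol(calls)))
    assays <- list(calls = calls)
    if (!is.null(dosage)) {
        dosage <- as.matrix(dosage)
        storage.mode(dosage) <- "integer"
        colnames(dosage) <- colnames(calls)
        assays$dosage <- dosage
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = sites)
    new("GenotypeMatrix", se)
}

#' Classify VCF genotypes as HOM, HET or MISSING
#'
#' Applies the heterozygous/homozygous dichotomy to parsed `GT` fields:
#' any two distinct allele indices (including two different ALT alleles,
#' e.g. `"1/2"`) count as heterozygous; a genotype with any missing allele
#' (`"./."`, `"./1"`, `"."`) is missing; identical alleles are homozygous.
#' Phase separators (`|` vs `/`) and allele order are irrelevant.  Haploid
#' calls carry a single allele and can never be heterozygous, so a
#' non-missing haploid genotype classifies as HOM.
#'
#' @param gt character vector of VCF `GT` strings.
#' @param codes if `TRUE` return integer codes (`0` HOM, `1` HET, `NA`
#'   missing) instead of labels.
#' @return character vector in `c("HOM", "HET", "MISSING")`, or integer
#'   codes.
#' @examples
#' classifyGenotype(c("0/0", "0|1", "1/2", "./.", "./1"))
#' @export
classifyGenotype <- function(gt, codes = FALSE) {
    gt <- as.character(gt)
    u <- unique(gt)
    ucode <- .classifyGT(u)
    code <- ucode[match(gt, u)]
    if (codes) return(unname(code))
    out <- rep("MISSING", length(code))
    out[!is.na(code)] <- c("HOM", "HET")[code[!is.na(code)] + 1L]
    out
}

## Classify a vector of *unique* GT strings into integer codes.
.classifyGT <- function(u) {
    ok <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))*$", u)
    if (!all(ok))
        stop("malformed GT field: '", u[!ok][1L], "'", call. = FALSE)
    parts <- strsplit(u, "[/|]", fixed = FALSE)
    vapply(parts, function(a) {
        if (any(a == ".")) return(NA_integer_)
        if (length(unique(a)) > 1L) .GT_HET else .GT_HOM
    }, integer(1))
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Reads `CHROM`, `POS`, `ID` and the `GT` genotype field of a VCF 4.x
#' file (plain or bgzipped) and classifies every genotype with
#' [classifyGenotype()].  Multi-allelic records are kept as single sites;
#' duplicate `(chrom, pos)` records are both retained in file order.  No
#' allele-frequency or quality filtering is applied: robustness to allele
#' frequency is intrinsic to the moving-average statistic.
#'
#' @param path VCF file.
#' @param samples optional character vector restricting to these samples
#'   (must exist in the header).
#' @param passOnly if `TRUE`, keep only records whose `FILTER` is `PASS`
#'   or `.` (default off).
#' @return a [GenotypeMatrix-class]; sites on sex chromosomes are scanned
#'   like autosomes but flagged by the object's `show()` method.
#' @export
readVCF <- function(path, samples = NULL, passOnly = FALSE) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    hdr <- VariantAnnotation::scanVcfHeader(path)
    avail <- VariantAnnotation::samples(hdr)
    if (!is.null(samples)) {
        bad <- setdiff(samples, avail)
        if (length(bad))
            stop("unknown sample(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(avail, collapse = ", "),
                 call. = FALSE)
        param <- VariantAnnotation::ScanVcfParam(info = NA, geno = "GT",
                                                 samples = samples)
    } else {
        param <- VariantAnnotation::ScanVcfParam(info = NA, geno = "GT")
    }
    vcf <- suppressWarnings(
        VariantAnnotation::readVcf(path, genome = "unknown", param = param))
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (passOnly && length(vcf)) {
        keep <- VariantAnnotation::filt(vcf) %in% c("PASS", ".")
        vcf <- vcf[keep]
        rr <- rr[keep]
    }
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    if (length(pos)) {
        r <- rle(chrom)
        if (anyDuplicated(r$values))
            stop("VCF records are not grouped by chromosome; ",
                 "sort the file (e.g. bcftools sort) and retry",
                 call. = FALSE)
        unsorted <- unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                                  function(p) any(diff(p) < 0)),
                           use.names = FALSE)
        if (any(unsorted))
            stop("VCF records are not position-sorted within chromosome; ",
                 "sort the file (e.g. bcftools sort) and retry",
                 call. = FALSE)
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        gt <- matrix(character(0), nrow = length(rr), ncol = 0)
    code <- tryCatch(classifyGenotype(as.vector(gt), codes = TRUE),
                     error = function(e) {
                         bad <- .firstBadGT(gt)
                         stop(conditionMessage(e), " at site ",
                              chrom[bad[1L]], ":", pos[bad[1L]],
                              ", sample ", colnames(gt)[bad[2L]],
                              call. = FALSE)
                     })
    calls <- matrix(code, nrow = nrow(gt), ncol = ncol(gt),
                    dimnames = list(NULL, colnames(gt)))
    sites <- GRanges(chrom, IRanges(pos, width = 1L))
    id <- names(rr)
    if (!is.null(id))
        mcols(sites)$id <- unname(id)
    GenotypeMatrix(sites, calls)
}

.firstBadGT <- function(gt) {
    ok <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))*$", gt)
    i <- which(!ok)[1L]
    c((i - 1L) %% nrow(gt) + 1L, (i - 1L) %/% nrow(gt) + 1L)
}

#' Write a GenotypeMatrix as minimal VCF 4.2
#'
#' Emits a GT-only VCF.  When the object carries a `"dosage"` assay (as
#' produced by [simulateCohort()]) genotypes are written at allele level
#' (`0/0`, `0/1`, `1/1`); otherwise the genotype class is encoded as
#' `0/0` (HOM), `0/1` (HET) or `./.` (missing), which round-trips the
#' class matrix exactly.  REF/ALT alleles are taken from `ref`/`alt`
#' metadata columns of the sites when present, else written as `A`/`C`
#' placeholders.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(x, path) {
    rr <- rowRanges(x)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    mc <- mcols(rr)
    id <- if ("id" %in% colnames(mc)) as.character(mc$id) else
        rep(".", length(rr))
    id[is.na(id) | id == ""] <- "."
    ref <- if ("ref" %in% colnames(mc)) as.character(mc$ref) else
        rep("A", length(rr))
    alt <- if ("alt" %in% colnames(mc)) as.character(mc$alt) else
        rep("C", length(rr))
    if ("dosage" %in% assayNames(x)) {
        dos <- assay(x, "dosage")
        gtmap <- c("0/0", "0/1", "1/1")
        gt <- matrix("./.", nrow(dos), ncol(dos))
        ok <- !is.na(dos)
        gt[ok] <- gtmap[dos[ok] + 1L]
    } else {
        cl <- assay(x, "calls")
        gt <- matrix("./.", nrow(cl), ncol(cl))
        gt[!is.na(cl) & cl == .GT_HOM] <- "0/0"
        gt[!is.na(cl) & cl == .GT_HET] <- "0/1"
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##source=HetScan-%s",
                         as.character(utils::packageVersion("HetScan"))),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 sprintf("##contig=<ID=%s>", unique(chrom)),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(x)),
                       collapse = "\t")), con)
    if (length(rr)) {
        body <- cbind(chrom, pos, id, ref, alt, ".", ".", ".", "GT", gt)
        writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    }
    invisible(path)
}
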