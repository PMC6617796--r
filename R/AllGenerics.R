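#' @include AllClasses.R
NULL

#' Extract the genotype-class matrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix, `0` = HOM, `1` = HET, `NA` = missing; rows are
#'   variant sites, columns samples.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeMatrix",
    function(x) assay(x, "calls"))

#' Variant sites of an object
#'
#' @param x a [GenotypeMatrix-class], [HTrack-class] or
#'   [RIHSegments-class].
#' @return a `GRanges` (width-1 positions for matrices and tracks;
#'   segment spans for `RIHSegments`).
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))

#' @rdname variantSites
#' @export
setMethod("variantSites", "GenotypeMatrix", function(x) rowRanges(x))

#' @rdname variantSites
#' @export
setMethod("variantSites", "HTrack", function(x) x@sites)

#' Number of variant sites
#' @param x a [GenotypeMatrix-class].
#' @return integer count of rows (one per VCF record read).
#' @export
nVariants <- function(x) length(rowRanges(x))

#' Stage-1 H values of a track
#'
#' @param x an [HTrack-class].
#' @return numeric vector of `H = h/(g+h)` values, one per eligible
#'   variant, in genome order.
#' @export
setGeneric("hValues", function(x) standardGeneric("hValues"))

#' @rdname hValues
#' @export
setMethod("hValues", "HTrack", function(x) mcols(x@sites)$H)

#' Segment table of an RIHSegments object
#'
#' @param x an [RIHSegments-class].
#' @return the underlying `GRanges` with metadata columns `hmax`,
#'   `hmaxPos`, `startIdx`, `endIdx`, `nVariants`, `lengthBp`.
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

#' @rdname segmentRanges
#' @export
setMethod("segmentRanges", "RIHSegments", function(x) x@segments)

setMethod("length", "HTrack", function(x) length(x@sites))
setMethod("length", "RIHSegments", function(x) length(x@segments))

#' Coerce a track or segment set to a data.frame
#'
#' @param x an [HTrack-class] or [RIHSegments-class].
#' @param row.names,optional,... ignored.
#' @return a base `data.frame` (track: chrom, pos, g, h, H; segments:
#'   chrom, startPos, endPos, hmax, hmaxPos, nVariants, lengthBp).
#' @name as.data.frame-HTrack
NULL

#' @rdname as.data.frame-HTrack
#' @export
setMethod("as.data.frame", "HTrack", function(x, row.names = NULL,
                                              optional = FALSE, ...) {
    s <- x@sites
    data.frame(chrom = as.character(seqnames(s)), pos = start(s),
               g = mcols(s)$g, h = mcols(s)$h, H = mcols(s)$H,
               stringsAsFactors = FALSE)
})

#' @rdname as.data.frame-HTrack
#' @export
setMethod("as.data.frame", "RIHSegments", function(x, row.names = NULL,
                                                   optional = FALSE, ...) {
    s <- x@segments
    data.frame(chrom = as.character(seqnames(s)), startPos = start(s),
               endPos = end(s), hmax = mcols(s)$hmax,
               hmaxPos = mcols(s)$hmaxPos, nVariants = mcols(s)$nVariants,
               lengthBp = mcols(s)$lengthBp, stringsAsFactors = FALSE)
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d sites x %d samples (%d chromosome%s)\n",
                nrow(object), ncol(object),
                length(unique(as.character(seqnames(rowRanges(object))))),
                if (length(unique(as.character(seqnames(rowRanges(object))))) == 1L)
                    "" else "s"))
    cl <- assay(object, "calls")
    cat(sprintf("  HOM %d | HET %d | missing %d\n",
                sum(cl == 0L, na.rm = TRUE), sum(cl == 1L, na.rm = TRUE),
                sum(is.na(cl))))
    sex <- intersect(unique(as.character(seqnames(rowRanges(object)))),
                     c("X", "Y", "chrX", "chrY"))
    if (length(sex))
        cat("  note: sex chromosome(s) present (", paste(sex, collapse = ", "),
            "); scanned like autosomes\n", sep = "")
})

setMethod("show", "HTrack", function(object) {
    H <- hValues(object)
    cat(sprintf("HTrack: %d H values (m = %d, %d-point window, %d sample%s pooled)\n",
                length(object), object@m, 2L * object@m + 1L,
                object@nSamples, if (object@nSamples == 1L) "" else "s"))
    if (length(H))
        cat(sprintf("  H: min %.4f | median %.4f | max %.4f\n",
                    min(H), stats::median(H), max(H)))
    if (object@nSkipped > 0L)
        cat(sprintf("  %d all-missing window(s) skipped\n", object@nSkipped))
})

setMethod("show", "RIHSegments", function(object) {
    cat(sprintf("RIHSegments: %d regions of increased heterozygosity\n",
                length(object)))
    if (length(object)) {
        mc <- mcols(object@segments)
        cat(sprintf("  hmax: min %.4f | max %.4f; mean length %.0f bp\n",
                    min(mc$hmax), max(mc$hmax), mean(mc$lengthBp)))
    }
})

setMethod("show", "Stage1Rank", function(object) {
    if (!object@found) {
        cat("Stage1Rank: no H value at target\n")
        return(invisible(NULL))
    }
    cat(sprintf("Stage1Rank: H = %.6f, rank %s of %s (top %s%%)\n",
                object@H, format(object@rank, big.mark = ","),
                format(object@nVar, big.mark = ","),
                formatTopPct(object@topPct)))
})

setMethod("show", "Stage2Rank", function(object) {
    if (object@status == "no_H") {
        cat("Stage2Rank: no Stage-1 H value at target\n")
        return(invisible(NULL))
    }
    if (object@status == "not_in_RIH") {
        cat("Stage2Rank: n (target H value does not occur in any RIH)\n")
        return(invisible(NULL))
    }
    fr <- function(r) if (is.na(r)) "n" else format(r, big.mark = ",")
    cat(sprintf("Stage2Rank: hmax = %.6f, rank %s | rank2 %s | rank3 %s | rank4 %s\n",
                object@hmax, fr(object@rank), fr(object@rank2),
                fr(object@rank3), fr(object@rank4)))
    cat(sprintf("  d = %.1f kb; mean RIH length w = %.0f %s\n",
                object@d / 1000, object@w, object@lengthUnit))
})

setMethod("show", "EmpiricalResult", function(object) {
    cat(sprintf("EmpiricalResult (N = %d): p_H = %.4g (k = %d)",
                object@N, object@pH, object@kH))
    if (!is.na(object@HmaxObs))
        cat(sprintf("; p_Hmax = %.4g (k = %d)", object@pHmax, object@kHmax))
    cat("\n")
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult (n = %d): AUC = %.4f\n", object@n, object@auc))
    cat(sprintf("  best cut %.2f%%: sensitivity %.3f, specificity %.3f, total correct %.3f\n",
                object@bestThreshold, object@bestSens, object@bestSpec,
                object@bestTotal))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d chromosomes x %d variants (%g bp each)\n",
                object@nChromosomes, object@nVariants, object@chromLengthBp))
    cat(sprintf("  disease variant %s:%g, R halfwidth %g bp, %d carriers / %d noncarriers\n",
                object@diseaseChrom, object@diseasePos, object@RHalfwidthBp,
                object@nCarriers, object@nNoncarriers))
})

setMethod("show", "CohortTruth", function(object) {
    cat(sprintf("CohortTruth: disease variant %s:%d; R = [%d, %d]\n",
                as.character(seqnames(object@diseaseSite)),
                start(object@diseaseSite), start(object@region),
                end(object@region)))
    cat(sprintf("  carriers: %s\n", paste(object@carriers, collapse = ", ")))
})
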