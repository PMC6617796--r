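#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay
#'   assayNames
NULL

## Integer codes used in the "calls" assay.  NA encodes a missing genotype.
.GT_HOM <- 0L
.GT_HET <- 1L

#' Genotype-class matrix over ordered variant sites
#'
#' `GenotypeMatrix` holds one genotype class (homozygous, heterozygous or
#' missing) per variant site and sample.  It extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are variant
#' sites (a [GenomicRanges::GRanges] of width-1 positions, 1-based, ordered
#' by position within each chromosome), columns are samples, and the
#' `"calls"` assay stores the classes as integers (`0` = HOM, `1` = HET,
#' `NA` = missing).  A `"dosage"` assay (ALT allele count, 0/1/2) may be
#' present when the object was produced by [simulateCohort()]; it is used
#' by [writeVCF()] to emit allele-level genotypes.
#'
#' @slot .Data see `RangedSummarizedExperiment`.
#' @seealso [readVCF()], [genotypeCalls()], [variantSites()]
#' @export
setClass("GenotypeMatrix",
    contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!("calls" %in% assayNames(object))) {
        msg <- c(msg, "a 'calls' assay is required")
    } else {
        cl <- assay(object, "calls")
        if (!is.integer(cl))
            msg <- c(msg, "'calls' must be an integer matrix")
        else if (!all(cl %in% c(.GT_HOM, .GT_HET) | is.na(cl)))
            msg <- c(msg, "'calls' values must be 0 (HOM), 1 (HET) or NA")
    }
    rr <- rowRanges(object)
    if (length(rr)) {
        if (any(start(rr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        sq <- as.character(seqnames(rr))
        r <- rle(sq)
        if (anyDuplicated(r$values))
            msg <- c(msg, "sites of one chromosome must be contiguous")
        ok <- vapply(split(start(rr), factor(sq, unique(sq))),
                     function(p) all(diff(p) >= 0), logical(1))
        if (!all(ok))
            msg <- c(msg, "sites must be position-sorted within chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Stage-1 moving-average heterozygosity track
#'
#' One record per eligible variant (those at least `m` variants from each
#' chromosome end, with at least one non-missing genotype in the window):
#' the window's pooled homozygous count `g`, heterozygous count `h`, and
#' heterozygosity `H = h / (g + h)`.
#'
#' @slot sites `GRanges` of the eligible variants, with metadata columns
#'   `g`, `h` (integer window counts) and `H` (numeric in `[0, 1]`).
#' @slot m integer half-window in variants; the moving average spans
#'   `2 * m + 1` consecutive variants.
#' @slot nSamples number of samples pooled into the counts.
#' @slot nSkipped number of eligible positions skipped because every
#'   genotype in their window was missing.
#' @seealso [computeHTrack()], [hValues()], [segmentRIH()]
#' @export
setClass("HTrack",
    representation(sites = "GRanges", m = "integer",
                   nSamples = "integer", nSkipped = "integer"))

setValidity("HTrack", function(object) {
    mc <- mcols(object@sites)
    if (!all(c("g", "h", "H") %in% colnames(mc)))
        return("'sites' must carry metadata columns g, h, H")
    g <- mc$g; h <- mc$h; H <- mc$H
    if (any(g + h < 1L))
        return("every emitted value needs g + h >= 1")
    if (any(abs(H - h / (g + h)) > 1e-12))
        return("H must equal h / (g + h)")
    if (object@m < 0L)
        return("m must be >= 0")
    TRUE
})

#' Regions of increased heterozygosity (RIH)
#'
#' Maximal rise-then-fall runs of the Stage-1 track: within a segment the
#' `H` values are non-decreasing up to the local maximum `hmax` and
#' non-increasing after it (runs of equal `H` are treated as one point
#' during the scan).  Strictly monotone stretches between a fall and the
#' next rise belong to no segment.
#'
#' @slot segments `GRanges` spanning first to last member variant, with
#'   metadata columns `hmax`, `hmaxPos` (bp of the leftmost variant
#'   attaining `hmax`), `startIdx`/`endIdx` (row indices into the source
#'   [HTrack]), `nVariants` and `lengthBp` (`end - start` in bp).
#' @slot m the half-window of the source track.
#' @seealso [segmentRIH()], [rankHmax()], [meanSegmentLength()]
#' @export
setClass("RIHSegments",
    representation(segments = "GRanges", m = "integer"))

#' Stage-1 rank of a target variant
#'
#' @slot found `FALSE` when the target has no Stage-1 `H` value (edge
#'   variant, skipped window, or absent from the data).
#' @slot H the target's `H` value.
#' @slot rank 1-based competition rank among all emitted `H` values
#'   (largest `H` is rank 1; ties share the smallest rank).
#' @slot topPct `100 * rank / nVar`, full precision (see
#'   [formatTopPct()] for the one-decimal display convention).
#' @slot nVar number of emitted `H` values genome-wide.
#' @slot target the queried site.
#' @export
setClass("Stage1Rank",
    representation(found = "logical", H = "numeric", rank = "numeric",
                   topPct = "numeric", nVar = "numeric", target = "GRanges"))

#' Stage-2 rank of the segment containing a target variant
#'
#' @slot status `"ok"`, `"not_in_RIH"` (the target's `H` value falls in no
#'   segment; reported as "n"), or `"no_H"` (no Stage-1 value to place).
#' @slot rank competition rank of the containing segment's `hmax` among
#'   all segments' `hmax` values.
#' @slot rank2,rank3,rank4 the same rank after discarding segments shorter
#'   than `w/4`, `w/2` and `w`; `NA` when the target's own segment is
#'   discarded by the filter.
#' @slot w mean segment length (genome-wide), in the unit of `lengthUnit`.
#' @slot d absolute distance in bp between the target position and the
#'   segment's `hmax` position (the estimated disease-variant location).
#' @slot hmax the containing segment's maximum `H`.
#' @slot segmentIndex row of the containing segment in the
#'   [RIHSegments-class] object.
#' @slot lengthUnit `"bp"` or `"variants"`.
#' @slot target the queried site.
#' @export
setClass("Stage2Rank",
    representation(status = "character", rank = "numeric", rank2 = "numeric",
                   rank3 = "numeric", rank4 = "numeric", w = "numeric",
                   d = "numeric", hmax = "numeric", segmentIndex = "numeric",
                   lengthUnit = "character", target = "GRanges"))

#' Empirical genome-wide significance of an observed H (and H_max)
#'
#' Obtained by placing a null disease variant uniformly at random among
#' all variants with an emitted `H` value, `N` times, and counting values
#' at least as large as the observed one (the observed value counts
#' itself, so the smallest attainable p is `1 / (N + 1)`).
#'
#' @slot HObs,HmaxObs observed Stage-1 `H` and containing-segment `hmax`
#'   (`HmaxObs` is `NA` when the target lies in no segment).
#' @slot N replicate count.
#' @slot kH,kHmax exceedance counts including the observed value.
#' @slot pH,pHmax `k / (N + 1)`.
#' @slot seed RNG seed used (`NA` if none supplied).
#' @seealso [empiricalP()]
#' @export
setClass("EmpiricalResult",
    representation(HObs = "numeric", HmaxObs = "numeric", N = "integer",
                   kH = "integer", kHmax = "integer", pH = "numeric",
                   pHmax = "numeric", seed = "numeric"))

#' ROC analysis of carrier/noncarrier top-percent scores
#'
#' @slot points `data.frame` with columns `fpr` (1 - specificity) and
#'   `tpr` (sensitivity), ordered from (0, 0) to (1, 1).
#' @slot auc trapezoidal area under the curve.
#' @slot bestThreshold top-percent cut maximizing the total probability of
#'   correct prediction (individuals with top-percent below the cut are
#'   predicted carriers); placed midway between the adjacent observed
#'   scores.
#' @slot bestSens,bestSpec,bestTotal operating characteristics at
#'   `bestThreshold`.
#' @slot n number of scored individuals.
#' @seealso [rocCurve()], [classifyThreshold()]
#' @export
setClass("ROCResult",
    representation(points = "data.frame", auc = "numeric",
                   bestThreshold = "numeric", bestSens = "numeric",
                   bestSpec = "numeric", bestTotal = "numeric",
                   n = "integer"))

#' Synthetic-cohort configuration
#'
#' Parameters of the generator behind [simulateCohort()].  Defaults define
#' a compact whole-genome-like design: 3 chromosomes of 2 Mb with 2,000
#' marker variants each (1 variant/kb), marker minor allele frequencies
#' skewed toward rare (`mafMax * Beta(mafShape1, mafShape2)`, floored at
#' `mafMin`), a dominant disease variant mid-chromosome-1 whose carriers
#' share a founder haplotype across the unrecombined region R
#' (`diseasePos` +/- `RHalfwidthBp`), 3 carriers and 3 noncarriers, and 2%
#' missing genotypes.
#'
#' @slot nVariants markers per chromosome.
#' @slot nChromosomes,chromLengthBp genome layout.
#' @slot mafShape1,mafShape2,mafMin,mafMax marker allele-frequency law.
#' @slot diseaseChrom,diseasePos location of the planted dominant variant.
#' @slot RHalfwidthBp extent of the unrecombined founder region on each
#'   side of the disease variant.
#' @slot nCarriers,nNoncarriers cohort composition.
#' @slot missingRate per-genotype missingness probability.
#' @slot founderMinor if `TRUE` (default) the founder haplotype carries
#'   the minor allele at every marker in R, the regime the closed-form
#'   model describes for an ascertained variant list; if `FALSE` the
#'   founder allele is drawn once per variant at its population frequency.
#' @slot seed default RNG seed (`NA` = must be given to
#'   [simulateCohort()]).
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
    representation(nVariants = "integer", nChromosomes = "integer",
                   chromLengthBp = "numeric", mafShape1 = "numeric",
                   mafShape2 = "numeric", mafMin = "numeric",
                   mafMax = "numeric", diseaseChrom = "character",
                   diseasePos = "numeric", RHalfwidthBp = "numeric",
                   nCarriers = "integer", nNoncarriers = "integer",
                   missingRate = "numeric", founderMinor = "logical",
                   seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
    if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must be in [0, 1)")
    if (object@nCarriers < 0L || object@nNoncarriers < 0L)
        msg <- c(msg, "cohort counts must be >= 0")
    if (!(object@diseaseChrom %in% paste0("chr", seq_len(object@nChromosomes))))
        msg <- c(msg, "diseaseChrom must name one of the simulated chromosomes")
    if (object@diseasePos < 1 || object@diseasePos > object@chromLengthBp)
        msg <- c(msg, "diseasePos must lie inside its chromosome")
    if (object@mafMin <= 0 || object@mafMax > 0.5 ||
        object@mafMin > object@mafMax)
        msg <- c(msg, "need 0 < mafMin <= mafMax <= 0.5")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot diseaseSite position of the planted dominant variant.
#' @slot region the unrecombined founder region R (truncated to the
#'   chromosome if necessary).
#' @slot carriers,noncarriers sample identifiers.
#' @slot founder `GRanges` of the markers inside R with metadata columns
#'   `allele` (founder haplotype allele, 0 = REF/major, 1 = ALT/minor) and
#'   `f` (ALT allele population frequency).
#' @slot maf ALT allele frequency of every emitted marker, in site order
#'   (`NA` at the disease site itself).
#' @slot seed the RNG seed the cohort was generated from.
#' @export
setClass("CohortTruth",
    representation(diseaseSite = "GRanges", region = "GRanges",
                   carriers = "character", noncarriers = "character",
                   founder = "GRanges", maf = "numeric", seed = "numeric"))
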