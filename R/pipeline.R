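#' Run the full heterozygosity-analysis pipeline
#'
#' Glues the stages together: read (or accept) a genotype matrix,
#' compute the Stage-1 moving-average heterozygosity track, segment it
#' into regions of increased heterozygosity, and — when a target variant
#' is supplied — rank the target at both stages and optionally estimate
#' empirical genome-wide significance.
#'
#' @param x a VCF path or a [GenotypeMatrix-class].
#' @param samples optional sample subset (VCF input only).
#' @param m Stage-1 half-window in variants (default 50, a 101-point
#'   average).
#' @param targetChrom,targetPos optional target variant.
#' @param N replicate count for empirical significance; `NULL` (default)
#'   skips the significance stage.  Classic choice: 999.
#' @param seed RNG seed for the significance stage.
#' @param lengthUnit RIH length-filter unit, `"bp"` or `"variants"`.
#' @param outPrefix optional path prefix; when given, writes
#'   `<prefix>_track.tsv`, `<prefix>_segments.bed` and (with a target)
#'   `<prefix>_rank.tsv` plus `<prefix>_pvalue.tsv`, each with
#'   provenance headers.
#' @return list with elements `track`, `segments`, and (with a target)
#'   `stage1`, `stage2`, `empirical` (`NULL` unless `N` given).
#' @examples
#' sim <- simulateCohort(simConfig(nVariants = 400, nChromosomes = 1,
#'                                 nCarriers = 2, nNoncarriers = 0,
#'                                 diseasePos = 1e6), seed = 7)
#' res <- runScan(sim$genotypes, m = 20,
#'                targetChrom = "chr1", targetPos = 1e6, N = 99, seed = 7)
#' res$stage1
#' @export
runScan <- function(x, samples = NULL, m = 50L, targetChrom = NULL,
                    targetPos = NULL, N = NULL, seed = NULL,
                    lengthUnit = c("bp", "variants"), outPrefix = NULL) {
    lengthUnit <- match.arg(lengthUnit)
    gm <- if (is(x, "GenotypeMatrix")) x else readVCF(x, samples = samples)
    chroms <- unique(as.character(seqnames(rowRanges(gm))))
    if (any(isSexChrom(chroms)))
        message("sex chromosome(s) scanned like autosomes: ",
                paste(chroms[isSexChrom(chroms)], collapse = ", "))
    track <- computeHTrack(gm, m = m)
    segments <- segmentRIH(track)
    res <- list(track = track, segments = segments, stage1 = NULL,
                stage2 = NULL, empirical = NULL)
    target <- NULL
    if (!is.null(targetChrom)) {
        target <- .asSite(targetChrom, targetPos)
        res$stage1 <- rankH(track, target)
        res$stage2 <- rankHmax(segments, track, target,
                               lengthUnit = lengthUnit)
        if (!is.null(N)) {
            if (!res$stage1@found)
                stop("target has no H value; cannot estimate significance",
                     call. = FALSE)
            res$empirical <- empiricalP(track, segments, target, N = N,
                                        seed = seed)
        }
    }
    if (!is.null(outPrefix)) {
        exportTrack(track, paste0(outPrefix, "_track.tsv"))
        exportSegmentsBED(segments, paste0(outPrefix, "_segments.bed"))
        if (!is.null(target))
            .exportRankReport(res, target, paste0(outPrefix, "_rank.tsv"))
        if (!is.null(res$empirical))
            exportEmpirical(res$empirical, target,
                            paste0(outPrefix, "_pvalue.tsv"))
    }
    res
}

## Rank report in the classic column layout: Stage-1 rank/top%/Nvar,
## then Stage-2 rank, d, rank2..rank4 ("n" when undefined).
.exportRankReport <- function(res, target, path) {
    s1 <- res$stage1
    s2 <- res$stage2
    fmt <- function(v) ifelse(is.na(v), "n", format(v))
    df <- data.frame(
        target = sprintf("%s:%d", as.character(seqnames(target)),
                         start(target)),
        rank = fmt(s1@rank),
        topPct = if (s1@found) formatTopPct(s1@topPct) else "n",
        Nvar = format(s1@nVar),
        rank_hmax = if (s2@status == "ok") fmt(s2@rank) else "n",
        d_kb = if (s2@status == "ok")
            format(roundHalfUp(s2@d / 1000, 1)) else "n",
        rank2 = if (s2@status == "ok") fmt(s2@rank2) else "n",
        rank3 = if (s2@status == "ok") fmt(s2@rank3) else "n",
        rank4 = if (s2@status == "ok") fmt(s2@rank4) else "n")
    con <- file(path, "w")
    writeLines(provenanceHeader(list(m = res$track@m,
                                     lengthUnit = s2@lengthUnit)), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
    close(con)
    invisible(path)
}
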