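#' Pooled genotype counts in a (2m+1)-variant window
#'
#' Counts homozygous (`g`) and heterozygous (`h`) genotypes at a variant
#' and the `m` variants on either side of it, pooled over all samples.
#' Missing genotypes contribute to neither count.  A window touching the
#' chromosome edge yields no value (`NULL`), not an error: the first and
#' last `m` variants of a chromosome carry no moving average.
#'
#' @param x a [GenotypeMatrix-class].
#' @param chrom chromosome identifier.
#' @param i 1-based variant index *within* that chromosome.
#' @param m half-window in variants (default 50, i.e. a 101-point
#'   average).
#' @return named integer vector `c(g =, h =)`, or `NULL` at an edge.
#' @seealso [computeHTrack()] for the full-genome vectorized scan.
#' @export
windowCounts <- function(x, chrom, i, m = 50L) {
    m <- as.integer(m)
    stopifnot(m >= 0L, i >= 1L)
    onChrom <- which(as.character(seqnames(rowRanges(x))) == chrom)
    n <- length(onChrom)
    if (n == 0L)
        stop("no sites on chromosome ", chrom, call. = FALSE)
    if (i > n)
        stop("index ", i, " exceeds the ", n, " sites on ", chrom,
             call. = FALSE)
    if (i - m < 1L || i + m > n)
        return(NULL)
    cl <- assay(x, "calls")[onChrom[(i - m):(i + m)], , drop = FALSE]
    h <- sum(cl == .GT_HET, na.rm = TRUE)
    g <- sum(cl == .GT_HOM, na.rm = TRUE)
    c(g = g, h = h)
}

#' Stage 1: moving-average heterozygosity across the genome
#'
#' At every variant at least `m` variants from each chromosome end, the
#' `(2m+1)`-point window counts `g` (homozygous) and `h` (heterozygous)
#' genotypes pooled over all samples, and the average heterozygosity is
#' `H = h / (g + h)`.  Counts, not per-sample `H` values, are pooled when
#' several individuals are analyzed jointly, so without missingness
#' `g + h = (2m+1) * n` for `n` samples.  Windows in which every genotype
#' is missing yield no `H` value; such variants are skipped (and counted
#' in the track's `nSkipped`).
#'
#' @param x a [GenotypeMatrix-class].
#' @param m half-window in variants (default 50).
#' @return an [HTrack-class].  Chromosomes with `2m + 1` or fewer
#'   variants contribute no values (with a warning); at least one
#'   chromosome must have more than `2m` variants.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:5 * 100, width = 1))
#' gm <- GenotypeMatrix(sites, matrix(c(0L, 1L, 1L, 0L, 0L), ncol = 1))
#' hValues(computeHTrack(gm, m = 1))  # 3 interior windows
#' @export
computeHTrack <- function(x, m = 50L) {
    m <- as.integer(m)
    stopifnot(m >= 0L)
    if (nrow(x) == 0L)
        stop("empty genotype matrix", call. = FALSE)
    cl <- assay(x, "calls")
    rr <- rowRanges(x)
    chrom <- as.character(seqnames(rr))
    hetPer <- as.integer(rowSums(cl == .GT_HET, na.rm = TRUE))
    obsPer <- as.integer(rowSums(!is.na(cl)))
    w <- 2L * m + 1L
    idxByChrom <- split(seq_along(chrom), factor(chrom, unique(chrom)))
    keep <- integer(0)
    gAll <- hAll <- integer(0)
    nSkipped <- 0L
    for (ix in idxByChrom) {
        n <- length(ix)
        if (n < w) {
            warning("chromosome ", chrom[ix[1L]], " has fewer than ",
                    w, " variants; no H values emitted", call. = FALSE)
            next
        }
        hWin <- .runSum(hetPer[ix], w)
        nWin <- .runSum(obsPer[ix], w)
        centers <- ix[(m + 1L):(n - m)]
        empty <- nWin == 0L
        if (any(empty)) {
            nSkipped <- nSkipped + sum(empty)
            message(sum(empty), " all-missing window(s) skipped on ",
                    chrom[ix[1L]])
        }
        keep <- c(keep, centers[!empty])
        hAll <- c(hAll, hWin[!empty])
        gAll <- c(gAll, nWin[!empty] - hWin[!empty])
    }
    if (!length(keep))
        stop("no chromosome has more than 2m variants; ",
             "decrease m or supply more data", call. = FALSE)
    sites <- GRanges(chrom[keep], IRanges(start(rr)[keep], width = 1L))
    mcols(sites)$g <- gAll
    mcols(sites)$h <- hAll
    mcols(sites)$H <- hAll / (gAll + hAll)
    new("HTrack", sites = sites, m = m, nSamples = ncol(x),
        nSkipped = as.integer(nSkipped))
}

## Running sum of window width w; one value per interior center.
.runSum <- function(v, w) {
    cs <- c(0L, cumsum(v))
    cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]
}

#' Stage-1 genome-wide rank of a target variant's H value
#'
#' Competition ranking: the largest `H` is rank 1, and the target's rank
#' is one plus the number of `H` values strictly greater than its own
#' (tied values share the smallest rank).  The top-percent is
#' `100 * rank / N_var` over all emitted `H` values.
#'
#' @param track an [HTrack-class].
#' @param chrom,pos target variant position (alternatively pass a
#'   length-1 `GRanges` as `chrom`).
#' @return a [Stage1Rank-class]; when the target carries no `H` value
#'   (edge variant, skipped or absent) the result has `found = FALSE`
#'   rather than raising an error.
#' @export
rankH <- function(track, chrom, pos = NULL) {
    target <- .asSite(chrom, pos)
    idx <- .trackIndex(track, target)
    H <- hValues(track)
    if (is.na(idx))
        return(new("Stage1Rank", found = FALSE, H = NA_real_,
                   rank = NA_real_, topPct = NA_real_,
                   nVar = as.numeric(length(H)), target = target))
    hObs <- H[idx]
    rk <- 1 + sum(H > hObs)
    new("Stage1Rank", found = TRUE, H = hObs, rank = as.numeric(rk),
        topPct = topPct(rk, length(H)), nVar = as.numeric(length(H)),
        target = target)
}

.asSite <- function(chrom, pos = NULL) {
    if (is(chrom, "GRanges")) {
        stopifnot(length(chrom) == 1L)
        return(chrom)
    }
    GRanges(as.character(chrom), IRanges(as.numeric(pos), width = 1L))
}

## Row index of a target site in a track (first match; NA if absent).
.trackIndex <- function(track, target) {
    s <- track@sites
    hit <- which(as.character(seqnames(s)) ==
                     as.character(seqnames(target))[1L] &
                 start(s) == start(target)[1L])
    if (!length(hit)) return(NA_integer_)
    if (length(hit) > 1L)
        warning("duplicate site at target position; using the first record",
                call. = FALSE)
    hit[1L]
}

#' Export a Stage-1 track
#'
#' Writes the track as tab-separated text (`chrom`, `pos`, `g`, `h`, `H`
#' with six decimals) preceded by provenance header lines, and optionally
#' as bedGraph for genome browsers.
#'
#' @param track an [HTrack-class].
#' @param path output TSV path.
#' @param bedGraph optional bedGraph output path.
#' @return `path`, invisibly.
#' @export
exportTrack <- function(track, path, bedGraph = NULL) {
    df <- as.data.frame(track)
    df$H <- sprintf("%.6f", df$H)
    con <- file(path, "w")
    writeLines(provenanceHeader(list(m = track@m,
                                     nSamples = track@nSamples)), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
    close(con)
    if (!is.null(bedGraph)) {
        bg <- data.frame(df$chrom, as.integer(df$pos) - 1L, df$pos, df$H)
        utils::write.table(bg, bedGraph, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}
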