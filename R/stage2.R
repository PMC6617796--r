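#' Stage 2: segment a heterozygosity track into RIH
#'
#' Partitions each chromosome's ordered `H` values into regions of
#' increased heterozygosity: runs that rise to a local maximum `H_max`
#' and then fall.  Operationally, successive differences of consecutive
#' `H` values are scanned; zero differences are skipped, i.e. runs of
#' equal `H` act as a single point.  A segment starts at the local
#' minimum from which the first rise departs (unless that variant already
#' closed the previous segment's fall, in which case the new segment
#' starts one variant later, keeping segments disjoint), peaks at
#' `H_max`, and ends with the last falling variant before the next rise.
#' Strictly monotone stretches before the first rise, after the last
#' completed fall, or a terminal rise that never falls, belong to no
#' segment — a target variant there is reported as "n" by [rankHmax()].
#'
#' @param track an [HTrack-class] with at least 2 `H` values per scanned
#'   chromosome.
#' @return an [RIHSegments-class].  A chromosome with constant `H`
#'   contributes zero segments (with a warning).
#' @examples
#' ## one rise-then-fall run covering all five points
#' tr <- HetScan:::.toyTrack(c(.1, .2, .3, .2, .1))
#' as.data.frame(segmentRIH(tr))
#' @export
segmentRIH <- function(track) {
    s <- track@sites
    H <- mcols(s)$H
    chrom <- as.character(seqnames(s))
    idxByChrom <- split(seq_along(H), factor(chrom, unique(chrom)))
    rows <- list()
    for (ix in idxByChrom) {
        if (length(ix) < 2L)
            next
        segs <- .scanSegments(H[ix])
        if (is.null(segs)) {
            warning("constant H on chromosome ", chrom[ix[1L]],
                    "; no RIH formed", call. = FALSE)
            next
        }
        if (!nrow(segs))
            next
        segs$startIdx <- ix[segs$startIdx]
        segs$endIdx <- ix[segs$endIdx]
        segs$hmaxIdx <- ix[segs$hmaxIdx]
        rows[[length(rows) + 1L]] <- segs
    }
    if (!length(rows)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(hmax = numeric(0), hmaxPos = integer(0),
                               startIdx = integer(0), endIdx = integer(0),
                               nVariants = integer(0), lengthBp = numeric(0))
        return(new("RIHSegments", segments = gr, m = track@m))
    }
    segs <- do.call(rbind, rows)
    pos <- start(s)
    gr <- GRanges(as.character(seqnames(s))[segs$startIdx],
                  IRanges(pos[segs$startIdx], pos[segs$endIdx]))
    mcols(gr) <- DataFrame(hmax = segs$hmax,
                           hmaxPos = pos[segs$hmaxIdx],
                           startIdx = segs$startIdx,
                           endIdx = segs$endIdx,
                           nVariants = segs$endIdx - segs$startIdx + 1L,
                           lengthBp = as.numeric(pos[segs$endIdx] -
                                                 pos[segs$startIdx]))
    new("RIHSegments", segments = gr, m = track@m)
}

## Rise-then-fall scan over one chromosome's H values.
## Returns a data.frame of index triples (into the given vector), an
## empty data.frame when no complete rise-and-fall exists, or NULL for a
## constant sequence.
.scanSegments <- function(h) {
    r <- rle(h)
    K <- length(r$values)
    if (K == 1L)
        return(NULL)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    d <- diff(r$values)                    # all non-zero after collapsing
    out <- list()
    lastEnd <- 0L                          # last run consumed by a segment
    j <- 1L
    while (j <= K - 1L) {
        if (d[j] <= 0) { j <- j + 1L; next }
        ## rise begins at run j -> j+1
        q <- j
        while (q <= K - 1L && d[q] > 0) q <- q + 1L
        if (q > K - 1L)
            break                          # terminal rise, never falls
        ## d[q] < 0: peak is run q; descend
        e <- q
        while (e <= K - 1L && d[e] < 0) e <- e + 1L
        startRun <- max(j, lastEnd + 1L)
        out[[length(out) + 1L]] <-
            c(startIdx = runStart[startRun], endIdx = runEnd[e],
              hmaxIdx = runStart[q], hmax = r$values[q])
        lastEnd <- e
        j <- e
    }
    if (!length(out))
        return(data.frame(startIdx = integer(0), endIdx = integer(0),
                          hmaxIdx = integer(0), hmax = numeric(0)))
    m <- do.call(rbind, out)
    data.frame(startIdx = as.integer(m[, "startIdx"]),
               endIdx = as.integer(m[, "endIdx"]),
               hmaxIdx = as.integer(m[, "hmaxIdx"]),
               hmax = m[, "hmax"])
}

## Tiny track constructor used in examples/tests: equally spaced sites
## on one chromosome with the given H values (g/h chosen to match H).
.toyTrack <- function(H, chrom = "chr1", pos = seq_along(H) * 1000L,
                      m = 0L) {
    den <- 1000L
    h <- as.integer(round(H * den))
    sites <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(sites)$g <- den - h
    mcols(sites)$h <- h
    mcols(sites)$H <- h / den
    new("HTrack", sites = sites, m = as.integer(m), nSamples = 1L,
        nSkipped = 0L)
}

#' Mean RIH segment length
#'
#' Arithmetic mean of segment lengths genome-wide; the quantity `w` used
#' by the rank2/rank3/rank4 length filters of [rankHmax()].
#'
#' @param segments an [RIHSegments-class] with at least one segment.
#' @param unit `"bp"` (end - start of the member variants) or
#'   `"variants"` (member-variant count).
#' @return numeric mean length.
#' @export
meanSegmentLength <- function(segments, unit = c("bp", "variants")) {
    unit <- match.arg(unit)
    if (!length(segments))
        stop("no segments", call. = FALSE)
    mc <- mcols(segments@segments)
    mean(if (unit == "bp") mc$lengthBp else mc$nVariants)
}

#' Stage-2 rank of the RIH segment containing a target variant
#'
#' Ranks the `H_max` of the segment containing the target among all
#' segments' `H_max` values (competition ranking), and again after
#' discarding segments shorter than `w/4` (`rank2`), `w/2` (`rank3`) and
#' `w` (`rank4`), where `w` is the mean segment length from
#' [meanSegmentLength()].  Length filters use "at least" comparisons
#' (`>=`), and the target's own segment is subject to the same filter: a
#' filtered rank is `NA` when the filter discards the very segment
#' containing the target.  The estimated disease-variant location is the
#' segment's `H_max` position, and `d` is its absolute distance in bp
#' from the target.
#'
#' @param segments an [RIHSegments-class].
#' @param track the [HTrack-class] the segments were derived from.
#' @param chrom,pos target variant (or a length-1 `GRanges` as `chrom`).
#' @param lengthUnit unit for segment lengths and `w` (`"bp"` default, or
#'   `"variants"`).
#' @return a [Stage2Rank-class].  `status` is `"no_H"` when the target
#'   has no Stage-1 value, `"not_in_RIH"` ("n") when its `H` value lies
#'   in no segment.
#' @export
rankHmax <- function(segments, track, chrom, pos = NULL,
                     lengthUnit = c("bp", "variants")) {
    lengthUnit <- match.arg(lengthUnit)
    target <- .asSite(chrom, pos)
    if (!length(segments))
        stop("no segments to rank within", call. = FALSE)
    idx <- .trackIndex(track, target)
    blank <- function(status)
        new("Stage2Rank", status = status, rank = NA_real_,
            rank2 = NA_real_, rank3 = NA_real_, rank4 = NA_real_,
            w = NA_real_, d = NA_real_, hmax = NA_real_,
            segmentIndex = NA_real_, lengthUnit = lengthUnit,
            target = target)
    if (is.na(idx))
        return(blank("no_H"))
    mc <- mcols(segments@segments)
    segIdx <- which(mc$startIdx <= idx & mc$endIdx >= idx)
    if (!length(segIdx))
        return(blank("not_in_RIH"))
    segIdx <- segIdx[1L]
    hmax <- mc$hmax
    len <- if (lengthUnit == "bp") mc$lengthBp else as.numeric(mc$nVariants)
    w <- mean(len)
    compRank <- function(keep) {
        if (!keep[segIdx]) return(NA_real_)
        1 + sum(hmax[keep] > hmax[segIdx])
    }
    d <- abs(mc$hmaxPos[segIdx] - start(target))
    res <- new("Stage2Rank", status = "ok",
               rank = compRank(rep(TRUE, length(hmax))),
               rank2 = compRank(len >= w / 4),
               rank3 = compRank(len >= w / 2),
               rank4 = compRank(len >= w),
               w = w, d = as.numeric(d), hmax = hmax[segIdx],
               segmentIndex = as.numeric(segIdx), lengthUnit = lengthUnit,
               target = target)
    if (is.na(res@rank4))
        message("target segment shorter than the mean RIH length; ",
                "rank4 (and possibly rank2/rank3) not defined")
    res
}

#' Export RIH segments as BED
#'
#' BED uses the 0-based half-open convention: `start_pos - 1` to
#' `end_pos`.  Columns: chrom, start, end, name (`hmax` value), score
#' (`lengthBp`).
#'
#' @param segments an [RIHSegments-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportSegmentsBED <- function(segments, path) {
    df <- as.data.frame(segments)
    bed <- data.frame(df$chrom, df$startPos - 1L, df$endPos,
                      sprintf("hmax=%.6f", df$hmax), df$lengthBp)
    con <- file(path, "w")
    writeLines(provenanceHeader(list(m = segments@m)), con)
    writeLines(do.call(paste, c(bed, sep = "\t")), con)
    close(con)
    invisible(path)
}
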