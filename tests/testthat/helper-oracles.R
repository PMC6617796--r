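## Shared helpers: tiny object builders and independently coded oracles.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## GenotypeMatrix from an integer class matrix (0 HOM, 1 HET, NA).
toyMatrix <- function(classes, chrom = "chr1",
                      pos = seq_len(nrow(as.matrix(classes))) * 100L) {
    classes <- as.matrix(classes)
    sites <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    GenotypeMatrix(sites, classes)
}

## Random class matrix with given missingness.
randClasses <- function(n, k, pMiss = 0.1) {
    m <- matrix(sample(c(0L, 1L), n * k, replace = TRUE), n, k)
    m[matrix(runif(n * k) < pMiss, n, k)] <- NA_integer_
    m
}

## Brute-force window counts: explicit double loop over cells.
bruteWindowCounts <- function(classes, i, m) {
    g <- 0L; h <- 0L
    for (r in (i - m):(i + m)) {
        for (cc in seq_len(ncol(classes))) {
            v <- classes[r, cc]
            if (is.na(v)) next
            if (v == 1L) h <- h + 1L else g <- g + 1L
        }
    }
    c(g = g, h = h)
}

## Naive per-variant track on a single-chromosome class matrix.
bruteTrack <- function(classes, m) {
    n <- nrow(classes)
    out <- NULL
    for (i in seq_len(n)) {
        if (i - m < 1L || i + m > n) next
        ct <- bruteWindowCounts(classes, i, m)
        if (sum(ct) == 0L) next
        out <- rbind(out, c(i = i, ct, H = unname(ct["h"] / sum(ct))))
    }
    as.data.frame(out)
}

## Independent RIH oracle: local-extremum bracketing on the
## plateau-collapsed sequence.  Returns a data.frame of variant index
## ranges (startIdx, endIdx, hmaxIdx, hmax) or NULL for constant input.
bracketSegments <- function(h) {
    keep <- c(TRUE, diff(h) != 0)
    runStart <- which(keep)
    runEnd <- c(runStart[-1] - 1L, length(h))
    v <- h[runStart]
    K <- length(v)
    if (K == 1L) return(NULL)
    s <- sign(diff(v))                      # +1 rise, -1 fall; no zeros
    ## peaks: runs with a rise in and a fall out
    peaks <- which(c(FALSE, s == 1) & c(s == -1, FALSE))
    if (!length(peaks))
        return(data.frame(startIdx = integer(0), endIdx = integer(0),
                          hmaxIdx = integer(0), hmax = numeric(0)))
    res <- NULL
    prevEnd <- 0L
    for (p in peaks) {
        a <- p                              # walk down to the local-min run
        while (a > 1L && s[a - 1L] == 1) a <- a - 1L
        b <- p
        while (b <= K - 1L && s[b] == -1) b <- b + 1L
        if (a <= prevEnd) a <- prevEnd + 1L # shared min stays with earlier fall
        res <- rbind(res, c(startIdx = runStart[a], endIdx = runEnd[b],
                            hmaxIdx = runStart[p], hmax = v[p]))
        prevEnd <- b
    }
    as.data.frame(res)
}

## Literal empirical-p: re-run the full scan for every replicate.
literalEmpiricalP <- function(gm, m, target, N, seed) {
    track0 <- computeHTrack(gm, m = m)
    seg0 <- segmentRIH(track0)
    H0 <- hValues(track0)
    idx <- HetScan:::.trackIndex(track0, target)
    hObs <- H0[idx]
    hmaxObs <- HetScan:::.hmaxByTrackIndex(seg0, length(H0))[idx]
    set.seed(seed)
    draws <- sample.int(length(H0), N, replace = TRUE)
    kH <- 1L
    kHmax <- 1L
    for (r in seq_len(N)) {
        tr <- computeHTrack(gm, m = m)      # the full per-replicate analysis
        sg <- segmentRIH(tr)
        Hr <- hValues(tr)[draws[r]]
        if (Hr >= hObs) kH <- kH + 1L
        hm <- HetScan:::.hmaxByTrackIndex(sg, length(hValues(tr)))[draws[r]]
        if (!is.na(hmaxObs) && !is.na(hm) && hm >= hmaxObs)
            kHmax <- kHmax + 1L
    }
    list(pH = kH / (N + 1),
         pHmax = if (is.na(hmaxObs)) NA_real_ else kHmax / (N + 1))
}

## Pairwise Mann-Whitney concordance that a carrier scores BELOW a
## noncarrier, with half credit for ties.
pairConcordance <- function(scores) {
    cs <- scores$topPct[scores$label == "C"]
    ns <- scores$topPct[scores$label == "N"]
    tot <- 0
    for (a in cs) for (b in ns)
        tot <- tot + (a < b) + 0.5 * (a == b)
    tot / (length(cs) * length(ns))
}

## Minimal VCF text written to a temp file; body rows are
## "chrom pos id ref alt gt1 gt2 ..." strings.
writeTempVCF <- function(rows, samples) {
    path <- tempfile(fileext = ".vcf")
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    body <- vapply(rows, function(r)
        paste(c(r[1:5], ".", ".", ".", "GT", r[-(1:5)]), collapse = "\t"),
        character(1))
    writeLines(c(hdr, body), path)
    path
}
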