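#' Empirical genome-wide significance by random null placement
#'
#' Under the null hypothesis the disease variant could sit at any marker,
#' so a null disease variant is placed uniformly at random among all
#' variants possessing an emitted `H` value, `N` times.  Because the scan
#' itself does not depend on where the target is, each replicate's
#' analysis reproduces the observed track exactly, and the replicate
#' statistics can be read off the precomputed track — an exact shortcut,
#' not an approximation.  For each replicate the `H` at the null position
#' and the `H_max` of the segment containing it (if any) are recorded;
#' the significance level is `p = k / (N + 1)` where `k` counts, among
#' the `N` replicate values *and the observed value itself*, those at
#' least as large as the observed one.  The smallest attainable p is
#' therefore `1 / (N + 1)` (0.001 at the default `N = 999`).  Null
#' positions falling in no RIH contribute no `H_max` exceedance.
#'
#' @param track an [HTrack-class].
#' @param segments the matching [RIHSegments-class].
#' @param chrom,pos target variant (or a length-1 `GRanges` as `chrom`).
#' @param N number of replicates (default 999).
#' @param seed optional RNG seed; when given, the caller's RNG state is
#'   left untouched and the result is reproducible.
#' @return an [EmpiricalResult-class].
#' @export
empiricalP <- function(track, segments, chrom, pos = NULL, N = 999L,
                       seed = NULL) {
    N <- as.integer(N)
    if (is.na(N) || N < 1L)
        stop("N must be >= 1", call. = FALSE)
    target <- .asSite(chrom, pos)
    idx <- .trackIndex(track, target)
    if (is.na(idx))
        stop("target has no H value (edge variant or absent); ",
             "empirical significance requires a Stage-1 value",
             call. = FALSE)
    H <- hValues(track)
    hmaxAt <- .hmaxByTrackIndex(segments, length(H))
    hObs <- H[idx]
    hmaxObs <- hmaxAt[idx]
    draws <- withLocalSeed(seed, sample.int(length(H), N, replace = TRUE))
    kH <- 1L + sum(H[draws] >= hObs)
    if (is.na(hmaxObs)) {
        kHmax <- NA_integer_
        pHmax <- NA_real_
    } else {
        kHmax <- 1L + sum(hmaxAt[draws] >= hmaxObs, na.rm = TRUE)
        pHmax <- kHmax / (N + 1)
    }
    new("EmpiricalResult", HObs = hObs, HmaxObs = hmaxObs, N = N,
        kH = as.integer(kH), kHmax = kHmax, pH = kH / (N + 1),
        pHmax = pHmax,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

## hmax of the containing segment for every track row (NA outside RIH).
.hmaxByTrackIndex <- function(segments, nTrack) {
    out <- rep(NA_real_, nTrack)
    mc <- mcols(segments@segments)
    for (k in seq_len(length(segments)))
        out[mc$startIdx[k]:mc$endIdx[k]] <- mc$hmax[k]
    out
}

#' Export an empirical-significance report
#'
#' Tab-separated single-row report: target, `H_obs`, `p_H`, `Hmax_obs`,
#' `p_Hmax`, `N`, seed, preceded by provenance headers.
#'
#' @param result an [EmpiricalResult-class].
#' @param target the tested site (`GRanges` of length 1).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportEmpirical <- function(result, target, path) {
    df <- data.frame(
        target = sprintf("%s:%d", as.character(seqnames(target)),
                         start(target)),
        H_obs = sprintf("%.6f", result@HObs),
        p_H = sprintf("%.4g", result@pH),
        Hmax_obs = ifelse(is.na(result@HmaxObs), "n",
                          sprintf("%.6f", result@HmaxObs)),
        p_Hmax = ifelse(is.na(result@pHmax), "n",
                        sprintf("%.4g", result@pHmax)),
        N = result@N, seed = result@seed)
    con <- file(path, "w")
    writeLines(provenanceHeader(list(N = result@N, seed = result@seed)), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
    close(con)
    invisible(path)
}
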