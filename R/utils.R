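#' Top-percent of a rank
#'
#' `topPct()` converts a 1-based rank among `nVar` ranked values to the
#' top-percent scale, `100 * rank / nVar`, at full precision.
#' `formatTopPct()` renders it with the one-decimal, round-half-up display
#' convention used in rank reports (e.g. rank 78,924 of 6,347,882 displays
#' as `"1.2"`).
#'
#' @param rank 1-based rank (1 = largest value).
#' @param nVar number of ranked values.
#' @return `topPct()`: numeric; `formatTopPct()`: character.
#' @examples
#' topPct(78924, 6347882)            # 1.2433...
#' formatTopPct(topPct(87720, 424175))  # "20.7"
#' @export
topPct <- function(rank, nVar) {
    stopifnot(all(rank >= 1), all(rank <= nVar))
    100 * rank / nVar
}

#' @rdname topPct
#' @param x a top-percent value.
#' @param digits decimals to keep (half-up).
#' @export
formatTopPct <- function(x, digits = 1L) {
    formatC(roundHalfUp(x, digits), format = "f", digits = digits)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; ranked-percent displays use the
#' conventional half-up rule instead.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 0L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

## Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
## seed = NULL leaves the global stream untouched (and advancing).
withLocalSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed))
        return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Provenance header lines for text outputs.
provenanceHeader <- function(config = list()) {
    c(sprintf("##HetScan=%s", as.character(utils::packageVersion("HetScan"))),
      if (length(config))
          sprintf("##config=%s", paste(names(config),
                                       vapply(config, function(v)
                                           paste(format(v), collapse = ","),
                                           character(1)),
                                       sep = "=", collapse = ";")))
}

## Sex-chromosome labels flagged (not excluded) in scan outputs.
isSexChrom <- function(chrom) {
    sub("^chr", "", chrom) %in% c("X", "Y")
}
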