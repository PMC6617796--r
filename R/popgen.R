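#' Haplotype frequencies for a disease variant and a nearby marker
#'
#' Two-locus haplotype table for a dominant disease variant (wild-type
#' `+`, mutant `u`, mutant frequency `e`) and a biallelic marker (alleles
#' `A`/`B`, `A` frequency `f`) with disequilibrium parameter `D`:
#' `uA = ef + D`, `uB = e(1-f) - D`, `+A = (1-e)f - D`,
#' `+B = (1-e)(1-f) + D`.  At `D = Dmax = e(1-f)` the `uB` cell is empty
#' (`D' = 1`): only the `A` allele occurs on the disease chromosome, the
#' regime created when a mutation arises once on a founder haplotype and
#' region R is passed on unrecombined.
#'
#' @param e disease (mutant) allele frequency, in (0, 1).
#' @param f marker `A`-allele frequency, in (0, 1).
#' @param D disequilibrium parameter; must keep all four cells
#'   non-negative.
#' @return named numeric vector `c(uA, uB, pA, pB)` summing to 1, with
#'   row sums `e`, `1 - e` and column sums `f`, `1 - f`.
#' @examples
#' haplotypeFreqs(e = 0.01, f = 0.1, D = 0.005)
#' haplotypeFreqs(0.01, 0.1, D = dMax(0.01, 0.1))["uB"]  # 0
#' @export
haplotypeFreqs <- function(e, f, D) {
    .checkEF(e, f)
    cells <- c(uA = e * f + D,
               uB = e * (1 - f) - D,
               pA = (1 - e) * f - D,
               pB = (1 - e) * (1 - f) + D)
    if (any(cells < -1e-12)) {
        lo <- max(-e * f, -(1 - e) * (1 - f))
        hi <- min(e * (1 - f), (1 - e) * f)
        stop(sprintf(
            "D = %g gives a negative haplotype frequency; admissible D in [%g, %g]",
            D, lo, hi), call. = FALSE)
    }
    pmax(cells, 0)
}

#' @rdname haplotypeFreqs
#' @return `dMax()`: the largest admissible `D`, `e * (1 - f)`.
#' @export
dMax <- function(e, f) {
    .checkEF(e, f)
    e * (1 - f)
}

.checkEF <- function(e, f) {
    if (any(e <= 0 | e >= 1)) stop("e must be in (0, 1)", call. = FALSE)
    if (any(f <= 0 | f >= 1)) stop("f must be in (0, 1)", call. = FALSE)
    invisible(TRUE)
}

#' Heterozygosity at a marker tightly linked to a dominant variant
#'
#' Under the three-haplotype regime (`D = Dmax`, the founder haplotype
#' carrying only `A` in region R), a carrier is heterozygous `A/B`
#' whenever the non-disease chromosome carries `B`:
#' `H = P(B | +) = (1 - f) / (1 - e)`, which always exceeds `1 - f`.
#' For a rare marker allele `A` (small `f`) this approaches 1.
#'
#' @param e disease allele frequency.
#' @param f marker `A`-allele frequency; requires `e <= f`, otherwise the
#'   `D = Dmax` assumption would imply a probability above 1.
#' @return numeric heterozygosity in (0, 1].
#' @examples
#' hetNearDisease(0.01, 0.1)  # 0.909...
#' @export
hetNearDisease <- function(e, f) {
    .checkEF(e, f)
    H <- (1 - f) / (1 - e)
    if (any(H > 1 + 1e-12))
        stop("e > f: the D = Dmax assumption is inconsistent with these ",
             "frequencies (implied heterozygosity exceeds 1)",
             call. = FALSE)
    pmin(H, 1)
}

#' Heterozygosity of a random (unlinked) marker
#'
#' Hardy-Weinberg heterozygosity `2 f (1 - f)`: the expectation far from
#' the disease variant, small for rare alleles and at most 0.5 at
#' `f = 0.5`.
#'
#' @param f allele frequency in (0, 1).
#' @return numeric.
#' @export
hetRandom <- function(f) {
    if (any(f <= 0 | f >= 1)) stop("f must be in (0, 1)", call. = FALSE)
    2 * f * (1 - f)
}

#' Heterozygosity enrichment near the disease variant
#'
#' The ratio of [hetNearDisease()] over [hetRandom()],
#' `r = 1 / (2 f (1 - e)) > 1 / (2 f)`: large for the rare markers that
#' matter most, which is why a window of low-frequency variants lights up
#' around an inherited dominant variant.
#'
#' @inheritParams hetNearDisease
#' @return numeric ratio.
#' @examples
#' hetRatio(0.01, 0.1)  # about 5.05
#' @export
hetRatio <- function(e, f) {
    hetNearDisease(e, f)  # validates, incl. e <= f
    1 / (2 * f * (1 - e))
}
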