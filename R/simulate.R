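#' Build a synthetic-cohort configuration
#'
#' See [SimConfig-class] for the meaning and defaults of every
#' parameter.  The defaults are the package's reference study
#' conditions; tests and worked examples use them unchanged.
#'
#' @param nVariants,nChromosomes,chromLengthBp genome layout.
#' @param mafShape1,mafShape2,mafMin,mafMax marker allele-frequency law:
#'   `f = max(mafMin, mafMax * Beta(mafShape1, mafShape2))`.
#' @param diseaseChrom,diseasePos planted dominant variant.
#' @param RHalfwidthBp unrecombined founder region half-width.
#' @param nCarriers,nNoncarriers cohort composition.
#' @param missingRate per-genotype missingness.
#' @param founderMinor founder haplotype carries the minor allele at
#'   every marker in R (default `TRUE`; see the package vignette).
#' @param seed default seed for [simulateCohort()].
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nVariants = 500, nChromosomes = 2)
#' @export
simConfig <- function(nVariants = 2000L, nChromosomes = 3L,
                      chromLengthBp = 2e6, mafShape1 = 1, mafShape2 = 4,
                      mafMin = 0.005, mafMax = 0.5,
                      diseaseChrom = "chr1", diseasePos = 1e6,
                      RHalfwidthBp = 5e4, nCarriers = 3L,
                      nNoncarriers = 3L, missingRate = 0.02,
                      founderMinor = TRUE, seed = NA_real_) {
    new("SimConfig", nVariants = as.integer(nVariants),
        nChromosomes = as.integer(nChromosomes),
        chromLengthBp = as.numeric(chromLengthBp),
        mafShape1 = mafShape1, mafShape2 = mafShape2,
        mafMin = mafMin, mafMax = mafMax,
        diseaseChrom = diseaseChrom, diseasePos = as.numeric(diseasePos),
        RHalfwidthBp = as.numeric(RHalfwidthBp),
        nCarriers = as.integer(nCarriers),
        nNoncarriers = as.integer(nNoncarriers),
        missingRate = missingRate, founderMinor = founderMinor,
        seed = as.numeric(seed))
}

#' Simulate a cohort with a planted inherited dominant variant
#'
#' Generates a truth-labeled multi-sample genotype set.  Marker
#' positions are uniform within each chromosome; each marker's ALT
#' (minor) allele frequency `f` is drawn from the configured law.
#' Noncarriers, and carriers outside the unrecombined region R, receive
#' two independent allele draws at frequency `f` (Hardy-Weinberg).
#' Inside R every carrier shares one fixed founder haplotype (by
#' default carrying the minor allele at each marker, the three-haplotype
#' `D = Dmax` regime of [hetNearDisease()]); the homologous chromosome
#' is a fresh population draw, so the per-site carrier heterozygosity in
#' R follows `(1 - f) / (1 - e)` with `e -> 0`.  The disease variant
#' itself is emitted as a site at `diseasePos` (heterozygous in
#' carriers, homozygous reference in noncarriers).  Missingness is
#' applied independently per genotype.  The generator is deterministic
#' given `seed`: the same seed yields a byte-identical VCF.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed (defaults to `config@seed`; required).  The
#'   caller's RNG state is left untouched.
#' @param vcfPath optional path; when given the cohort is also written
#'   as VCF 4.2 via [writeVCF()].
#' @return list with elements `genotypes` (a [GenotypeMatrix-class] with
#'   `calls` and `dosage` assays) and `truth` (a [CohortTruth-class]).
#' @examples
#' sim <- simulateCohort(simConfig(nVariants = 300, nChromosomes = 1,
#'                                 diseasePos = 1e6), seed = 1)
#' sim$truth
#' @export
simulateCohort <- function(config, seed = config@seed, vcfPath = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (is.na(seed))
        stop("a seed is required for reproducible simulation",
             call. = FALSE)
    carriers <- if (config@nCarriers)
        paste0("carrier", seq_len(config@nCarriers)) else character(0)
    noncarriers <- if (config@nNoncarriers)
        paste0("noncarrier", seq_len(config@nNoncarriers)) else character(0)
    samples <- c(carriers, noncarriers)
    if (!length(samples))
        stop("cohort must contain at least one sample", call. = FALSE)
    lo <- config@diseasePos - config@RHalfwidthBp
    hi <- config@diseasePos + config@RHalfwidthBp
    if (lo < 1 || hi > config@chromLengthBp) {
        warning("region R extends past the chromosome end; truncated",
                call. = FALSE)
        lo <- max(1, lo); hi <- min(config@chromLengthBp, hi)
    }
    chromNames <- paste0("chr", seq_len(config@nChromosomes))
    out <- withLocalSeed(seed, {
        lapply(chromNames, function(cn)
            .simChrom(config, cn, chromNames, carriers, noncarriers,
                      lo, hi))
    })
    sites <- do.call(c, lapply(out, `[[`, "sites"))
    calls <- do.call(rbind, lapply(out, `[[`, "calls"))
    dosage <- do.call(rbind, lapply(out, `[[`, "dosage"))
    maf <- do.call(c, lapply(out, `[[`, "maf"))
    colnames(calls) <- colnames(dosage) <- samples
    gm <- GenotypeMatrix(sites, calls, dosage = dosage)
    di <- which(chromNames == config@diseaseChrom)
    founder <- out[[di]]$founder
    truth <- new("CohortTruth",
                 diseaseSite = GRanges(config@diseaseChrom,
                                       IRanges(config@diseasePos, width = 1L)),
                 region = GRanges(config@diseaseChrom, IRanges(lo, hi)),
                 carriers = carriers, noncarriers = noncarriers,
                 founder = founder, maf = maf, seed = as.numeric(seed))
    if (!is.null(vcfPath))
        writeVCF(gm, vcfPath)
    list(genotypes = gm, truth = truth)
}

## One chromosome of the simulation.  Draw order is fixed (positions,
## frequencies, founder, haplotypes per sample, missingness) so that a
## given seed reproduces the cohort exactly.
.simChrom <- function(config, chromName, chromNames, carriers,
                      noncarriers, lo, hi) {
    n <- config@nVariants
    onDisease <- chromName == config@diseaseChrom
    pos <- sort(sample.int(config@chromLengthBp, n))
    if (onDisease) {
        pos <- pos[pos != config@diseasePos]
        pos <- sort(c(pos, config@diseasePos))
        n <- length(pos)
        diseaseIdx <- match(config@diseasePos, pos)
    } else {
        diseaseIdx <- NA_integer_
    }
    f <- pmax(config@mafMin,
              config@mafMax * stats::rbeta(n, config@mafShape1,
                                           config@mafShape2))
    inR <- onDisease & pos >= lo & pos <= hi
    founderAllele <- if (config@founderMinor) rep(1L, n) else
        as.integer(stats::rbinom(n, 1L, f))
    nS <- length(carriers) + length(noncarriers)
    hap1 <- hap2 <- matrix(0L, n, nS)
    for (j in seq_len(nS)) {
        isCarrier <- j <= length(carriers)
        a1 <- as.integer(stats::rbinom(n, 1L, f))
        a2 <- as.integer(stats::rbinom(n, 1L, f))
        if (isCarrier && any(inR))
            a1[inR] <- founderAllele[inR]
        hap1[, j] <- a1
        hap2[, j] <- a2
    }
    dosage <- hap1 + hap2
    calls <- matrix(as.integer(hap1 != hap2), n, nS)
    if (onDisease) {
        isCarrier <- seq_len(nS) <= length(carriers)
        calls[diseaseIdx, ] <- as.integer(isCarrier)
        dosage[diseaseIdx, ] <- as.integer(isCarrier)
    }
    if (config@missingRate > 0) {
        miss <- matrix(stats::rbinom(n * nS, 1L, config@missingRate) == 1L,
                       n, nS)
        calls[miss] <- NA_integer_
        dosage[miss] <- NA_integer_
    }
    sites <- GRanges(factor(rep(chromName, n), levels = chromNames),
                     IRanges(pos, width = 1L))
    ids <- sprintf("%s_v%d", chromName, seq_len(n))
    if (onDisease)
        ids[diseaseIdx] <- "disease"
    mcols(sites)$id <- ids
    mcols(sites)$ref <- "A"
    mcols(sites)$alt <- "C"
    maf <- f
    founder <- GRanges()
    if (onDisease) {
        maf[diseaseIdx] <- NA_real_
        keep <- which(inR)
        founder <- GRanges(chromName, IRanges(pos[keep], width = 1L))
        mcols(founder)$allele <- founderAllele[keep]
        mcols(founder)$f <- f[keep]
    }
    list(sites = sites, calls = calls, dosage = dosage, maf = maf,
         founder = founder)
}

#' Nearest-site pseudo-disease target
#'
#' For negative controls a pseudo-disease variant is the site in the
#' data closest to a given position; ranking and significance then treat
#' it exactly like a real target.
#'
#' @param x a [GenotypeMatrix-class].
#' @param chrom chromosome (must be present in `x`).
#' @param pos 1-based query position.
#' @return length-1 `GRanges` of the site minimizing `|pos - query|`;
#'   midpoint ties resolve to the lower position.
#' @export
pseudoDiseaseTarget <- function(x, chrom, pos) {
    rr <- rowRanges(x)
    on <- which(as.character(seqnames(rr)) == as.character(chrom))
    if (!length(on))
        stop("chromosome ", chrom, " not present", call. = FALSE)
    p <- start(rr)[on]
    d <- abs(p - as.numeric(pos))
    best <- on[order(d, p)[1L]]
    rr[best]
}
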