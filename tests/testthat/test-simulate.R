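test_that("the generator is deterministic: same seed, byte-identical VCF", {
    cfg <- simConfig(nVariants = 200L, nChromosomes = 2L,
                     chromLengthBp = 2e5, diseasePos = 1e5,
                     RHalfwidthBp = 3e4)
    p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
    simulateCohort(cfg, seed = 5, vcfPath = p1)
    simulateCohort(cfg, seed = 5, vcfPath = p2)
    expect_identical(readLines(p1), readLines(p2))
    ## a different seed changes the data
    p3 <- tempfile(fileext = ".vcf")
    simulateCohort(cfg, seed = 6, vcfPath = p3)
    expect_false(identical(readLines(p1), readLines(p3)))
    ## seed is mandatory and recorded in the truth
    expect_error(simulateCohort(cfg), "seed is required")
    expect_equal(simulateCohort(cfg, seed = 5)$truth@seed, 5)
})

test_that("a carrier-free cohort is Hardy-Weinberg at every marker", {
    sim <- simulateCohort(simConfig(nVariants = 4000L, nChromosomes = 1L,
                                    chromLengthBp = 4e6, diseasePos = 2e6,
                                    RHalfwidthBp = 1e5, nCarriers = 0L,
                                    nNoncarriers = 8L, missingRate = 0),
                          seed = 13)
    cl <- genotypeCalls(sim$genotypes)
    f <- sim$truth@maf
    keep <- !is.na(f)                        # drop the disease site itself
    hetObs <- mean(cl[keep, ] == 1L)
    hetExp <- mean(2 * f[keep] * (1 - f[keep]))
    nObs <- sum(keep) * ncol(cl)
    se <- sqrt(hetExp * (1 - hetExp) / nObs)
    expect_lt(abs(hetObs - hetExp), 3 * se)
})

test_that("carrier heterozygosity matches the closed-form model in and out of R", {
    ## fixed f = 0.1, founder carrying the minor allele, e -> 0:
    ## expected per-site heterozygosity (1-f)/(1-e) -> 0.9 inside R,
    ## 2f(1-f) = 0.18 outside
    sim <- simulateCohort(simConfig(nVariants = 4000L, nChromosomes = 1L,
                                    chromLengthBp = 4e6, diseasePos = 2e6,
                                    RHalfwidthBp = 5e5,
                                    mafMin = 0.1, mafMax = 0.1,
                                    nCarriers = 10L, nNoncarriers = 0L,
                                    missingRate = 0), seed = 17)
    cl <- genotypeCalls(sim$genotypes)
    sites <- variantSites(sim$genotypes)
    inR <- start(sites) >= start(sim$truth@region) &
           start(sites) <= end(sim$truth@region) &
           !is.na(sim$truth@maf)
    outR <- !inR & !is.na(sim$truth@maf)
    hIn <- mean(cl[inR, ] == 1L)
    hOut <- mean(cl[outR, ] == 1L)
    eIn <- hetNearDisease(1e-12, 0.1)        # 0.9
    eOut <- hetRandom(0.1)                   # 0.18
    expect_lt(abs(hIn - eIn), 3 * sqrt(eIn * (1 - eIn) / (sum(inR) * 10)))
    expect_lt(abs(hOut - eOut), 3 * sqrt(eOut * (1 - eOut) / (sum(outR) * 10)))
})

test_that("population-frequency founders give no average excess in R", {
    ## with founderMinor = FALSE the founder haplotype is a random
    ## population draw and carrier heterozygosity in R stays at the
    ## Hardy-Weinberg level: this is why the default plants the
    ## minor-allele founder
    sim <- simulateCohort(simConfig(nVariants = 4000L, nChromosomes = 1L,
                                    chromLengthBp = 4e6, diseasePos = 2e6,
                                    RHalfwidthBp = 5e5,
                                    mafMin = 0.1, mafMax = 0.1,
                                    nCarriers = 10L, nNoncarriers = 0L,
                                    missingRate = 0, founderMinor = FALSE),
                          seed = 19)
    cl <- genotypeCalls(sim$genotypes)
    sites <- variantSites(sim$genotypes)
    inR <- start(sites) >= start(sim$truth@region) &
           start(sites) <= end(sim$truth@region) &
           !is.na(sim$truth@maf)
    hIn <- mean(cl[inR, ] == 1L)
    expect_lt(abs(hIn - 0.18), 3 * sqrt(0.18 * 0.82 / (sum(inR) * 10)))
})

test_that("truth record is consistent with the emitted genotypes", {
    cfg <- simConfig(nVariants = 500L, nChromosomes = 2L,
                     chromLengthBp = 5e5, diseasePos = 2.5e5,
                     RHalfwidthBp = 5e4, missingRate = 0)
    sim <- simulateCohort(cfg, seed = 23)
    gm <- sim$genotypes; tr <- sim$truth
    expect_equal(colnames(gm), c(tr@carriers, tr@noncarriers))
    expect_equal(length(tr@maf), nVariants(gm))
    ## the disease site exists, heterozygous in carriers, homozygous in
    ## noncarriers
    di <- which(as.character(seqnames(variantSites(gm))) == "chr1" &
                start(variantSites(gm)) == 2.5e5)
    expect_length(di, 1)
    expect_true(all(genotypeCalls(gm)[di, tr@carriers] == 1L))
    expect_true(all(genotypeCalls(gm)[di, tr@noncarriers] == 0L))
    ## founder annotations cover exactly the markers inside R
    expect_true(all(start(tr@founder) >= start(tr@region)))
    expect_true(all(end(tr@founder) <= end(tr@region)))
    ## default founder carries the minor allele everywhere in R
    expect_true(all(mcols(tr@founder)$allele == 1L))
})

test_that("region R is truncated at the chromosome end with a warning", {
    cfg <- simConfig(nVariants = 200L, nChromosomes = 1L,
                     chromLengthBp = 1e5, diseasePos = 1e4,
                     RHalfwidthBp = 5e4)
    expect_warning(sim <- simulateCohort(cfg, seed = 29), "truncated")
    expect_equal(start(sim$truth@region), 1)
    expect_equal(end(sim$truth@region), 6e4)
})

test_that("pseudo-disease lookup returns the nearest site, lower position on ties", {
    gm <- toyMatrix(matrix(0L, 5, 1), pos = c(100L, 200L, 300L, 500L, 900L))
    expect_equal(start(pseudoDiseaseTarget(gm, "chr1", 300)), 300)
    expect_equal(start(pseudoDiseaseTarget(gm, "chr1", 400)), 300)  # midpoint
    expect_equal(start(pseudoDiseaseTarget(gm, "chr1", 650)), 500)
    expect_error(pseudoDiseaseTarget(gm, "chr9", 100), "not present")
    ## linear-scan oracle on random queries
    set.seed(31)
    pos <- sort(sample.int(1e5, 80))
    gm2 <- toyMatrix(matrix(0L, 80, 1), pos = pos)
    for (q in sample.int(1e5, 25)) {
        d <- abs(pos - q)
        best <- pos[d == min(d)]
        expect_equal(start(pseudoDiseaseTarget(gm2, "chr1", q)), min(best))
    }
})

test_that("a noncarrier scan shows no localized peak in R", {
    ## across seeds, the max H inside R should beat a random same-width
    ## region only about half the time
    wins <- 0L
    nSeeds <- 20L
    for (s in seq_len(nSeeds)) {
        sim <- simulateCohort(simConfig(nVariants = 1200L, nChromosomes = 1L,
                                        chromLengthBp = 1.2e6,
                                        diseasePos = 6e5,
                                        RHalfwidthBp = 1e5, nCarriers = 0L,
                                        nNoncarriers = 4L), seed = 100 + s)
        tr <- computeHTrack(sim$genotypes, m = 50)
        pos <- start(variantSites(tr))
        H <- hValues(tr)
        inR <- pos >= 5e5 & pos <= 7e5
        set.seed(200 + s)
        lo <- sample(seq(min(pos), max(pos) - 2e5), 1)
        inRand <- pos >= lo & pos <= lo + 2e5
        if (max(H[inR]) > max(H[inRand])) wins <- wins + 1L
    }
    ## 3-SE band around 0.5 for 20 Bernoulli trials
    expect_gte(wins, 4L)
    expect_lte(wins, 16L)
})
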