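test_that("segmentation reproduces hand-traced rise-then-fall runs", {
    ## single run covering all points
    s1 <- as.data.frame(segmentRIH(HetScan:::.toyTrack(c(.1, .2, .3, .2, .1))))
    expect_equal(nrow(s1), 1)
    expect_equal(s1$startPos, 1000); expect_equal(s1$endPos, 5000)
    expect_equal(s1$hmax, 0.3); expect_equal(s1$hmaxPos, 3000)
    ## plateau absorbed by zero-difference skipping
    s2 <- as.data.frame(segmentRIH(HetScan:::.toyTrack(c(.1, .2, .2, .3, .1))))
    expect_equal(nrow(s2), 1)
    expect_equal(s2$startPos, 1000); expect_equal(s2$endPos, 5000)
    expect_equal(s2$hmax, 0.3)
    ## leading strictly-falling prefix is unassigned
    s3 <- as.data.frame(segmentRIH(HetScan:::.toyTrack(c(.3, .2, .1, .2, .3, .2))))
    expect_equal(nrow(s3), 1)
    expect_equal(s3$startPos, 3000); expect_equal(s3$endPos, 6000)
    expect_equal(s3$hmax, 0.3); expect_equal(s3$hmaxPos, 5000)
    ## adjacent segments stay disjoint; the shared minimum closes the fall
    s4 <- as.data.frame(segmentRIH(
        HetScan:::.toyTrack(c(.1, .2, .3, .2, .1, .2, .3, .2))))
    expect_equal(nrow(s4), 2)
    expect_equal(s4$startPos, c(1000, 6000))
    expect_equal(s4$endPos, c(5000, 8000))
    ## a terminal rise that never falls forms no segment
    s5 <- as.data.frame(segmentRIH(HetScan:::.toyTrack(c(.3, .1, .2, .3, .4))))
    expect_equal(nrow(s5), 0)
})

test_that("constant H yields zero segments with a warning", {
    expect_warning(sg <- segmentRIH(HetScan:::.toyTrack(rep(.4, 6))),
                   "constant H")
    expect_equal(length(sg), 0)
})

test_that("segmentation agrees with the independent bracketing oracle", {
    set.seed(515)
    for (rep in 1:40) {
        n <- sample(5:60, 1)
        ## coarse grid makes plateaus and ties common
        h <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
        tr <- HetScan:::.toyTrack(h)
        got <- suppressWarnings(as.data.frame(segmentRIH(tr)))
        ref <- bracketSegments(h)
        if (is.null(ref) || nrow(ref) == 0) {
            expect_equal(nrow(got), 0, info = paste(h, collapse = ","))
        } else {
            expect_equal(got$startPos, ref$startIdx * 1000,
                         info = paste(h, collapse = ","))
            expect_equal(got$endPos, ref$endIdx * 1000)
            expect_equal(got$hmax, ref$hmax)
            expect_equal(got$hmaxPos, ref$hmaxIdx * 1000)
        }
    }
})

test_that("segments are disjoint, sorted, unimodal, and hmax is the member maximum", {
    set.seed(616)
    for (rep in 1:15) {
        h <- round(runif(80), 2)
        tr <- HetScan:::.toyTrack(h)
        sg <- suppressWarnings(segmentRIH(tr))
        if (!length(sg)) next
        mc <- mcols(segmentRanges(sg))
        expect_true(all(diff(mc$startIdx) > 0))
        expect_true(all(mc$startIdx[-1] > mc$endIdx[-length(sg)]))
        for (k in seq_len(length(sg))) {
            member <- h[mc$startIdx[k]:mc$endIdx[k]]
            expect_equal(mc$hmax[k], max(member))
            ## rise-then-fall after collapsing equal neighbours
            v <- member[c(TRUE, diff(member) != 0)]
            pk <- which.max(v)
            expect_true(all(diff(v[seq_len(pk)]) > 0))
            if (pk < length(v))
                expect_true(all(diff(v[pk:length(v)]) < 0))
        }
    }
})

test_that("mean segment length is the plain arithmetic mean", {
    sg <- segmentRIH(HetScan:::.toyTrack(c(.1, .3, .1)))
    expect_equal(meanSegmentLength(sg), 2000)
    set.seed(717)
    h <- round(runif(200), 2)
    sg2 <- suppressWarnings(segmentRIH(HetScan:::.toyTrack(h)))
    expect_equal(meanSegmentLength(sg2),
                 mean(as.data.frame(sg2)$lengthBp))
    expect_equal(meanSegmentLength(sg2, unit = "variants"),
                 mean(as.data.frame(sg2)$nVariants))
})

test_that("Stage-2 ranking and the w/4, w/2, w length filters behave", {
    ## three bumps with hmax .9 / .8 / .7; target sits in the .8 bump
    h <- c(.1, .9, .1, .2, .8, .2, .1, .7, .1)
    tr <- HetScan:::.toyTrack(h)
    sg <- segmentRIH(tr)
    expect_equal(length(sg), 3)
    r <- rankHmax(sg, tr, "chr1", 5000)
    expect_equal(r@status, "ok")
    expect_equal(r@rank, 2)
    expect_equal(r@hmax, 0.8)
    ## d: hmax position of the containing segment vs target
    expect_equal(r@d, 0)
    expect_equal(rankHmax(sg, tr, "chr1", 4000)@d, 1000)
    ## equal-length segments survive every filter; ranks never worsen
    expect_equal(r@rank2, 2); expect_equal(r@rank3, 2); expect_equal(r@rank4, 2)
})

test_that("a short target segment is excluded by the length filters", {
    ## narrow spike (length 2000 bp) beside one broad segment (8000 bp)
    h <- c(.1, .9, .1, .15, .2, .3, .5, .6, .5, .3, .1)
    tr <- HetScan:::.toyTrack(h)
    sg <- segmentRIH(tr)
    expect_equal(length(sg), 2)
    r <- suppressMessages(rankHmax(sg, tr, "chr1", 2000))
    expect_equal(r@rank, 1)       # the spike has the larger hmax
    expect_true(is.na(r@rank4))   # but is shorter than the mean length
    ## the surviving broad segment keeps a rank no worse than unfiltered
    rb <- rankHmax(sg, tr, "chr1", 8000)
    expect_true(all(c(rb@rank2, rb@rank3, rb@rank4) <= rb@rank, na.rm = TRUE))
})

test_that("targets outside any RIH report the explicit n state", {
    h <- c(.5, .4, .3, .4, .5, .4)   # leading fall is unassigned
    tr <- HetScan:::.toyTrack(h)
    sg <- segmentRIH(tr)
    r <- rankHmax(sg, tr, "chr1", 1000)
    expect_equal(r@status, "not_in_RIH")
    expect_true(is.na(r@rank))
    ## no Stage-1 value propagates its own state
    r2 <- rankHmax(sg, tr, "chr1", 99999)
    expect_equal(r2@status, "no_H")
})

test_that("variant-count lengths are available as an alternative filter unit", {
    h <- c(.1, .9, .1, .15, .2, .3, .5, .6, .5, .3, .1)
    tr <- HetScan:::.toyTrack(h)
    sg <- segmentRIH(tr)
    r <- suppressMessages(rankHmax(sg, tr, "chr1", 2000,
                                   lengthUnit = "variants"))
    expect_equal(r@w, mean(as.data.frame(sg)$nVariants))
})

test_that("BED export uses the 0-based half-open convention", {
    tr <- HetScan:::.toyTrack(c(.1, .3, .1))
    sg <- segmentRIH(tr)
    path <- tempfile(fileext = ".bed")
    exportSegmentsBED(sg, path)
    ln <- readLines(path)
    row <- strsplit(ln[!grepl("^##", ln)], "\t")[[1]]
    expect_equal(as.integer(row[2]), 999)
    expect_equal(as.integer(row[3]), 3000)
})
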