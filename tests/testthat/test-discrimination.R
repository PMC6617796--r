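test_that("the bundled score set loads with its published layout", {
    sc <- carrierScores()
    expect_equal(nrow(sc), 17)
    expect_equal(sum(sc$label == "C"), 9)
    expect_equal(sum(sc$label == "N"), 8)
    expect_true(all(sc$topPct > 0 & sc$topPct <= 100))
})

test_that("threshold classification reproduces the published operating points", {
    sc <- carrierScores()
    at182 <- classifyThreshold(sc, 18.2)
    expect_equal(at182$sensitivity, 4 / 9, tolerance = 1e-12)
    expect_equal(at182$specificity, 0.750)
    ## six individuals fall below the 18.2 cut
    expect_equal(sum(sc$topPct < 18.2), 6)
    at21 <- classifyThreshold(sc, 21)
    expect_equal(at21$sensitivity, 8 / 9, tolerance = 1e-12)
    expect_equal(at21$specificity, 0.750)
    expect_equal(at21$totalCorrect, 14 / 17, tolerance = 1e-12)
})

test_that("degenerate thresholds give the degenerate corners", {
    sc <- carrierScores()
    hi <- classifyThreshold(sc, max(sc$topPct) + 1)
    expect_equal(hi$sensitivity, 1)
    expect_equal(hi$specificity, 0)
    lo <- classifyThreshold(sc, 0)
    expect_equal(lo$sensitivity, 0)
    expect_equal(lo$specificity, 1)
})

test_that("ROC curve is monotone, ends at the corners, and picks the best cut", {
    roc <- rocCurve(carrierScores())
    expect_true(all(diff(roc@points$fpr) >= 0))
    expect_true(all(diff(roc@points$tpr) >= 0))
    expect_equal(roc@points[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(roc@points[nrow(roc@points), ]),
                 c(fpr = 1, tpr = 1))
    expect_equal(roc@bestSens, 8 / 9, tolerance = 1e-12)
    expect_equal(roc@bestSpec, 0.750)
    expect_equal(roc@bestTotal, 14 / 17, tolerance = 1e-12)
    ## the best cut separates the 20.7 and 22.0 scores
    expect_gt(roc@bestThreshold, 20.7)
    expect_lt(roc@bestThreshold, 22.0)
    ## the packaged rule sits in the same gap with the same characteristics
    expect_gt(carrierCallRule["threshold"], 20.7)
    expect_lt(carrierCallRule["threshold"], 22.0)
})

test_that("trapezoidal AUC equals Mann-Whitney pair concordance", {
    sc <- carrierScores()
    roc <- rocCurve(sc)
    expect_equal(roc@auc, pairConcordance(sc), tolerance = 1e-12)
    expect_equal(pairConcordance(sc), 61 / 72, tolerance = 1e-12)
    ## tied scores get half credit in both routes
    tied <- data.frame(id = letters[1:6], topPct = c(1, 2, 2, 2, 3, 4),
                       label = c("C", "C", "N", "C", "N", "N"))
    expect_equal(rocCurve(tied)@auc, pairConcordance(tied),
                 tolerance = 1e-12)
    ## library cross-check
    skip_if_not_installed("pROC")
    pr <- pROC::roc(response = sc$label, predictor = sc$topPct,
                    levels = c("N", "C"), direction = ">", quiet = TRUE)
    expect_equal(roc@auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and single-class input errors", {
    sep <- data.frame(id = letters[1:6], topPct = c(1, 2, 3, 40, 50, 60),
                      label = c("C", "C", "C", "N", "N", "N"))
    expect_equal(rocCurve(sep)@auc, 1)
    oneClass <- data.frame(id = "a", topPct = 5, label = "C")
    expect_error(rocCurve(oneClass), "carrier and.*noncarrier")
    expect_error(classifyThreshold(oneClass, 10), "carrier and.*noncarrier")
})

test_that("ROC is invariant under strictly monotone score transforms", {
    sc <- carrierScores()
    for (f in list(function(x) log(x), function(x) x^3,
                   function(x) 5 * x + 2)) {
        tf <- sc; tf$topPct <- 100 * (f(sc$topPct) - min(f(sc$topPct)) + 1) /
            (max(f(sc$topPct)) - min(f(sc$topPct)) + 1)
        expect_equal(rocCurve(tf)@auc, rocCurve(sc)@auc, tolerance = 1e-12)
    }
})

test_that("label permutation drives AUC to 0.5 on average", {
    sc <- carrierScores()
    x <- sc$topPct
    rk <- rank(x)
    nC <- 9; nN <- 8
    set.seed(808)
    aucs <- replicate(1e4, {
        nIdx <- sample.int(17, nN)
        (sum(rk[nIdx]) - nN * (nN + 1) / 2) / (nC * nN)
    })
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
    ## the permutation statistic matches the package AUC on the real labels
    nIdx <- which(sc$label == "N")
    expect_equal((sum(rk[nIdx]) - nN * (nN + 1) / 2) / (nC * nN),
                 rocCurve(sc)@auc, tolerance = 1e-12)
})

test_that("best total correct never falls below the majority rule", {
    set.seed(909)
    for (rep in 1:10) {
        n <- sample(6:20, 1)
        sc <- data.frame(id = as.character(seq_len(n)),
                         topPct = runif(n, 1, 99),
                         label = sample(c("C", "N"), n, replace = TRUE))
        if (length(unique(sc$label)) < 2) next
        roc <- rocCurve(sc)
        prev <- mean(sc$label == "C")
        expect_gte(roc@bestTotal, max(prev, 1 - prev) - 1e-12)
    }
})

test_that("score IO validates labels and range and round-trips", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("id\ttopPct\tlabel", "a\t5\tC", "b\t50\tN"), path)
    sc <- readScores(path)
    expect_equal(sc$topPct, c(5, 50))
    writeLines(c("id\ttopPct\tlabel", "a\t5\tX"), path)
    expect_error(readScores(path), "'C' or 'N'")
    writeLines(c("id\ttopPct\tlabel", "a\t0\tC", "b\t2\tN"), path)
    expect_error(readScores(path), "\\(0, 100\\]")
    roc <- rocCurve(carrierScores())
    pts <- tempfile(); smry <- tempfile()
    exportROC(roc, pts, smry)
    js <- jsonlite::read_json(smry)
    expect_equal(js$auc, roc@auc, tolerance = 1e-12)
})
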