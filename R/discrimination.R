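#' Read labeled top-percent scores
#'
#' Loads a tab-separated table of per-individual Stage-1 top-percent
#' scores with carrier labels: columns `id`, `topPct`, `label` (`"C"`
#' carrier / `"N"` noncarrier).
#'
#' @param path TSV file.
#' @return `data.frame` with columns `id` (character), `topPct`
#'   (numeric in (0, 100]) and `label` (character, `"C"`/`"N"`).
#' @export
readScores <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("id", "topPct", "label")
    if (!all(need %in% colnames(df)))
        stop("score table needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (!all(df$label %in% c("C", "N")))
        stop("labels must be 'C' or 'N'", call. = FALSE)
    if (any(df$topPct <= 0 | df$topPct > 100))
        stop("topPct must lie in (0, 100]", call. = FALSE)
    df[need]
}

#' Bundled carrier/noncarrier score set
#'
#' The package ships the published score table of nine carriers and
#' eight noncarriers of known dominant pathogenic variants (breast
#' cancer, neuroblastoma and hearing-impairment families plus control
#' individuals assigned pseudo-disease variants): each row is one
#' analyzed individual with the Stage-1 top-percent of its (pseudo-)
#' disease variant.  Low top-percent indicates a carrier.
#'
#' @return `data.frame` as from [readScores()]; 17 rows.
#' @examples
#' rocCurve(carrierScores())
#' @export
carrierScores <- function() {
    readScores(system.file("extdata", "carrier_scores.tsv",
                           package = "HetScan", mustWork = TRUE))
}

#' Published Stage-2 rank table for one breast-cancer family
#'
#' Per-individual Stage-2 (`H_max`) genome-wide ranks of the known
#' pathogenic variant for the three carriers and three noncarriers of
#' the bundled breast-cancer family, used for aggregate comparisons of
#' carrier vs noncarrier ranking.
#'
#' @return `data.frame` with columns `id`, `stage2Rank`, `label`.
#' @export
familyStage2Ranks <- function() {
    df <- utils::read.delim(system.file("extdata", "family_stage2_ranks.tsv",
                                        package = "HetScan",
                                        mustWork = TRUE),
                            stringsAsFactors = FALSE, comment.char = "#")
    df
}

#' Threshold classification of carriers by top-percent
#'
#' Predicts an individual to be a carrier when its top-percent score lies
#' *below* the threshold (a small top-percent means the target's `H`
#' ranks high genome-wide, the carrier signature).
#'
#' @param scores `data.frame` as from [readScores()] (needs at least one
#'   carrier and one noncarrier).
#' @param threshold top-percent cut; scores strictly below it predict
#'   carrier.  A threshold of 0 or less predicts everyone noncarrier (a
#'   valid degenerate operating point).
#' @return named list: `sensitivity` (carriers predicted carriers),
#'   `specificity` (noncarriers predicted noncarriers), `totalCorrect`.
#' @examples
#' classifyThreshold(carrierScores(), 18.2)  # sens 4/9, spec 6/8
#' @export
classifyThreshold <- function(scores, threshold) {
    .checkScores(scores)
    pred <- scores$topPct < threshold
    isC <- scores$label == "C"
    tp <- sum(pred & isC); fn <- sum(!pred & isC)
    tn <- sum(!pred & !isC); fp <- sum(pred & !isC)
    list(sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         totalCorrect = (tp + tn) / nrow(scores))
}

.checkScores <- function(scores) {
    if (!all(c("topPct", "label") %in% colnames(scores)))
        stop("scores need 'topPct' and 'label' columns", call. = FALSE)
    if (!any(scores$label == "C") || !any(scores$label == "N"))
        stop("need at least one carrier and one noncarrier",
             call. = FALSE)
    invisible(TRUE)
}

#' ROC curve, AUC and best threshold for carrier discrimination
#'
#' Sweeps a cut just above each distinct observed top-percent
#' (equivalently: predict carrier iff `topPct <= s` for each observed
#' `s`), plus the degenerate endpoints, and plots sensitivity against
#' 1 - specificity.  The AUC is the trapezoidal area, which equals the
#' Mann-Whitney concordance probability (with half credit for ties) that
#' a random carrier scores below a random noncarrier.  The best
#' threshold maximizes the total probability of correct prediction, ties
#' resolved toward higher specificity, and is reported midway between
#' the adjacent observed scores.
#'
#' @param scores `data.frame` as from [readScores()]; both classes must
#'   be present (AUC is undefined otherwise).
#' @return a [ROCResult-class].
#' @examples
#' roc <- rocCurve(carrierScores())
#' roc  # AUC 0.85 on the bundled 17-individual set
#' @export
rocCurve <- function(scores) {
    .checkScores(scores)
    isC <- scores$label == "C"
    x <- scores$topPct
    ## -Inf is the degenerate predict-nobody cut
    cuts <- c(-Inf, sort(unique(x)))
    nC <- sum(isC); nN <- sum(!isC)
    sens <- vapply(cuts, function(s) sum(isC & x <= s) / nC, numeric(1))
    spec <- vapply(cuts, function(s) sum(!isC & x > s) / nN, numeric(1))
    total <- vapply(cuts, function(s)
        (sum(isC & x <= s) + sum(!isC & x > s)) / length(x), numeric(1))
    pts <- data.frame(fpr = c(1 - spec, 1), tpr = c(sens, 1))
    pts <- unique(pts[order(pts$fpr, pts$tpr), ])
    rownames(pts) <- NULL
    auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
    best <- which(total == max(total))
    best <- best[which.max(spec[best])]
    s <- cuts[best]
    above <- cuts[is.finite(cuts) & cuts > s]
    thr <- if (is.infinite(s)) min(x)
           else if (length(above)) (s + min(above)) / 2
           else s + 1
    new("ROCResult", points = pts, auc = auc, bestThreshold = thr,
        bestSens = sens[best], bestSpec = spec[best],
        bestTotal = total[best], n = nrow(scores))
}

#' Packaged carrier-call rule
#'
#' The empirical decision rule estimated from the bundled 17-individual
#' score set ([carrierScores()]): declare a candidate variant a true
#' positive when the individual's Stage-1 top-percent is smaller than
#' 21%.  Estimated operating characteristics at that cut: sensitivity
#' 0.889, specificity 0.750, total correct 0.824 — the maximum over all
#' cuts for those data.  With n = 17 these estimates are coarse; treat
#' the rule as a screening heuristic, not a calibrated classifier.
#'
#' @format named numeric vector with elements `threshold`,
#'   `sensitivity`, `specificity`, `totalCorrect`.
#' @export
carrierCallRule <- c(threshold = 21, sensitivity = 0.889,
                     specificity = 0.750, totalCorrect = 0.824)

#' Export ROC results
#'
#' Writes the ROC points as TSV and the summary (`auc`, `bestThreshold`,
#' `bestSens`, `bestSpec`, `bestTotal`, `n`) as JSON.
#'
#' @param roc a [ROCResult-class].
#' @param pointsPath TSV output for the curve points.
#' @param summaryPath JSON output for the summary.
#' @return `summaryPath`, invisibly.
#' @export
exportROC <- function(roc, pointsPath, summaryPath) {
    con <- file(pointsPath, "w")
    writeLines(provenanceHeader(list(n = roc@n)), con)
    writeLines("fpr\ttpr", con)
    writeLines(sprintf("%.6f\t%.6f", roc@points$fpr, roc@points$tpr), con)
    close(con)
    jsonlite::write_json(
        list(auc = roc@auc, bestThreshold = roc@bestThreshold,
             bestSens = roc@bestSens, bestSpec = roc@bestSpec,
             bestTotal = roc@bestTotal, n = roc@n),
        summaryPath, auto_unbox = TRUE, digits = NA)
    invisible(summaryPath)
}
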