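test_that("confusion tallies hard predictions with nephrotoxic positive", {
    labels <- c(1, 1, 1, 0, 0, 0)
    expect_identical(counts(confusion(labels, labels)),
        c(tp = 3, fp = 0, tn = 3, fn = 0))
    expect_identical(counts(confusion(labels, 1 - labels)),
        c(tp = 0, fp = 3, tn = 0, fn = 3))
    # hand-counted 6-item toy
    pred <- c(1, 0, 1, 1, 0, 0)
    expect_identical(counts(confusion(labels, pred)),
        c(tp = 2, fp = 1, tn = 2, fn = 1))
    expect_error(confusion(labels, pred[-1]), "aligned")
})

test_that("Q/SE/SP follow their definitions on printed-table scale", {
    cm <- ConfusionMatrix(tp = 48, fp = 7, tn = 47, fn = 7)
    expect_equal(round(totalAccuracy(cm), 2), 87.16)
    expect_equal(round(sensitivity(cm), 2), 87.27)
    expect_equal(round(specificity(cm), 2), 87.04)
    perfect <- ConfusionMatrix(1, 0, 1, 0)
    expect_equal(totalAccuracy(perfect), 100)
    expect_equal(sensitivity(perfect), 100)
    expect_equal(specificity(perfect), 100)
    # degenerate: no positive labels -> SE undefined, flagged
    expect_warning(se <- sensitivity(ConfusionMatrix(0, 0, 5, 0)),
        "undefined")
    expect_true(is.na(se))
})

test_that("the enrichment factor is negative-class enrichment as defined", {
    cm <- ConfusionMatrix(tp = 48, fp = 7, tn = 47, fn = 7)
    expect_equal(round(enrichmentFactor(cm), 2), 1.76)
    expect_equal(round(enrichmentFactor(
        ConfusionMatrix(47, 7, 47, 8)), 2), 1.72)
    # the all-negative predictor scores exactly 1 for every class balance
    for (b in list(c(10, 10), c(3, 17), c(19, 1)))
        expect_equal(enrichmentFactor(
            ConfusionMatrix(0, 0, b[2], b[1])), 1)
})

test_that("MCC matches printed values, bounds, and antisymmetry", {
    expect_equal(round(matthewsCC(ConfusionMatrix(48, 7, 47, 7)), 2), 0.74)
    expect_equal(round(matthewsCC(ConfusionMatrix(47, 10, 44, 8)), 2), 0.67)
    expect_equal(matthewsCC(ConfusionMatrix(9, 0, 11, 0)), 1)
    expect_warning(z <- matthewsCC(ConfusionMatrix(0, 0, 5, 5)),
        "undefined")
    expect_identical(z, 0)
    # inverting the predicted classes (tp<->fp, tn<->fn) negates MCC
    set.seed(5)
    for (k in 1:20) {
        v <- sample(1:30, 4, replace = TRUE)
        cm <- ConfusionMatrix(v[1], v[2], v[3], v[4])
        inv <- ConfusionMatrix(v[2], v[1], v[4], v[3])
        expect_equal(matthewsCC(inv), -matthewsCC(cm))
        expect_true(abs(matthewsCC(cm)) <= 1)
    }
})

test_that("Q decomposes exactly into class-weighted SE and SP", {
    set.seed(8)
    for (k in 1:20) {
        v <- sample(0:25, 4, replace = TRUE)
        if (v[1] + v[4] == 0 || v[2] + v[3] == 0) next
        cm <- ConfusionMatrix(v[1], v[2], v[3], v[4])
        n_pos <- v[1] + v[4]; n_neg <- v[2] + v[3]
        expect_equal(totalAccuracy(cm) * (n_pos + n_neg),
            sensitivity(cm) * n_pos + specificity(cm) * n_neg)
    }
})

test_that("rank AUC equals exhaustive pair counting", {
    expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
    expect_equal(rocAuc(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
    set.seed(3)
    for (k in 1:15) {
        n <- sample(6:12, 1)
        labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
        scores <- round(runif(n), 1)    # coarse grid forces ties
        expect_equal(rocAuc(scores, labels), oracle_auc(scores, labels))
    }
    expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curves start at (0,0), end at (1,1), and are monotone", {
    set.seed(14)
    scores <- runif(20); labels <- rbinom(20, 1, 0.5)
    labels[1:2] <- c(0, 1)
    rc <- rocCurve(scores, labels)
    expect_equal(unlist(rc[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
    expect_equal(unlist(rc[nrow(rc), c("fpr", "tpr")],
        use.names = FALSE), c(1, 1))
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("confusion matrices reconstruct from printed SE/SP", {
    expect_identical(counts(reconstructConfusion(87.27, 87.04, 55, 54)),
        c(tp = 48, fp = 7, tn = 47, fn = 7))
    expect_identical(counts(reconstructConfusion(100, 100, 5, 5)),
        c(tp = 5, fp = 0, tn = 5, fn = 0))
    # 0.8545 * 55 = 46.9975 -> 47; re-applying SE/SP confirms
    cm <- reconstructConfusion(85.45, 87.04, 55, 54)
    expect_identical(counts(cm), c(tp = 47, fp = 7, tn = 47, fn = 8))
    expect_equal(round(sensitivity(cm), 2), 85.45)
    expect_equal(round(specificity(cm), 2), 87.04)
    expect_error(reconstructConfusion(104, 50, 10, 10), "0, 100")
})

test_that("every external-validation row reproduces from its SE/SP", {
    rows <- table3_rows()
    for (i in seq_len(nrow(rows))) {
        cm <- reconstructConfusion(rows$se[i], rows$sp[i], 55, 54)
        expect_equal(round(totalAccuracy(cm), 2), rows$q[i],
            label = rows$model[i])
        expect_equal(round(enrichmentFactor(cm), 2), rows$ef[i],
            label = rows$model[i])
        expect_equal(round(matthewsCC(cm), 2), rows$mcc[i],
            label = rows$model[i])
    }
})

test_that("consensus averaging and its tie rule behave as documented", {
    ids <- c("a", "b", "c")
    m1 <- PredictionSet(ids, c(0.9, 0.1, 0.4), labels = c(1, 0, 1))
    m2 <- PredictionSet(ids, c(0.2, 0.3, 0.5))
    m3 <- PredictionSet(ids, c(0.7, 0.2, 0.6), labels = c(1, 0, 1))
    cons <- consensusPredict(list(m1, m2, m3))
    expect_equal(unname(predictionScores(cons)), c(0.6, 0.2, 0.5))
    # labels propagate from whichever member carries them
    expect_identical(unname(compoundLabels(cons)), c(1L, 0L, 1L))
    # mean of 0.6 -> class 1; exact 0.5 tie -> class 1
    expect_identical(classify(cons), c(1L, 0L, 1L))
    # averaging identical members is the identity
    same <- consensusPredict(list(m1, m1))
    expect_equal(predictionScores(same), predictionScores(m1))
    expect_error(consensusPredict(list(m1)), "at least two")
    bad <- PredictionSet(c("a", "b", "x"), c(0.1, 0.2, 0.3))
    expect_error(consensusPredict(list(m1, bad)), "misaligned")
    flipped <- PredictionSet(ids, c(0.1, 0.2, 0.3), labels = c(0, 1, 1))
    expect_error(consensusPredict(list(m1, flipped)), "disagree")
})

test_that("metric reports format to two decimals with flags preserved", {
    cm <- ConfusionMatrix(47, 7, 47, 8)
    m <- metricsReport(cm, auc = 0.93)
    expect_equal(round(unname(m["q"]), 2), 86.24)
    fm <- formatMetrics(m)
    expect_identical(unname(fm["mcc"]), "0.72")
    expect_identical(unname(formatMetrics(c(q = NA_real_))["q"]),
        "undefined")
})

test_that("prediction files round-trip", {
    ps <- PredictionSet(c("a", "b"), c(0.25, 0.75), labels = c(0, 1))
    f <- tempfile(fileext = ".csv")
    writePredictions(ps, f)
    back <- readPredictions(f)
    expect_equal(predictionScores(back), predictionScores(ps))
    expect_identical(compoundLabels(back), compoundLabels(ps))
    f2 <- write_compound_csv(data.frame(compound_id = "a", value = 1))
    expect_error(readPredictions(f2), "score")
})
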