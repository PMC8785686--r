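#' Confusion matrix from labels and hard predictions
#'
#' Label 1 (nephrotoxic) is the positive class.
#'
#' @param labels,predictions aligned 0/1 vectors.
#' @return A [ConfusionMatrix-class].
#' @export
confusion <- function(labels, predictions) {
    labels <- as.integer(labels); predictions <- as.integer(predictions)
    if (length(labels) != length(predictions))
        stop("labels and predictions must be aligned")
    if (!all(c(labels, predictions) %in% c(0L, 1L)))
        stop("labels and predictions must be 0/1")
    ConfusionMatrix(
        tp = sum(predictions == 1L & labels == 1L),
        fp = sum(predictions == 1L & labels == 0L),
        tn = sum(predictions == 0L & labels == 0L),
        fn = sum(predictions == 0L & labels == 1L))
}

#' Confusion-based metric suite
#'
#' The five classifier statistics used throughout the package, on a 2x2
#' confusion matrix with nephrotoxic = positive:
#' \describe{
#'   \item{totalAccuracy}{Q = 100 (TP+TN) / (TP+FN+TN+FP), percent.}
#'   \item{sensitivity}{SE = 100 TP / (TP+FN), percent.}
#'   \item{specificity}{SP = 100 TN / (TN+FP), percent.}
#'   \item{enrichmentFactor}{EF = \[TN/(TN+FN)\] / \[(TN+FP)/total\]: the
#'     precision of negative predictions relative to the negative-class
#'     prevalence. An all-negative predictor scores exactly 1 for every
#'     class balance.}
#'   \item{matthewsCC}{MCC = (TP TN - FP FN) /
#'     sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), in \[-1, 1\].}
#' }
#' Metrics with a zero denominator are undefined and return NA with a
#' warning, except MCC which (by the usual convention) warns and returns 0
#' when a marginal sum is zero.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A single numeric value.
#' @examples
#' cm <- ConfusionMatrix(tp = 48, fp = 7, tn = 47, fn = 7)
#' totalAccuracy(cm)     # 87.16
#' enrichmentFactor(cm)  # 1.76 at 2 d.p.
#' matthewsCC(cm)        # 0.74 at 2 d.p.
#' @name metricSuite
NULL

.cm_counts <- function(cm) {
    stopifnot(is(cm, "ConfusionMatrix"))
    counts(cm)
}

#' @rdname metricSuite
#' @export
totalAccuracy <- function(cm) {
    v <- .cm_counts(cm)
    tot <- sum(v)
    if (tot == 0) {
        warning("total accuracy undefined: empty confusion matrix")
        return(NA_real_)
    }
    100 * (v[["tp"]] + v[["tn"]]) / tot
}

#' @rdname metricSuite
#' @export
sensitivity <- function(cm) {
    v <- .cm_counts(cm)
    if (v[["tp"]] + v[["fn"]] == 0) {
        warning("sensitivity undefined: no positive labels")
        return(NA_real_)
    }
    100 * v[["tp"]] / (v[["tp"]] + v[["fn"]])
}

#' @rdname metricSuite
#' @export
specificity <- function(cm) {
    v <- .cm_counts(cm)
    if (v[["tn"]] + v[["fp"]] == 0) {
        warning("specificity undefined: no negative labels")
        return(NA_real_)
    }
    100 * v[["tn"]] / (v[["tn"]] + v[["fp"]])
}

#' @rdname metricSuite
#' @export
enrichmentFactor <- function(cm) {
    v <- .cm_counts(cm)
    if (v[["tn"]] + v[["fn"]] == 0 || v[["tn"]] + v[["fp"]] == 0) {
        warning("enrichment factor undefined: zero denominator")
        return(NA_real_)
    }
    (v[["tn"]] / (v[["tn"]] + v[["fn"]])) /
        ((v[["tn"]] + v[["fp"]]) / sum(v))
}

#' @rdname metricSuite
#' @export
matthewsCC <- function(cm) {
    v <- .cm_counts(cm)
    tp <- v[["tp"]]; fp <- v[["fp"]]; tn <- v[["tn"]]; fn <- v[["fn"]]
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) {
        warning("MCC undefined (a marginal sum is zero); reporting 0")
        return(0)
    }
    (tp * tn - fp * fn) / sqrt(den)
}

#' Rank-based ROC AUC
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the probability that a random positive scores above a random
#' negative, with ties counted half (midranks).
#'
#' @param x a [PredictionSet-class], or numeric scores.
#' @param labels 0/1 vector (ignored when `x` is a PredictionSet).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))   # 1
#' @export
rocAuc <- function(x, labels = NULL) {
    if (is(x, "PredictionSet")) {
        labels <- compoundLabels(x)
        x <- predictionScores(x)
    }
    labels <- as.integer(labels)
    np <- sum(labels == 1L); nn <- sum(labels == 0L)
    if (np == 0L || nn == 0L)
        stop("both classes must be present to compute AUC")
    r <- rank(x)  # midranks for ties
    (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' @param x a [PredictionSet-class], or numeric scores.
#' @param labels 0/1 vector (ignored when `x` is a PredictionSet).
#' @return data.frame (fpr, tpr, threshold) sweeping the decision threshold
#'   from above the maximum score downwards; suitable for plotting or
#'   writing as CSV.
#' @export
rocCurve <- function(x, labels = NULL) {
    if (is(x, "PredictionSet")) {
        labels <- compoundLabels(x)
        x <- predictionScores(x)
    }
    labels <- as.integer(labels)
    np <- sum(labels == 1L); nn <- sum(labels == 0L)
    if (np == 0L || nn == 0L) stop("both classes must be present")
    thr <- c(Inf, sort(unique(x), decreasing = TRUE))
    pts <- t(vapply(thr, function(t) {
        pred <- x >= t
        c(fpr = sum(pred & labels == 0L) / nn,
          tpr = sum(pred & labels == 1L) / np)
    }, c(fpr = 0, tpr = 0)))
    data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"], threshold = thr)
}

#' Reconstruct integer confusion counts from printed sensitivity/specificity
#'
#' Audit bridge from published percentage tables to exact counts: with the
#' validation class sizes known, TP is the nearest integer to
#' se * n_pos / 100 and TN the nearest integer to sp * n_neg / 100
#' (round half up); FN and FP are the complements. Inputs outside
#' \[0, 100\] are rejected. (A nearest integer is always within 0.5 of the
#' target, so consistently printed percentages always reconstruct; the
#' 0.5 + 1e-9 guard only rejects degenerate input.)
#'
#' @param se_pct,sp_pct printed sensitivity and specificity, percent.
#' @param n_pos,n_neg class sizes of the evaluated set.
#' @return A [ConfusionMatrix-class].
#' @examples
#' # external-validation row: SE 87.27, SP 87.04 over 55 pos / 54 neg
#' counts(reconstructConfusion(87.27, 87.04, 55, 54))  # tp 48 fp 7 tn 47 fn 7
#' @export
reconstructConfusion <- function(se_pct, sp_pct, n_pos, n_neg) {
    if (se_pct < 0 || se_pct > 100 || sp_pct < 0 || sp_pct > 100)
        stop("percentages must lie in [0, 100]")
    tp_t <- se_pct * n_pos / 100
    tn_t <- sp_pct * n_neg / 100
    tp <- .nearest_int(tp_t)
    tn <- .nearest_int(tn_t)
    if (abs(tp - tp_t) > 0.5 + 1e-9 || abs(tn - tn_t) > 0.5 + 1e-9)
        stop("printed percentages are inconsistent with integer counts")
    ConfusionMatrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Consensus of several prediction sets by simple averaging
#'
#' The consensus score of each compound is the arithmetic mean of the member
#' models' scores; the predicted class (see [classify()]) is 1 iff the mean
#' is >= 0.5 (ties classify positive: a toxicity screen prefers
#' sensitivity).
#'
#' @param score_sets list of >= 2 [PredictionSet-class] objects with
#'   identical compound ordering (and consistent labels, where present).
#' @return A [PredictionSet-class] of consensus scores.
#' @export
consensusPredict <- function(score_sets) {
    if (length(score_sets) < 2)
        stop("consensus needs at least two member prediction sets")
    ids <- compoundIds(score_sets[[1]])
    for (s in score_sets[-1])
        if (!identical(compoundIds(s), ids))
            stop("member prediction sets are misaligned (compound ids differ)")
    labs <- compoundLabels(score_sets[[1]])
    for (s in score_sets[-1]) {
        l <- compoundLabels(s)
        both <- !is.na(labs) & !is.na(l)
        if (any(labs[both] != l[both]))
            stop("member prediction sets disagree on labels")
        labs[is.na(labs)] <- l[is.na(labs)]
    }
    scores <- rowMeans(vapply(score_sets,
        function(s) unname(predictionScores(s)),
        numeric(length(ids))))
    PredictionSet(ids, scores, unname(labs))
}

#' Hard classification of scores
#'
#' @param x a [PredictionSet-class] or numeric scores.
#' @param threshold decision threshold (default 0.5); scores equal to the
#'   threshold classify positive.
#' @return Integer 0/1 vector.
#' @export
classify <- function(x, threshold = 0.5) {
    s <- if (is(x, "PredictionSet")) unname(predictionScores(x)) else x
    as.integer(s >= threshold)
}

#' Full metrics report for a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @param auc optional AUC to include.
#' @return Named numeric vector (q, se, sp, ef, mcc, auc) at full
#'   precision; use [formatMetrics()] for the 2-decimal display form.
#' @export
metricsReport <- function(cm, auc = NA_real_) {
    c(q = totalAccuracy(cm), se = sensitivity(cm), sp = specificity(cm),
      ef = enrichmentFactor(cm), mcc = matthewsCC(cm), auc = auc)
}

#' @rdname metricsReport
#' @param metrics a vector as returned by `metricsReport`.
#' @export
formatMetrics <- function(metrics) {
    vapply(metrics, function(v)
        if (is.na(v)) "undefined" else sprintf("%.2f", v), character(1))
}

#' Read / write prediction-score files
#'
#' CSV with header \code{compound_id,score[,label]}.
#'
#' @param path CSV path.
#' @param x a [PredictionSet-class].
#' @return `readPredictions`: a [PredictionSet-class];
#'   `writePredictions`: `path` invisibly.
#' @export
readPredictions <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("compound_id", "score") %in% names(d)))
        stop("prediction CSV needs columns compound_id, score")
    PredictionSet(d$compound_id, d$score,
        labels = if ("label" %in% names(d)) d$label else NA)
}

#' @rdname readPredictions
#' @export
writePredictions <- function(x, path) {
    d <- data.frame(compound_id = compoundIds(x),
        score = unname(predictionScores(x)),
        label = unname(compoundLabels(x)))
    if (all(is.na(d$label))) d$label <- NULL
    write.csv(d, path, row.names = FALSE)
    invisible(path)
}
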