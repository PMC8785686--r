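#' Screen one compound against a set of alert bits
#'
#' A compound is classified nephrotoxic (1) iff its fingerprint sets at
#' least one alert bit; the matched bits are reported for interpretability.
#'
#' @param fingerprint named 0/1 vector (as from [computeFingerprint()]).
#' @param alert_bits character vector of bit ids; must all exist in the
#'   fingerprint.
#' @return list(prediction = 0/1, matched = character vector of set alert
#'   bits).
#' @examples
#' fp <- c(KR3548 = 1L, KR4081 = 0L)
#' screenCompound(fp, "KR3548")
#' @export
screenCompound <- function(fingerprint, alert_bits) {
    unknown <- setdiff(alert_bits, names(fingerprint))
    if (length(unknown))
        stop("alert bit(s) not in fingerprint: ",
             paste(unknown, collapse = ", "))
    matched <- alert_bits[fingerprint[alert_bits] == 1]
    list(prediction = as.integer(length(matched) > 0), matched = matched)
}

#' Screen a compound set with selected alerts
#'
#' Applies the any-alert rule to every row of the fingerprint matrix and
#' tallies the screen statistics: how many compounds carry at least one
#' alert, how many of those are truly nephrotoxic, and the complementary
#' counts for alert-free compounds.
#'
#' @param x a [FingerprintMatrix-class].
#' @param alerts an [AlertSet-class] (its selected bits are used) or a
#'   character vector of bit ids.
#' @param labels 0/1 vector aligned with rows.
#' @return A [ScreenReport-class].
#' @export
screenSet <- function(x, alerts, labels) {
    m <- presenceMatrix(x)
    labels <- as.integer(labels)
    if (length(labels) != nrow(m))
        stop("labels length must equal compound count")
    bits <- if (is(alerts, "AlertSet")) selectedBits(alerts)
        else as.character(alerts)
    unknown <- setdiff(bits, colnames(m))
    if (length(unknown))
        stop("alert bit(s) not in matrix: ", paste(unknown, collapse = ", "))
    sub <- m[, bits, drop = FALSE]
    pred <- as.integer(rowSums(sub) > 0)
    matched <- vapply(seq_len(nrow(sub)), function(i)
        paste(bits[sub[i, ] == 1], collapse = ";"), character(1))
    preds <- data.frame(compound_id = rownames(m), label = labels,
        prediction = pred, matched_bits = matched,
        stringsAsFactors = FALSE)
    new("ScreenReport",
        n_with_alert = sum(pred == 1L),
        n_with_alert_true_pos = sum(pred == 1L & labels == 1L),
        n_without_alert = sum(pred == 0L),
        n_without_alert_true_neg = sum(pred == 0L & labels == 0L),
        predictions = preds)
}

#' Build a ScreenReport from summary counts
#'
#' For auditing published screen tallies without per-compound data: the
#' accuracy arithmetic (accuracy among alert carriers, among alert-free
#' compounds, and overall) is derived from the four counts alone.
#'
#' @param n_with_alert compounds carrying >= 1 alert.
#' @param n_with_alert_true_pos of those, truly nephrotoxic.
#' @param n_without_alert compounds carrying no alert.
#' @param n_without_alert_true_neg of those, truly non-toxic.
#' @return A [ScreenReport-class] with an empty per-compound table.
#' @examples
#' # e.g. 290 carriers of which 218 toxic, 275 alert-free of which 206 clean
#' r <- screenReportFromCounts(290, 218, 275, 206)
#' screenSummary(r)["accuracy_overall"]   # 75.04 (424/565)
#' @export
screenReportFromCounts <- function(n_with_alert, n_with_alert_true_pos,
                                   n_without_alert,
                                   n_without_alert_true_neg) {
    new("ScreenReport",
        n_with_alert = n_with_alert,
        n_with_alert_true_pos = n_with_alert_true_pos,
        n_without_alert = n_without_alert,
        n_without_alert_true_neg = n_without_alert_true_neg,
        predictions = data.frame(compound_id = character(),
            label = integer(), prediction = integer(),
            matched_bits = character(), stringsAsFactors = FALSE))
}

#' Convert a ScreenReport to a ConfusionMatrix
#'
#' Alert carriers are predicted positive, so true positives are the toxic
#' carriers and true negatives the non-toxic alert-free compounds.
#'
#' @param report a [ScreenReport-class].
#' @return A [ConfusionMatrix-class].
#' @export
screenConfusion <- function(report) {
    s <- screenSummary(report)
    ConfusionMatrix(
        tp = s[["n_with_alert_true_pos"]],
        fp = s[["n_with_alert"]] - s[["n_with_alert_true_pos"]],
        tn = s[["n_without_alert_true_neg"]],
        fn = s[["n_without_alert"]] - s[["n_without_alert_true_neg"]])
}

#' Write a screen report
#'
#' @param report a [ScreenReport-class].
#' @param path output path; `.json` writes the summary (and per-compound
#'   predictions when present), `.csv` the per-compound table only.
#' @return `path`, invisibly.
#' @export
writeScreenReport <- function(report, path) {
    if (tolower(tools::file_ext(path)) == "json") {
        s <- as.list(screenSummary(report))
        obj <- list(schema_version = "1.0", summary = s)
        if (nrow(screenPredictions(report)))
            obj$predictions <- screenPredictions(report)
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
            na = "null")
    } else {
        write.csv(screenPredictions(report), path, row.names = FALSE)
    }
    invisible(path)
}
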