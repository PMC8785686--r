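#' @name accessors
#' @title Accessors for nephroSA container classes
#' @description Slot access goes through these accessors; slots are internal.
#' @param x a nephroSA object.
#' @return The requested component (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @rdname accessors
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))
#' @rdname accessors
#' @export
setGeneric("compoundSplits", function(x) standardGeneric("compoundSplits"))
#' @rdname accessors
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))
#' @rdname accessors
#' @export
setGeneric("rejects", function(x) standardGeneric("rejects"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("bitIds", function(x) standardGeneric("bitIds"))
#' @rdname accessors
#' @export
setGeneric("catalogSmarts", function(x) standardGeneric("catalogSmarts"))
#' @rdname accessors
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))
#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("alertTable", function(x) standardGeneric("alertTable"))
#' @rdname accessors
#' @export
setGeneric("selectedBits", function(x) standardGeneric("selectedBits"))
#' @rdname accessors
#' @export
setGeneric("miningConfig", function(x) standardGeneric("miningConfig"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("predictionScores", function(x) standardGeneric("predictionScores"))
#' @rdname accessors
#' @export
setGeneric("screenSummary", function(x) standardGeneric("screenSummary"))
#' @rdname accessors
#' @export
setGeneric("screenPredictions",
    function(x) standardGeneric("screenPredictions"))

## ---- CompoundSet ----

#' @rdname accessors
setMethod("compoundIds", "CompoundSet", function(x) x@data$compound_id)
#' @rdname accessors
setMethod("compoundSmiles", "CompoundSet", function(x)
    setNames(x@data$smiles, x@data$compound_id))
#' @rdname accessors
setMethod("compoundLabels", "CompoundSet", function(x)
    setNames(x@data$label, x@data$compound_id))
#' @rdname accessors
setMethod("compoundSplits", "CompoundSet", function(x)
    setNames(x@data$split, x@data$compound_id))
#' @rdname accessors
setMethod("compoundData", "CompoundSet", function(x) x@data)
#' @rdname accessors
setMethod("rejects", "CompoundSet", function(x) x@rejects)
#' @rdname accessors
setMethod("provenance", "CompoundSet", function(x) x@provenance)

#' @describeIn CompoundSet number of (accepted) records.
#' @param x a CompoundSet.
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))

#' @describeIn CompoundSet subset records by index, id or logical mask.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@data$compound_id)
    d <- x@data[i, , drop = FALSE]
    rownames(d) <- NULL
    initialize(x, data = d)
})

setMethod("show", "CompoundSet", function(object) {
    d <- object@data
    cat("CompoundSet with", nrow(d), "compounds",
        sprintf("(%d nephrotoxic, %d non-nephrotoxic)\n",
            sum(d$label == 1L), sum(d$label == 0L)))
    tab <- table(factor(d$split, levels = .SPLIT_LEVELS))
    cat("  split:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    if (nrow(object@rejects))
        cat("  rejects:", nrow(object@rejects), "record(s)\n")
    if (nzchar(object@provenance))
        cat("  provenance:", object@provenance, "\n")
    invisible(NULL)
})

## ---- SmartsCatalog ----

#' @rdname accessors
setMethod("bitIds", "SmartsCatalog", function(x) x@entries$bit_id)
#' @rdname accessors
setMethod("catalogSmarts", "SmartsCatalog", function(x)
    setNames(x@entries$smarts, x@entries$bit_id))
#' @rdname accessors
setMethod("catalogEntries", "SmartsCatalog", function(x) x@entries)

#' @describeIn SmartsCatalog number of entries.
#' @param x a SmartsCatalog.
#' @export
setMethod("length", "SmartsCatalog", function(x) nrow(x@entries))

#' @describeIn SmartsCatalog subset by index or bit id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SmartsCatalog", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@entries$bit_id)
    e <- x@entries[i, , drop = FALSE]
    rownames(e) <- NULL
    initialize(x, entries = e)
})

setMethod("show", "SmartsCatalog", function(object) {
    cat("SmartsCatalog with", nrow(object@entries), "substructure keys\n")
    if (nrow(object@entries)) {
        hd <- head(object@entries, 4)
        for (k in seq_len(nrow(hd)))
            cat("  ", hd$bit_id[k], " ", hd$smarts[k], "\n", sep = "")
        if (nrow(object@entries) > 4) cat("  ...\n")
    }
    invisible(NULL)
})

## ---- FingerprintMatrix ----

#' @rdname accessors
setMethod("presenceMatrix", "FingerprintMatrix", function(x) x@presence)
#' @rdname accessors
setMethod("compoundIds", "FingerprintMatrix", function(x)
    rownames(x@presence))
#' @rdname accessors
setMethod("bitIds", "FingerprintMatrix", function(x) colnames(x@presence))
#' @rdname accessors
setMethod("catalogSmarts", "FingerprintMatrix", function(x)
    setNames(x@bit_smarts, colnames(x@presence)))

#' @describeIn FingerprintMatrix matrix dimensions (compounds, bits).
#' @param x a FingerprintMatrix.
#' @export
setMethod("dim", "FingerprintMatrix", function(x) dim(x@presence))

setMethod("show", "FingerprintMatrix", function(object) {
    cat("FingerprintMatrix:", nrow(object@presence), "compounds x",
        ncol(object@presence), "bits")
    if (nzchar(object@catalog_ref))
        cat(" [", object@catalog_ref, "]", sep = "")
    dens <- if (length(object@presence)) mean(object@presence) else NA
    cat(sprintf("\n  density: %.4f\n", dens))
    invisible(NULL)
})

## ---- AlertSet ----

#' @rdname accessors
setMethod("alertTable", "AlertSet", function(x) x@table)
#' @rdname accessors
setMethod("selectedBits", "AlertSet", function(x)
    x@table$bit_id[x@table$selected])
#' @rdname accessors
setMethod("miningConfig", "AlertSet", function(x) x@config)

#' @describeIn AlertSet number of candidate bits scored.
#' @param x an AlertSet.
#' @export
setMethod("length", "AlertSet", function(x) nrow(x@table))

setMethod("show", "AlertSet", function(object) {
    t <- object@table
    cat("AlertSet:", nrow(t), "candidate bits,", sum(t$selected),
        "selected,", sum(t$exclusive), "exclusive to the positive class\n")
    cfg <- object@config
    cat(sprintf("  thresholds: support >= %g, f-score >= %g, PR >= %g (%s)\n",
        cfg@min_support, cfg@f_min, cfg@pr_min, cfg@score_method))
    sel <- head(t[t$selected, c("bit_id", "n_pos", "n_neg",
        "positive_rate", "f_score")], 5)
    if (nrow(sel)) {
        print(sel, row.names = FALSE, digits = 4)
        if (sum(t$selected) > 5) cat("  ...\n")
    }
    invisible(NULL)
})

## ---- ConfusionMatrix ----

#' @rdname accessors
setMethod("counts", "ConfusionMatrix", function(x)
    c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))

setMethod("show", "ConfusionMatrix", function(object) {
    cat("ConfusionMatrix (positive class = nephrotoxic)\n")
    m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
        dimnames = list(c("pred 1", "pred 0"), c("label 1", "label 0")))
    print(m)
    invisible(NULL)
})

## ---- PredictionSet ----

#' @rdname accessors
setMethod("compoundIds", "PredictionSet", function(x) x@compound_ids)
#' @rdname accessors
setMethod("predictionScores", "PredictionSet", function(x)
    setNames(x@scores, x@compound_ids))
#' @rdname accessors
setMethod("compoundLabels", "PredictionSet", function(x)
    setNames(x@labels, x@compound_ids))

#' @describeIn PredictionSet number of predictions.
#' @param x a PredictionSet.
#' @export
setMethod("length", "PredictionSet", function(x) length(x@compound_ids))

setMethod("show", "PredictionSet", function(object) {
    cat("PredictionSet with", length(object@compound_ids), "compounds;",
        sum(!is.na(object@labels)), "labelled\n")
    invisible(NULL)
})

## ---- ScreenReport ----

#' @rdname accessors
setMethod("screenSummary", "ScreenReport", function(x) {
    total <- x@n_with_alert + x@n_without_alert
    c(n_with_alert = x@n_with_alert,
      n_with_alert_true_pos = x@n_with_alert_true_pos,
      n_without_alert = x@n_without_alert,
      n_without_alert_true_neg = x@n_without_alert_true_neg,
      accuracy_with = 100 * x@n_with_alert_true_pos / x@n_with_alert,
      accuracy_without = 100 * x@n_without_alert_true_neg / x@n_without_alert,
      accuracy_overall = 100 *
          (x@n_with_alert_true_pos + x@n_without_alert_true_neg) / total)
})
#' @rdname accessors
setMethod("screenPredictions", "ScreenReport", function(x) x@predictions)

setMethod("show", "ScreenReport", function(object) {
    s <- screenSummary(object)
    cat("ScreenReport over", s["n_with_alert"] + s["n_without_alert"],
        "compounds\n")
    cat(sprintf("  with >=1 alert:    %d (%d nephrotoxic, accuracy %.2f%%)\n",
        as.integer(s["n_with_alert"]),
        as.integer(s["n_with_alert_true_pos"]), s["accuracy_with"]))
    cat(sprintf("  without any alert: %d (%d non-toxic,   accuracy %.2f%%)\n",
        as.integer(s["n_without_alert"]),
        as.integer(s["n_without_alert_true_neg"]), s["accuracy_without"]))
    cat(sprintf("  overall accuracy:  %.2f%%\n", s["accuracy_overall"]))
    invisible(NULL)
})

## ---- SyntheticSpec ----

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@n_pos, "pos /", object@n_neg, "neg,",
        object@n_bits, "bits, background rate", object@background_rate, "\n")
    np <- if (nrow(object@planted)) nrow(object@planted) else object@n_planted
    cat("  planted bits:", np,
        if (!nrow(object@planted)) "(drawn from seed at generation)" else "",
        "\n  seed:", object@seed, "\n")
    invisible(NULL)
})
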