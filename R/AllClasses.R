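#' @import methods
#' @importFrom stats prcomp rbinom runif sd t.test var setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

.SPLIT_LEVELS <- c("train", "validation", "unassigned")

#' CompoundSet: a labelled collection of chemical structures
#'
#' Holds one record per compound: identifier, SMILES, a binary nephrotoxicity
#' label (1 = nephrotoxic, 0 = non-nephrotoxic) and a train/validation split
#' assignment. Structures that failed parsing or standardization are kept in
#' the \code{rejects} slot (with a reason) rather than silently dropped.
#'
#' @slot data data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{label} (integer 0/1) and \code{split}
#'   (\code{"train"}, \code{"validation"} or \code{"unassigned"}).
#' @slot provenance free-text origin of the set.
#' @slot rejects data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{reason}.
#' @seealso [loadCompounds()], [standardizeCompounds()],
#'   [deduplicateCompounds()], [splitDataset()]
#' @exportClass CompoundSet
setClass("CompoundSet",
    representation(data = "data.frame", provenance = "character",
        rejects = "data.frame"),
    prototype(
        data = data.frame(compound_id = character(), smiles = character(),
            label = integer(), split = character(),
            stringsAsFactors = FALSE),
        provenance = "",
        rejects = data.frame(compound_id = character(), smiles = character(),
            reason = character(), stringsAsFactors = FALSE)))

setValidity("CompoundSet", function(object) {
    d <- object@data
    msgs <- character()
    need <- c("compound_id", "smiles", "label", "split")
    if (!all(need %in% names(d)))
        return(paste("data must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(d$compound_id))
        msgs <- c(msgs, "compound_id values must be unique")
    if (!all(d$label %in% c(0L, 1L)))
        msgs <- c(msgs, "label must be 0 or 1")
    if (!all(d$split %in% .SPLIT_LEVELS))
        msgs <- c(msgs, "split must be train/validation/unassigned")
    if (!all(c("compound_id", "smiles", "reason") %in%
             names(object@rejects)))
        msgs <- c(msgs, "rejects needs compound_id, smiles, reason columns")
    if (length(msgs)) msgs else TRUE
})

#' Construct a CompoundSet
#'
#' @param compound_id character vector of unique identifiers.
#' @param smiles character vector of SMILES strings.
#' @param label binary labels; accepted encodings are 0/1, "0"/"1",
#'   "nephrotoxic"/"non-nephrotoxic" (anything else is an error, never
#'   coerced).
#' @param split optional split assignment, default "unassigned".
#' @param provenance free-text origin.
#' @param rejects optional data.frame of rejected records
#'   (compound_id, smiles, reason).
#' @return A [CompoundSet-class] object.
#' @examples
#' cs <- CompoundSet(c("a", "b"), c("CCO", "c1ccccc1"), c(1, 0))
#' compoundLabels(cs)
#' @export
CompoundSet <- function(compound_id, smiles, label,
                        split = "unassigned", provenance = "",
                        rejects = NULL) {
    n <- length(smiles)
    split <- rep_len(as.character(split), n)
    d <- data.frame(compound_id = as.character(compound_id),
        smiles = as.character(smiles),
        label = .coerce_labels(label),
        split = split, stringsAsFactors = FALSE)
    rownames(d) <- NULL
    if (is.null(rejects))
        rejects <- data.frame(compound_id = character(),
            smiles = character(), reason = character(),
            stringsAsFactors = FALSE)
    new("CompoundSet", data = d, provenance = provenance, rejects = rejects)
}

# strict label decoding; anything unrecognized is an error (never coerced)
.coerce_labels <- function(label) {
    x <- tolower(trimws(as.character(label)))
    out <- rep(NA_integer_, length(x))
    out[x %in% c("1", "nephrotoxic", "positive", "pos")] <- 1L
    out[x %in% c("0", "non-nephrotoxic", "nonnephrotoxic", "negative",
                 "neg")] <- 0L
    if (anyNA(out))
        stop("unrecognized label value(s): ",
             paste(unique(label[is.na(out)]), collapse = ", "),
             " (accepted: 0, 1, nephrotoxic, non-nephrotoxic)")
    out
}

#' SmartsCatalog: an ordered dictionary of substructure keys
#'
#' Each entry maps a bit identifier to a SMARTS pattern; the catalog defines
#' the columns of a [FingerprintMatrix-class]. Every pattern is checked to
#' parse at construction time.
#'
#' @slot entries data.frame with columns \code{bit_id}, \code{smarts}.
#' @seealso [bundledAlertCatalog()], [readSmartsCatalog()]
#' @exportClass SmartsCatalog
setClass("SmartsCatalog",
    representation(entries = "data.frame"),
    prototype(entries = data.frame(bit_id = character(),
        smarts = character(), stringsAsFactors = FALSE)))

setValidity("SmartsCatalog", function(object) {
    e <- object@entries
    if (!all(c("bit_id", "smarts") %in% names(e)))
        return("entries must have columns bit_id, smarts")
    if (anyDuplicated(e$bit_id))
        return("bit_id values must be unique")
    TRUE
})

#' Construct a SmartsCatalog
#'
#' @param bit_id character vector of unique bit identifiers.
#' @param smarts character vector of SMARTS patterns.
#' @param validate check that every pattern parses (default TRUE).
#' @return A [SmartsCatalog-class].
#' @export
SmartsCatalog <- function(bit_id, smarts, validate = TRUE) {
    e <- data.frame(bit_id = as.character(bit_id),
        smarts = as.character(smarts), stringsAsFactors = FALSE)
    rownames(e) <- NULL
    obj <- new("SmartsCatalog", entries = e)
    if (validate && nrow(e)) {
        bad <- !vapply(e$smarts, .smarts_parses, logical(1))
        if (any(bad))
            stop("SMARTS pattern(s) failed to parse for bit_id: ",
                 paste(e$bit_id[bad], collapse = ", "))
    }
    obj
}

#' FingerprintMatrix: binary compound-by-bit presence matrix
#'
#' Rows are compounds, columns are catalog bits; entries are 0/1 presence
#' flags (presence, not embedding counts). Column order follows the catalog.
#'
#' @slot presence integer matrix with compound ids as rownames and bit ids
#'   as colnames; all entries in \{0, 1\}.
#' @slot bit_smarts character vector aligned with columns (NA when the
#'   generating catalog carried no SMARTS, e.g. abstract synthetic bits).
#' @slot catalog_ref free-text reference to the generating catalog.
#' @seealso [buildFingerprintMatrix()], [mineAlerts()]
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
    representation(presence = "matrix", bit_smarts = "character",
        catalog_ref = "character"))

setValidity("FingerprintMatrix", function(object) {
    p <- object@presence
    msgs <- character()
    if (!is.numeric(p)) msgs <- c(msgs, "presence must be numeric")
    else if (length(p) && !all(p %in% c(0, 1)))
        msgs <- c(msgs, "presence entries must be 0/1")
    if (is.null(rownames(p)) && nrow(p))
        msgs <- c(msgs, "presence needs compound ids as rownames")
    if (is.null(colnames(p)) && ncol(p))
        msgs <- c(msgs, "presence needs bit ids as colnames")
    if (length(object@bit_smarts) != ncol(p))
        msgs <- c(msgs, "bit_smarts length must equal column count")
    if (length(msgs)) msgs else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param presence 0/1 matrix (compounds x bits) with dimnames.
#' @param bit_smarts optional SMARTS per column.
#' @param catalog_ref free-text catalog reference.
#' @return A [FingerprintMatrix-class].
#' @export
FingerprintMatrix <- function(presence, bit_smarts = NULL,
                              catalog_ref = "") {
    storage.mode(presence) <- "integer"
    if (is.null(bit_smarts)) bit_smarts <- rep(NA_character_, ncol(presence))
    new("FingerprintMatrix", presence = presence,
        bit_smarts = as.character(bit_smarts), catalog_ref = catalog_ref)
}

#' MiningConfig: thresholds for structural-alert selection
#'
#' Defaults are the filtering rules of the alert-mining procedure: a fragment
#' is kept only when it occurs in at least \code{min_support} compounds of the
#' whole set, its discrimination f-score is at least \code{f_min} and its
#' positive rate is at least \code{pr_min}. All comparisons are inclusive.
#'
#' @slot min_support minimum carrier count over both classes (default 6).
#' @slot f_min minimum f-score (default 0.005).
#' @slot pr_min minimum positive rate (default 0.75).
#' @slot score_method "fisher" (Chen-Lin Fisher score, default) or "f1"
#'   (F1 of the bit used as a one-rule classifier).
#' @exportClass MiningConfig
setClass("MiningConfig",
    representation(min_support = "numeric", f_min = "numeric",
        pr_min = "numeric", score_method = "character"),
    prototype(min_support = 6, f_min = 0.005, pr_min = 0.75,
        score_method = "fisher"))

setValidity("MiningConfig", function(object) {
    msgs <- character()
    if (object@min_support < 1) msgs <- c(msgs, "min_support must be >= 1")
    if (object@f_min < 0 || object@pr_min < 0)
        msgs <- c(msgs, "thresholds must be >= 0")
    if (!object@score_method %in% c("fisher", "f1"))
        msgs <- c(msgs, "score_method must be 'fisher' or 'f1'")
    if (length(msgs)) msgs else TRUE
})

#' @rdname MiningConfig-class
#' @param min_support,f_min,pr_min,score_method see slot documentation.
#' @return A [MiningConfig-class].
#' @examples
#' MiningConfig()                     # the default thresholds
#' MiningConfig(pr_min = 0.9)
#' @export
MiningConfig <- function(min_support = 6, f_min = 0.005, pr_min = 0.75,
                         score_method = c("fisher", "f1")) {
    new("MiningConfig", min_support = min_support, f_min = f_min,
        pr_min = pr_min, score_method = match.arg(score_method))
}

#' AlertSet: per-bit mining statistics and selection flags
#'
#' One row per catalog bit, ordered by f-score (descending, infinite scores
#' first, ties broken by bit id): carrier counts per class, positive rate,
#' f-score, and whether the bit passed all three filters (\code{selected}).
#' \code{exclusive} marks selected bits carried by toxic compounds only
#' (\code{n_neg} = 0).
#'
#' @slot table data.frame with columns bit_id, smarts, n_pos, n_neg, n_total,
#'   positive_rate, f_score, selected, exclusive.
#' @slot config the [MiningConfig-class] used.
#' @seealso [mineAlerts()], [screenSet()]
#' @exportClass AlertSet
setClass("AlertSet",
    representation(table = "data.frame", config = "MiningConfig"))

setValidity("AlertSet", function(object) {
    need <- c("bit_id", "smarts", "n_pos", "n_neg", "n_total",
        "positive_rate", "f_score", "selected", "exclusive")
    if (!all(need %in% names(object@table)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' ConfusionMatrix: 2x2 classification counts
#'
#' Carrier for the confusion-based metric suite; label 1 (nephrotoxic) is the
#' positive class.
#'
#' @slot tp,fp,tn,fn non-negative counts.
#' @seealso [confusion()], [totalAccuracy()], [matthewsCC()]
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
    representation(tp = "numeric", fp = "numeric", tn = "numeric",
        fn = "numeric"))

setValidity("ConfusionMatrix", function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(v < 0)) return("counts must be non-negative")
    if (any(v != round(v))) return("counts must be integers")
    TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- ConfusionMatrix(tp = 48, fp = 7, tn = 47, fn = 7)
#' matthewsCC(cm)
#' @export
ConfusionMatrix <- function(tp, fp, tn, fn) {
    new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
        tn = as.numeric(tn), fn = as.numeric(fn))
}

#' PredictionSet: per-compound classifier scores
#'
#' @slot compound_ids character identifiers.
#' @slot scores numeric scores in \[0, 1\].
#' @slot labels integer 0/1 reference labels (NA when unknown).
#' @seealso [consensusPredict()], [rocAuc()]
#' @exportClass PredictionSet
setClass("PredictionSet",
    representation(compound_ids = "character", scores = "numeric",
        labels = "integer"))

setValidity("PredictionSet", function(object) {
    n <- length(object@compound_ids)
    if (length(object@scores) != n || length(object@labels) != n)
        return("compound_ids, scores and labels must be aligned")
    if (any(!is.na(object@scores) &
            (object@scores < 0 | object@scores > 1)))
        return("scores must lie in [0, 1]")
    if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
        return("labels must be 0/1/NA")
    TRUE
})

#' Construct a PredictionSet
#'
#' @param compound_ids identifiers.
#' @param scores numeric scores in \[0, 1\].
#' @param labels optional 0/1 labels (default NA).
#' @return A [PredictionSet-class].
#' @export
PredictionSet <- function(compound_ids, scores, labels = NA) {
    n <- length(compound_ids)
    labels <- rep_len(labels, n)
    labels <- ifelse(is.na(labels), NA_integer_, as.integer(labels))
    new("PredictionSet", compound_ids = as.character(compound_ids),
        scores = as.numeric(scores), labels = labels)
}

#' ScreenReport: results of a structural-alert screen
#'
#' @slot n_with_alert compounds carrying at least one selected alert.
#' @slot n_with_alert_true_pos of those, how many are truly nephrotoxic.
#' @slot n_without_alert compounds carrying no alert.
#' @slot n_without_alert_true_neg of those, how many are truly non-toxic.
#' @slot predictions per-compound data.frame (compound_id, label, prediction,
#'   matched_bits); zero rows when the report was built from counts alone.
#' @seealso [screenSet()], [screenReportFromCounts()]
#' @exportClass ScreenReport
setClass("ScreenReport",
    representation(n_with_alert = "numeric",
        n_with_alert_true_pos = "numeric",
        n_without_alert = "numeric",
        n_without_alert_true_neg = "numeric",
        predictions = "data.frame"))

setValidity("ScreenReport", function(object) {
    if (object@n_with_alert_true_pos > object@n_with_alert)
        return("true positives cannot exceed alert carriers")
    if (object@n_without_alert_true_neg > object@n_without_alert)
        return("true negatives cannot exceed alert-free compounds")
    TRUE
})

#' SyntheticSpec: parameters of the planted-alert generator
#'
#' The defaults are the study conditions the generator emulates: 287 toxic and
#' 278 non-toxic compounds, a 4,860-bit substructure catalog, 87 planted alert
#' bits with carrier support between 6 and 40 and positive-rate targets in
#' \[0.75, 1\], over a sparse random background where each remaining bit is
#' set independently with probability 0.05.
#'
#' @slot n_pos,n_neg class sizes.
#' @slot n_bits total catalog width.
#' @slot background_rate per-compound probability that a background bit is set.
#' @slot planted data.frame (bit_id, support, pr_target); zero rows means
#'   "draw the default 87 planted bits from the seed".
#' @slot n_planted,support_range,pr_range parameters of that default draw.
#' @slot seed integer seed; the generator uses a single RNG stream seeded once.
#' @seealso [generatePlantedMatrix()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(n_pos = "numeric", n_neg = "numeric", n_bits = "numeric",
        background_rate = "numeric", planted = "data.frame",
        n_planted = "numeric", support_range = "numeric",
        pr_range = "numeric", seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@background_rate < 0 || object@background_rate > 1)
        msgs <- c(msgs, "background_rate must be in [0, 1]")
    if (nrow(object@planted)) {
        p <- object@planted
        if (!all(c("bit_id", "support", "pr_target") %in% names(p)))
            msgs <- c(msgs, "planted needs bit_id, support, pr_target")
        else {
            if (any(p$support > object@n_pos + object@n_neg))
                msgs <- c(msgs, "planted support exceeds compound count")
            if (any(p$pr_target < 0 | p$pr_target > 1))
                msgs <- c(msgs, "pr_target must be in [0, 1]")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' @rdname SyntheticSpec-class
#' @param n_pos,n_neg,n_bits,background_rate,planted,n_planted,support_range,pr_range,seed
#'   see slot documentation.
#' @return A [SyntheticSpec-class].
#' @examples
#' sp <- SyntheticSpec(n_pos = 30, n_neg = 30, n_bits = 200,
#'     planted = data.frame(bit_id = "bit0001", support = 8, pr_target = 1))
#' @export
SyntheticSpec <- function(n_pos = 287, n_neg = 278, n_bits = 4860,
                          background_rate = 0.05, planted = NULL,
                          n_planted = 87, support_range = c(6, 40),
                          pr_range = c(0.75, 1), seed = 1) {
    if (is.null(planted))
        planted <- data.frame(bit_id = character(), support = numeric(),
            pr_target = numeric(), stringsAsFactors = FALSE)
    new("SyntheticSpec", n_pos = n_pos, n_neg = n_neg, n_bits = n_bits,
        background_rate = background_rate, planted = planted,
        n_planted = n_planted, support_range = support_range,
        pr_range = pr_range, seed = seed)
}
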