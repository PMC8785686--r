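#' Per-bit carrier counts by class
#'
#' For every fingerprint bit, the number of nephrotoxic (n_pos) and
#' non-nephrotoxic (n_neg) compounds carrying it.
#'
#' @param x a [FingerprintMatrix-class] or binary matrix.
#' @param labels 0/1 vector aligned with the rows.
#' @return data.frame with columns bit_id, n_pos, n_neg, n_total.
#' @export
bitCounts <- function(x, labels) {
    m <- if (is(x, "FingerprintMatrix")) presenceMatrix(x) else x
    labels <- as.integer(labels)
    if (length(labels) != nrow(m))
        stop("labels length (", length(labels),
             ") must equal row count (", nrow(m), ")")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    storage.mode(m) <- "double"
    n_pos <- as.vector(crossprod(m, labels))
    n_tot <- colSums(m)
    data.frame(bit_id = colnames(m), n_pos = n_pos,
        n_neg = n_tot - n_pos, n_total = n_tot,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Positive rate of a fragment
#'
#' The fraction of fragment-carrying compounds that are nephrotoxic:
#' n_pos / (n_pos + n_neg). Undefined (NA) when no compound carries the
#' fragment; such a bit can never pass the support filter anyway.
#'
#' @param n_pos,n_neg carrier counts per class (vectorized).
#' @return Ratio in \[0, 1\], or NA where the total is zero.
#' @examples
#' positiveRate(9, 0)     # 1.0
#' positiveRate(3, 1)     # 0.75, passes the inclusive 0.75 threshold
#' @export
positiveRate <- function(n_pos, n_neg) {
    tot <- n_pos + n_neg
    ifelse(tot > 0, n_pos / tot, NA_real_)
}

#' Fisher discrimination score of fingerprint bits
#'
#' The Chen-Lin Fisher score of each binary feature: squared separation of
#' the class-conditional means from the overall mean, over the summed
#' unbiased within-class variances,
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'            {s^2_+ + s^2_-}.}
#' A bit present in every compound of one class and absent from the other
#' has zero within-class variance and scores +Inf (perfect separator); a bit
#' with equal class-conditional means scores 0.
#'
#' @param x a [FingerprintMatrix-class], binary matrix, or single 0/1
#'   column vector.
#' @param labels 0/1 vector aligned with rows (or entries).
#' @return Numeric score(s), one per bit.
#' @export
fisherScore <- function(x, labels) {
    m <- if (is(x, "FingerprintMatrix")) presenceMatrix(x)
        else if (is.matrix(x)) x else matrix(x, ncol = 1)
    labels <- as.integer(labels)
    if (length(labels) != nrow(m))
        stop("labels length must equal row count")
    np <- sum(labels == 1L); nn <- sum(labels == 0L)
    if (np == 0L || nn == 0L)
        stop("both classes must be non-empty")
    storage.mode(m) <- "double"
    s1 <- as.vector(crossprod(m, labels))
    s0 <- colSums(m) - s1
    m1 <- s1 / np; m0 <- s0 / nn; mall <- (s1 + s0) / (np + nn)
    num <- (m1 - mall)^2 + (m0 - mall)^2
    # binary shortcut: sum (x - mean)^2 = s - s^2/n
    v1 <- if (np > 1) (s1 - s1^2 / np) / (np - 1) else rep(0, length(s1))
    v0 <- if (nn > 1) (s0 - s0^2 / nn) / (nn - 1) else rep(0, length(s0))
    den <- v1 + v0
    out <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    setNames(out, colnames(m))
}

# F1 of the bit used as a one-rule classifier (predict toxic iff bit set).
.f1Score <- function(n_pos, n_neg, total_pos) {
    denom <- 2 * n_pos + n_neg + (total_pos - n_pos)
    ifelse(denom > 0, 2 * n_pos / denom, 0)
}

#' Mine structural alerts from a fingerprint matrix
#'
#' Scores every catalog bit by positive rate and f-score, then applies the
#' three inclusive filters of the mining procedure: whole-set carrier
#' support >= \code{min_support}, f-score >= \code{f_min} and positive rate
#' >= \code{pr_min}. Candidates are returned for every bit (selected or
#' not), sorted by f-score descending — infinite scores first — with ties
#' broken by bit id. Selected bits absent from all non-toxic compounds are
#' flagged \code{exclusive}.
#'
#' @param x a [FingerprintMatrix-class] (or binary matrix).
#' @param labels 0/1 vector aligned with rows.
#' @param config a [MiningConfig-class] (default: support 6, f-score 0.005,
#'   positive rate 0.75, Fisher scoring).
#' @return An [AlertSet-class].
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 0, 0,
#'               1, 0, 1, 0, 1, 0), ncol = 2,
#'     dimnames = list(paste0("c", 1:6), c("bitA", "bitB")))
#' mineAlerts(m, labels = c(1, 1, 1, 0, 0, 0),
#'     config = MiningConfig(min_support = 2))
#' @export
mineAlerts <- function(x, labels, config = MiningConfig()) {
    stopifnot(is(config, "MiningConfig"))
    cnt <- bitCounts(x, labels)
    pr <- positiveRate(cnt$n_pos, cnt$n_neg)
    f <- if (config@score_method == "fisher") {
        unname(fisherScore(x, labels))
    } else {
        .f1Score(cnt$n_pos, cnt$n_neg, sum(labels == 1L))
    }
    selected <- !is.na(pr) &
        cnt$n_total >= config@min_support &
        f >= config@f_min &
        pr >= config@pr_min
    smarts <- if (is(x, "FingerprintMatrix")) unname(catalogSmarts(x))
        else rep(NA_character_, nrow(cnt))
    tab <- data.frame(bit_id = cnt$bit_id, smarts = smarts,
        n_pos = cnt$n_pos, n_neg = cnt$n_neg, n_total = cnt$n_total,
        positive_rate = pr, f_score = f, selected = selected,
        exclusive = selected & cnt$n_neg == 0,
        stringsAsFactors = FALSE)
    tab <- tab[order(-tab$f_score, tab$bit_id), ]
    rownames(tab) <- NULL
    new("AlertSet", table = tab, config = config)
}

#' Write an alert table
#'
#' @param alerts an [AlertSet-class].
#' @param path output file.
#' @param format "csv" or "json" (JSON carries a schema_version field and
#'   the mining thresholds).
#' @return `path`, invisibly.
#' @export
writeAlertTable <- function(alerts, path, format = c("csv", "json")) {
    format <- match.arg(format)
    tab <- alertTable(alerts)
    if (format == "csv") {
        write.csv(tab, path, row.names = FALSE)
    } else {
        cfg <- miningConfig(alerts)
        # JSON has no Inf literal; infinite scores round-trip as null
        tab$f_score[is.infinite(tab$f_score)] <- NA_real_
        obj <- list(schema_version = "1.0",
            config = list(min_support = cfg@min_support, f_min = cfg@f_min,
                pr_min = cfg@pr_min, score_method = cfg@score_method),
            alerts = tab)
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
            na = "null")
    }
    invisible(path)
}

#' Read an alert table written by [writeAlertTable()]
#'
#' @param path CSV or JSON alert table.
#' @return An [AlertSet-class].
#' @export
readAlertTable <- function(path) {
    if (tolower(tools::file_ext(path)) == "json") {
        obj <- jsonlite::read_json(path, simplifyVector = TRUE)
        cfg <- MiningConfig(obj$config$min_support, obj$config$f_min,
            obj$config$pr_min, obj$config$score_method)
        tab <- as.data.frame(obj$alerts, stringsAsFactors = FALSE)
        tab$smarts <- as.character(tab$smarts)  # all-NA reads as logical
        tab$f_score <- as.numeric(tab$f_score)
        tab$f_score[is.na(tab$f_score)] <- Inf  # JSON has no Inf literal
        new("AlertSet", table = tab, config = cfg)
    } else {
        tab <- read.csv(path, stringsAsFactors = FALSE)
        tab$smarts <- as.character(tab$smarts)
        new("AlertSet", table = tab, config = MiningConfig())
    }
}
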