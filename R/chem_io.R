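#' Read a compound table from CSV, SDF or SMILES
#'
#' Reads identifier, SMILES and binary nephrotoxicity label (plus an optional
#' train/validation split column) into a [CompoundSet-class]. Records whose
#' SMILES does not parse are collected in the rejects slot with a reason,
#' never silently dropped. Labels are decoded strictly: 0/1, "0"/"1",
#' "nephrotoxic"/"non-nephrotoxic"; anything else is an error.
#'
#' Accepted formats:
#' \describe{
#'   \item{csv}{UTF-8 with header \code{compound_id,smiles,label[,split]}.}
#'   \item{sdf}{label (and optionally compound_id, split) as named data
#'     fields; the MOL title is the fallback identifier.}
#'   \item{smi}{whitespace-separated \code{smiles id label [split]} lines.}
#' }
#'
#' @param path input file.
#' @param format "csv", "sdf" or "smi"; default guesses from the extension.
#' @param provenance free text recorded in the set (default: the file name).
#' @return A [CompoundSet-class]; records are in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(compound_id = c("a", "b"),
#'     smiles = c("CCO", "c1ccccc1"), label = c(1, 0)), f, row.names = FALSE)
#' loadCompounds(f)
#' @seealso [writeCompounds()], [standardizeCompounds()]
#' @export
loadCompounds <- function(path, format = c("auto", "csv", "sdf", "smi"),
                          provenance = basename(path)) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", sdf = "sdf", smi = "smi",
            txt = "smi",
            stop("cannot guess format from extension '", ext,
                 "'; pass format="))
    }
    tab <- switch(format,
        csv = .read_compound_csv(path),
        sdf = .read_compound_sdf(path),
        smi = .read_compound_smi(path))
    if (!nrow(tab)) stop("no records found in ", path)
    ok <- .smiles_valid(tab$smiles)
    rej <- data.frame(compound_id = tab$compound_id[!ok],
        smiles = tab$smiles[!ok],
        reason = rep("unparseable SMILES", sum(!ok)),
        stringsAsFactors = FALSE)
    if (!any(ok)) stop("no parseable structures in ", path)
    CompoundSet(tab$compound_id[ok], tab$smiles[ok], tab$label[ok],
        split = tab$split[ok], provenance = provenance, rejects = rej)
}

.read_compound_csv <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("compound_id", "smiles", "label")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("CSV is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (is.null(d$split)) d$split <- "unassigned"
    d[c("compound_id", "smiles", "label", "split")]
}

.read_compound_sdf <- function(path) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- suppressWarnings(ChemmineR::validSDF(sdf))
    if (!any(valid)) stop("no parseable structures in ", path)
    sdf <- sdf[valid]
    db <- ChemmineR::datablock2ma(ChemmineR::datablock(sdf))
    if (!"label" %in% colnames(db))
        stop("SDF is missing the required 'label' data field")
    ids <- if ("compound_id" %in% colnames(db)) db[, "compound_id"]
        else ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    split <- if ("split" %in% colnames(db)) db[, "split"] else "unassigned"
    data.frame(compound_id = as.character(ids), smiles = smi,
        label = db[, "label"], split = split, stringsAsFactors = FALSE)
}

.read_compound_smi <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 3))
        stop(".smi lines must be 'smiles id label [split]'; line(s) ",
             paste(which(nf < 3), collapse = ", "), " malformed")
    data.frame(
        compound_id = vapply(parts, `[`, "", 2),
        smiles = vapply(parts, `[`, "", 1),
        label = vapply(parts, `[`, "", 3),
        split = vapply(parts, function(p)
            if (length(p) >= 4) p[4] else "unassigned", ""),
        stringsAsFactors = FALSE)
}

#' Write a compound set
#'
#' Inverse of [loadCompounds()]: a written set reads back field-for-field
#' (ids, SMILES as stored, labels, splits).
#'
#' @param set a [CompoundSet-class].
#' @param path output file.
#' @param format "csv", "sdf" or "smi" (default from extension).
#' @return `path`, invisibly.
#' @export
writeCompounds <- function(set, path,
                           format = c("auto", "csv", "sdf", "smi")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", sdf = "sdf", smi = "smi",
            stop("cannot guess format from extension '", ext, "'"))
    }
    d <- compoundData(set)
    if (format == "csv") {
        write.csv(d, path, row.names = FALSE, quote = FALSE)
    } else if (format == "smi") {
        writeLines(paste(d$smiles, d$compound_id, d$label, d$split), path)
    } else {
        parsed <- .smiles_to_sdf(d$smiles, d$compound_id)
        sdf <- parsed$sdf
        ChemmineR::datablock(sdf) <- data.frame(
            compound_id = d$compound_id, label = as.character(d$label),
            split = d$split, stringsAsFactors = FALSE)
        ChemmineR::write.SDF(sdf, path, cid = TRUE)
    }
    invisible(path)
}

#' Write the rejects report of a compound set
#'
#' @param set a [CompoundSet-class].
#' @param path output CSV (columns compound_id, smiles, reason).
#' @return `path`, invisibly.
#' @export
writeRejects <- function(set, path) {
    write.csv(rejects(set), path, row.names = FALSE)
    invisible(path)
}

#' Standardize a SMILES string to its parent structure
#'
#' Reduces salts and mixtures to a single parent: the largest organic
#' (carbon-containing) fragment by heavy-atom count, ties broken by carbon
#' count and then by lexicographically smallest canonical SMILES. The kept
#' fragment is neutralized (protonation states reset where chemically
#' possible) and returned as its canonical SMILES. The operation is
#' idempotent: standardizing a standardized structure is a no-op.
#'
#' @param smiles character vector of SMILES.
#' @return Character vector of standardized canonical SMILES. Entries that
#'   fail (unparseable input, or no organic fragment, e.g. a purely
#'   inorganic salt) are `NA` with the reason in the
#'   `attr(, "errors")` character vector.
#' @examples
#' standardizeSmiles("CC(=O)O.[Na+]")      # acetate salt -> acetic acid
#' standardizeSmiles("CCO.c1ccccc1O")      # mixture -> phenol (larger)
#' @seealso [standardizeCompounds()] for whole-set standardization with
#'   rejects handling.
#' @export
standardizeSmiles <- function(smiles) {
    out <- rep(NA_character_, length(smiles))
    errs <- rep(NA_character_, length(smiles))
    for (i in seq_along(smiles)) {
        r <- .standardize_one(smiles[i])
        out[i] <- r$smiles
        errs[i] <- r$error
    }
    attr(out, "errors") <- errs
    out
}

.standardize_one <- function(s) {
    fail <- function(msg) list(smiles = NA_character_, error = msg)
    if (is.na(s) || !nzchar(trimws(s))) return(fail("empty SMILES"))
    if (!.smiles_valid(s)) return(fail("unparseable SMILES"))
    frags <- strsplit(.canonical_smiles(s), ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    sizes <- .fragment_sizes(frags)
    organic <- !is.na(sizes[, "carbons"]) & sizes[, "carbons"] > 0
    if (!any(organic))
        return(fail("no organic fragment after salt stripping"))
    frags <- frags[organic]
    sizes <- sizes[organic, , drop = FALSE]
    canon <- .canonical_smiles(frags)
    ord <- order(-sizes[, "heavy"], -sizes[, "carbons"], canon)
    list(smiles = .neutral_canonical_smiles(frags[ord[1]]),
         error = NA_character_)
}

#' Standardize every record of a compound set
#'
#' Applies [standardizeSmiles()] to each record; records that cannot be
#' standardized move to the rejects report.
#'
#' @param set a [CompoundSet-class].
#' @return A [CompoundSet-class] with standardized SMILES.
#' @export
standardizeCompounds <- function(set) {
    d <- compoundData(set)
    std <- standardizeSmiles(d$smiles)
    errs <- attr(std, "errors")
    ok <- !is.na(std)
    newrej <- data.frame(compound_id = d$compound_id[!ok],
        smiles = d$smiles[!ok], reason = errs[!ok],
        stringsAsFactors = FALSE)
    CompoundSet(d$compound_id[ok], as.character(std[ok]), d$label[ok],
        split = d$split[ok], provenance = provenance(set),
        rejects = rbind(rejects(set), newrej))
}

#' Remove duplicate structures
#'
#' Two records are duplicates when their standardized canonical SMILES are
#' identical (stereoisomers whose canonical forms differ remain distinct).
#' The first occurrence is kept; dropped duplicates are reported in the
#' rejects slot with reason "duplicate of <id>".
#'
#' @param set a [CompoundSet-class]; records should be standardized first.
#' @return A deduplicated [CompoundSet-class].
#' @export
deduplicateCompounds <- function(set) {
    d <- compoundData(set)
    key <- d$smiles
    first <- !duplicated(key)
    dupof <- d$compound_id[match(key, key)]
    newrej <- data.frame(compound_id = d$compound_id[!first],
        smiles = d$smiles[!first],
        reason = paste0("duplicate of ", dupof)[!first],
        stringsAsFactors = FALSE)
    CompoundSet(d$compound_id[first], d$smiles[first], d$label[first],
        split = d$split[first], provenance = provenance(set),
        rejects = rbind(rejects(set), newrej))
}

#' Randomly split a compound set into training and validation
#'
#' Draws exactly `n_train_pos` nephrotoxic and `n_train_neg` non-toxic
#' compounds into the training set; every remaining compound is assigned to
#' validation. Deterministic for a fixed seed; class counts are conserved.
#'
#' @param set a [CompoundSet-class].
#' @param n_train_pos,n_train_neg training-set class sizes.
#' @param seed integer seed.
#' @return The set with the `split` column filled.
#' @examples
#' \dontrun{
#' # the study design: 565 compounds -> 456 train / 109 validation
#' splitDataset(set, n_train_pos = 232, n_train_neg = 224, seed = 7)
#' }
#' @export
splitDataset <- function(set, n_train_pos, n_train_neg, seed = 1) {
    d <- compoundData(set)
    pos <- which(d$label == 1L)
    neg <- which(d$label == 0L)
    if (n_train_pos > length(pos))
        stop("requested ", n_train_pos, " training positives but only ",
             length(pos), " available")
    if (n_train_neg > length(neg))
        stop("requested ", n_train_neg, " training negatives but only ",
             length(neg), " available")
    split <- rep("validation", nrow(d))
    .with_seed(seed, {
        split[pos[sample.int(length(pos), n_train_pos)]] <- "train"
        split[neg[sample.int(length(neg), n_train_neg)]] <- "train"
    })
    CompoundSet(d$compound_id, d$smiles, d$label, split = split,
        provenance = provenance(set), rejects = rejects(set))
}
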