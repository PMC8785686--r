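#' The bundled nephrotoxicity alert catalog
#'
#' Sixteen substructure keys (Klekota-Roth style SMARTS) that, in the
#' reference nephrotoxicity data set, occur in nephrotoxic drugs only:
#' phenyl fluorides, polyamine/bis-amide motifs, benzimidazoles, toluene and
#' biphenyl motifs, aromatic nitriles, aminoacetophenone and proline-like
#' fragments. These are the package's default screening catalog; a full
#' substructure-key dictionary can be supplied via [readSmartsCatalog()].
#'
#' @return A [SmartsCatalog-class] with 16 entries.
#' @examples
#' cat16 <- bundledAlertCatalog()
#' length(cat16)
#' @export
bundledAlertCatalog <- function() {
    path <- system.file("extdata", "nephrotoxicity_alerts.csv",
        package = "nephroSA", mustWork = TRUE)
    readSmartsCatalog(path)
}

#' Read a SMARTS catalog from a two-column CSV
#'
#' @param path CSV with header \code{bit_id,smarts}.
#' @param validate check that every pattern parses (default TRUE); a
#'   non-parsing pattern is a catalog error naming the offending bit_id.
#' @return A [SmartsCatalog-class].
#' @export
readSmartsCatalog <- function(path, validate = TRUE) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("bit_id", "smarts") %in% names(d)))
        stop("catalog CSV needs columns bit_id, smarts")
    SmartsCatalog(d$bit_id, d$smarts, validate = validate)
}

#' Write a SMARTS catalog
#'
#' @param catalog a [SmartsCatalog-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeSmartsCatalog <- function(catalog, path) {
    write.csv(catalogEntries(catalog), path, row.names = FALSE)
    invisible(path)
}

#' Substructure presence of a SMARTS pattern in molecules
#'
#' Presence (not embedding count): 1 iff at least one substructure embedding
#' of the pattern exists in the molecule, under the toolkit's aromaticity
#' perception.
#'
#' @param smiles character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @param bit_id identifier used in error messages (default: the pattern).
#' @return Integer 0/1 vector, one element per molecule.
#' @examples
#' matchSmarts(c("Cc1ccc(F)cc1", "CCO"), "Cc1ccc(F)cc1")
#' @export
matchSmarts <- function(smiles, smarts, bit_id = smarts) {
    stopifnot(length(smarts) == 1L)
    parsed <- .smiles_to_sdf(smiles)
    if (!all(parsed$valid))
        stop("unparseable SMILES at position(s): ",
             paste(which(!parsed$valid), collapse = ", "))
    as.integer(.smarts_counts(parsed$sdf, smarts, bit_id) > 0)
}

#' Binary substructure-key fingerprint of one molecule
#'
#' @param smiles a single (standardized) SMILES.
#' @param catalog a [SmartsCatalog-class].
#' @return Named integer 0/1 vector over the catalog's bit ids; element i is
#'   the presence of pattern i.
#' @examples
#' fp <- computeFingerprint("c1ccc2[nH]cnc2c1", bundledAlertCatalog())
#' fp["KR3206"]
#' @export
computeFingerprint <- function(smiles, catalog) {
    stopifnot(length(smiles) == 1L)
    m <- buildFingerprintMatrix(
        CompoundSet("x", smiles, 0L), catalog)
    setNames(as.integer(presenceMatrix(m)[1, ]), bitIds(m))
}

#' Build the compound-by-bit presence matrix
#'
#' Row i is the fingerprint of record i; rows follow the set's record order,
#' columns the catalog order. Deterministic.
#'
#' @param set a [CompoundSet-class] (or character vector of SMILES).
#' @param catalog a [SmartsCatalog-class].
#' @return A [FingerprintMatrix-class].
#' @export
buildFingerprintMatrix <- function(set, catalog) {
    if (is.character(set))
        set <- CompoundSet(sprintf("mol%04d", seq_along(set)), set, 0L)
    ids <- compoundIds(set)
    smi <- unname(compoundSmiles(set))
    entries <- catalogEntries(catalog)
    m <- matrix(0L, nrow = length(ids), ncol = nrow(entries),
        dimnames = list(ids, entries$bit_id))
    if (length(ids) && nrow(entries)) {
        parsed <- .smiles_to_sdf(smi, ids)
        if (!all(parsed$valid))
            stop("unparseable SMILES for compound(s): ",
                 paste(ids[!parsed$valid], collapse = ", "))
        for (k in seq_len(nrow(entries)))
            m[, k] <- as.integer(
                .smarts_counts(parsed$sdf, entries$smarts[k],
                    entries$bit_id[k]) > 0)
    }
    FingerprintMatrix(m, bit_smarts = entries$smarts,
        catalog_ref = paste0("smarts:", .md5_of(paste(entries$smarts,
            collapse = "\n"))))
}

#' ECFP4 fingerprints for data-set diversity
#'
#' Hashed circular fingerprints of radius 2 (diameter 4), 4096 bits, used by
#' [meanPairwiseTsi()] to summarize structural diversity. The alert-mining
#' pipeline itself uses only SMARTS catalog bits.
#'
#' @param set a [CompoundSet-class] or character vector of SMILES.
#' @return A [FingerprintMatrix-class] with catalog_ref "ECFP4".
#' @export
ecfpFingerprints <- function(set) {
    if (is.character(set))
        set <- CompoundSet(sprintf("mol%04d", seq_along(set)), set, 0L)
    parsed <- .smiles_to_sdf(unname(compoundSmiles(set)), compoundIds(set))
    if (!all(parsed$valid))
        stop("unparseable SMILES for compound(s): ",
             paste(compoundIds(set)[!parsed$valid], collapse = ", "))
    fp <- ChemmineR::fingerprintOB(parsed$sdf, "ECFP4")
    m <- fp@fpma
    storage.mode(m) <- "integer"
    colnames(m) <- sprintf("ecfp%04d", seq_len(ncol(m)))
    FingerprintMatrix(m, catalog_ref = "ECFP4")
}

#' Tanimoto similarity of two binary vectors
#'
#' |a AND b| / |a OR b|, with the empty-union case 0/0 defined as 0.
#'
#' @param a,b equal-length binary vectors.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))   # 1/3
#' @export
tanimoto <- function(a, b) {
    if (length(a) != length(b))
        stop("vectors must have equal length")
    inter <- sum(a == 1 & b == 1)
    uni <- sum(a == 1 | b == 1)
    if (uni == 0) 0 else inter / uni
}

#' Mean pairwise Tanimoto similarity of a fingerprint matrix
#'
#' The mean of [tanimoto()] over all unordered compound pairs; a low value
#' indicates a structurally diverse set.
#'
#' @param x a [FingerprintMatrix-class] or binary matrix (rows = compounds).
#' @return The mean pairwise similarity.
#' @export
meanPairwiseTsi <- function(x) {
    m <- if (is(x, "FingerprintMatrix")) presenceMatrix(x) else x
    n <- nrow(m)
    if (n < 2) stop("need at least 2 compounds")
    storage.mode(m) <- "double"
    inter <- tcrossprod(m)
    r <- rowSums(m)
    uni <- outer(r, r, "+") - inter
    tsi <- ifelse(uni == 0, 0, inter / uni)
    mean(tsi[upper.tri(tsi)])
}

#' Read / write fingerprint matrices
#'
#' Wide CSV: \code{compound_id} plus one 0/1 column per bit, optionally a
#' \code{label} column. Sparse triplet CSV: \code{compound_id,bit_id,value}
#' rows for the set bits only, preceded by the full id lists so empty rows
#' and columns survive the round trip.
#'
#' @param x a [FingerprintMatrix-class].
#' @param path CSV path.
#' @param labels optional 0/1 vector written as a \code{label} column.
#' @return `writeFingerprintMatrix`: `path` invisibly.
#'   `readFingerprintMatrix`: list with elements `matrix`
#'   (a [FingerprintMatrix-class]) and `labels` (integer vector or NULL).
#' @export
writeFingerprintMatrix <- function(x, path, labels = NULL) {
    m <- presenceMatrix(x)
    d <- data.frame(compound_id = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    if (!is.null(labels)) {
        d <- data.frame(compound_id = rownames(m),
            label = as.integer(labels), m, check.names = FALSE,
            stringsAsFactors = FALSE)
    }
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeFingerprintMatrix
#' @export
readFingerprintMatrix <- function(path) {
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"compound_id" %in% names(d))
        stop("fingerprint CSV needs a compound_id column")
    labels <- NULL
    if ("label" %in% names(d)) {
        labels <- as.integer(d$label)
        d$label <- NULL
    }
    m <- as.matrix(d[setdiff(names(d), "compound_id")])
    rownames(m) <- d$compound_id
    list(matrix = FingerprintMatrix(m), labels = labels)
}

#' @rdname writeFingerprintMatrix
#' @export
writeFingerprintTriplets <- function(x, path) {
    m <- presenceMatrix(x)
    idx <- which(m == 1L, arr.ind = TRUE)
    hdr <- c(paste0("#compounds=", paste(rownames(m), collapse = ";")),
             paste0("#bits=", paste(colnames(m), collapse = ";")))
    body <- data.frame(compound_id = rownames(m)[idx[, 1]],
        bit_id = colnames(m)[idx[, 2]], value = 1L)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    write.csv(body, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeFingerprintMatrix
#' @export
readFingerprintTriplets <- function(path) {
    lines <- readLines(path)
    cids <- strsplit(sub("^#compounds=", "", lines[1]), ";")[[1]]
    bids <- strsplit(sub("^#bits=", "", lines[2]), ";")[[1]]
    body <- read.csv(text = lines[-(1:2)], stringsAsFactors = FALSE)
    m <- matrix(0L, length(cids), length(bids),
        dimnames = list(cids, bids))
    if (nrow(body))
        m[cbind(match(body$compound_id, cids),
                match(body$bit_id, bids))] <- 1L
    FingerprintMatrix(m)
}
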