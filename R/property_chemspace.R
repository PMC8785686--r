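#' Physicochemical property vector of compounds
#'
#' Computes the eight properties used for the toxic/non-toxic class
#' comparison:
#' \describe{
#'   \item{mw}{molecular weight, g/mol.}
#'   \item{mpsa}{topological polar surface area, A^2.}
#'   \item{alogp}{atomistic logP (octanol/water partition estimate).}
#'   \item{logs}{aqueous solubility, log(mol/L), via an ESOL-style
#'     estimate from logP, MW, rotatable bonds and aromatic proportion.}
#'   \item{nhba}{hydrogen-bond acceptor count.}
#'   \item{nhbd}{hydrogen-bond donor count.}
#'   \item{nrotb}{rotatable bonds: non-ring single bonds between
#'     non-terminal heavy atoms, bonds to amide nitrogens excluded.}
#'   \item{nar}{aromatic rings (5-, 6- and 7-membered SSSR rings).}
#' }
#' Values are deterministic per toolkit version and independent of input
#' atom ordering (they are computed from the perceived structure).
#'
#' @param x a [CompoundSet-class] or character vector of (standardized)
#'   SMILES.
#' @return data.frame, one row per compound (rownames = compound ids).
#' @examples
#' computeProperties(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' @export
computeProperties <- function(x) {
    if (is.character(x)) {
        ids <- if (!is.null(names(x))) names(x)
            else sprintf("mol%04d", seq_along(x))
        x <- CompoundSet(ids, unname(x), 0L)
    }
    ids <- compoundIds(x)
    smi <- unname(compoundSmiles(x))
    parsed <- .smiles_to_sdf(smi, ids)
    if (!all(parsed$valid))
        stop("unparseable SMILES for compound(s): ",
             paste(ids[!parsed$valid], collapse = ", "))
    sdf <- parsed$sdf
    props <- ChemmineR::propOB(sdf)

    # rotatable bonds: each bond matched twice (once per direction)
    rot_smarts <- paste0("[!$(*#*)&!D1&!$([NX3][CX3]=[OX1])]-&!@",
        "[!$(*#*)&!D1&!$([NX3][CX3]=[OX1])]")
    nrotb <- .smarts_counts(sdf, rot_smarts, "rotatable-bond") / 2
    # aromatic SSSR rings by size (each n-ring matched 2n times)
    nar <- .smarts_counts(sdf, "[aR]1[aR][aR][aR][aR]1", "ar5") / 10 +
        .smarts_counts(sdf, "[aR]1[aR][aR][aR][aR][aR]1", "ar6") / 12 +
        .smarts_counts(sdf, "[aR]1[aR][aR][aR][aR][aR][aR]1", "ar7") / 14
    n_arom <- .smarts_counts(sdf, "a", "aromatic-atom")
    n_heavy <- .smarts_counts(sdf, "[!#1]", "heavy-atom")
    # ESOL (Delaney) solubility estimate
    logs <- 0.16 - 0.63 * props$logP - 0.0062 * props$MW +
        0.066 * nrotb - 0.74 * (n_arom / pmax(n_heavy, 1))

    out <- data.frame(
        mw = props$MW, mpsa = props$TPSA, alogp = props$logP,
        logs = as.numeric(logs),
        nhba = as.integer(props$HBA2), nhbd = as.integer(props$HBD),
        nrotb = as.integer(nrotb), nar = as.integer(nar),
        row.names = ids, stringsAsFactors = FALSE)
    out
}

#' Compare a property between toxic and non-toxic groups
#'
#' Two-sided two-sample t-test (Welch by default; set `welch = FALSE` for
#' the pooled-variance Student form), with class means and the pooled mean.
#' Significance is declared at p < 0.05. Degenerate inputs (fewer than two
#' values in a group, or zero variance in both groups) are flagged: the
#' p-value is omitted (NA) rather than fabricated.
#'
#' @param values_pos,values_neg numeric property values per class.
#' @param property label for the output row.
#' @param welch use the Welch unequal-variance form (default TRUE).
#' @return One-row data.frame: property, mean_pos, mean_neg, mean_all,
#'   t_statistic, p_value, significant.
#' @export
compareGroups <- function(values_pos, values_neg, property = "",
                          welch = TRUE) {
    values_pos <- values_pos[!is.na(values_pos)]
    values_neg <- values_neg[!is.na(values_neg)]
    mean_pos <- mean(values_pos); mean_neg <- mean(values_neg)
    mean_all <- mean(c(values_pos, values_neg))
    degenerate <- length(values_pos) < 2 || length(values_neg) < 2 ||
        (var(values_pos) == 0 && var(values_neg) == 0)
    if (degenerate) {
        t_stat <- NA_real_; p <- NA_real_
    } else {
        tt <- t.test(values_pos, values_neg, var.equal = !welch)
        t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(property = property, mean_pos = mean_pos,
        mean_neg = mean_neg, mean_all = mean_all, t_statistic = t_stat,
        p_value = p, significant = !is.na(p) & p < 0.05,
        stringsAsFactors = FALSE)
}

#' Compare all eight properties between classes
#'
#' @param properties data.frame from [computeProperties()].
#' @param labels 0/1 vector aligned with its rows.
#' @param welch see [compareGroups()].
#' @return data.frame with one row per property.
#' @export
compareProperties <- function(properties, labels, welch = TRUE) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(properties))
    out <- do.call(rbind, lapply(names(properties), function(p)
        compareGroups(properties[labels == 1L, p],
            properties[labels == 0L, p], property = p, welch = welch)))
    rownames(out) <- NULL
    out
}

#' PCA projection of the chemical space
#'
#' Standardizes the descriptor columns (zero mean, unit variance; constant
#' columns dropped), performs PCA and returns the first two component
#' scores per compound together with each component's share of the total
#' variance. Component signs are fixed so that the loading with the largest
#' magnitude on each component is positive, making scores reproducible
#' across platforms.
#'
#' @param descriptors numeric matrix or data.frame (compounds x
#'   descriptors); needs >= 3 rows and rank >= 2 after dropping constant
#'   columns.
#' @param labels optional group labels carried into the scores table.
#' @return list with `scores` (data.frame compound_id, pc1, pc2, label),
#'   `explained` (variance shares of PC1 and PC2), `loadings`
#'   (descriptors x 2).
#' @export
pcaChemspace <- function(descriptors, labels = NULL) {
    m <- as.matrix(descriptors)
    if (nrow(m) < 3) stop("need at least 3 compounds for PCA")
    keep <- apply(m, 2, function(col) sd(col) > 0)
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 2)
        stop("fewer than 2 non-constant descriptors; chemical-space PCA ",
             "is undefined")
    pc <- prcomp(m, center = TRUE, scale. = TRUE)
    if (length(pc$sdev) < 2)
        stop("descriptor matrix has rank < 2 after standardization")
    flip <- vapply(1:2, function(k) {
        l <- pc$rotation[, k]
        if (l[which.max(abs(l))] < 0) -1 else 1
    }, numeric(1))
    scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, "*")
    loadings <- sweep(pc$rotation[, 1:2, drop = FALSE], 2, flip, "*")
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    ids <- if (!is.null(rownames(m))) rownames(m)
        else sprintf("mol%04d", seq_len(nrow(m)))
    if (is.null(labels)) labels <- NA
    list(scores = data.frame(compound_id = ids, pc1 = scores[, 1],
            pc2 = scores[, 2], label = rep_len(labels, nrow(m)),
            stringsAsFactors = FALSE, row.names = NULL),
        explained = c(pc1 = expl[1], pc2 = expl[2]),
        loadings = loadings)
}
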