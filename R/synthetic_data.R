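#' Generate a fingerprint matrix with planted alert bits
#'
#' Emulates the fragment/label structure that alert mining assumes: a
#' two-class compound set whose fingerprint contains a small number of
#' informative ("planted") bits with controlled carrier support and positive
#' rate, against a sparse random background. Planted carriers are assigned
#' by exact count — a planted bit with support s and positive-rate target p
#' is set in exactly round(s*p) toxic and s - round(s*p) non-toxic
#' compounds (carriers drawn without replacement) — so its realized
#' (n_pos, n_neg) match the specification by construction, not in
#' expectation. Background bits are independent Bernoulli(background_rate).
#'
#' All randomness comes from one generator seeded once with `spec@seed`;
#' draws happen in a fixed order (planted-bit parameters if not supplied,
#' then background bits, then carriers per planted bit), so two runs with
#' equal seeds are bit-identical. The caller's RNG state is untouched.
#'
#' @param spec a [SyntheticSpec-class]. When its `planted` table is empty,
#'   `n_planted` bits are drawn from the seed: column positions sampled
#'   uniformly, supports uniform on `support_range`, positive-rate targets
#'   uniform on `pr_range`.
#' @return list with `matrix` (a [FingerprintMatrix-class], labels first
#'   `n_pos` rows positive), `labels` (0/1 vector), `planted` (data.frame
#'   bit_id, support, pr_target, n_pos, n_neg of realized counts).
#' @examples
#' sp <- SyntheticSpec(n_pos = 20, n_neg = 20, n_bits = 50,
#'     background_rate = 0,
#'     planted = data.frame(bit_id = "bit0001", support = 8, pr_target = 1))
#' g <- generatePlantedMatrix(sp)
#' bitCounts(g$matrix, g$labels)[1, ]   # n_pos 8, n_neg 0
#' @export
generatePlantedMatrix <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    n <- spec@n_pos + spec@n_neg
    .with_seed(spec@seed, {
        planted <- spec@planted
        if (!nrow(planted)) {
            cols <- sort(sample.int(spec@n_bits, spec@n_planted))
            planted <- data.frame(
                bit_id = sprintf("bit%04d", cols),
                support = sample(seq(spec@support_range[1],
                    spec@support_range[2]), spec@n_planted, replace = TRUE),
                pr_target = runif(spec@n_planted, spec@pr_range[1],
                    spec@pr_range[2]),
                stringsAsFactors = FALSE)
        }
        bit_ids <- sprintf("bit%04d", seq_len(spec@n_bits))
        missing <- setdiff(planted$bit_id, bit_ids)
        if (length(missing))
            stop("planted bit_id(s) outside the catalog: ",
                 paste(missing, collapse = ", "))
        m <- matrix(as.integer(runif(n * spec@n_bits) <
                spec@background_rate),
            nrow = n, ncol = spec@n_bits,
            dimnames = list(sprintf("cpd%04d", seq_len(n)), bit_ids))
        k_pos <- .nearest_int(planted$support * planted$pr_target)
        k_neg <- planted$support - k_pos
        if (any(k_pos > spec@n_pos) || any(k_neg > spec@n_neg))
            stop("infeasible planted carrier counts for class sizes")
        for (j in seq_len(nrow(planted))) {
            col <- match(planted$bit_id[j], bit_ids)
            m[, col] <- 0L
            if (k_pos[j] > 0)
                m[sample.int(spec@n_pos, k_pos[j]), col] <- 1L
            if (k_neg[j] > 0)
                m[spec@n_pos + sample.int(spec@n_neg, k_neg[j]), col] <- 1L
        }
        planted$n_pos <- k_pos
        planted$n_neg <- k_neg
        list(matrix = FingerprintMatrix(m,
                catalog_ref = sprintf("synthetic:seed=%d", spec@seed)),
            labels = rep(c(1L, 0L), c(spec@n_pos, spec@n_neg)),
            planted = planted)
    })
}

# one exemplar template per bundled alert bit: %s is replaced by an alkyl
# chain; the chain-free variant must itself carry the bit
.ALERT_EXEMPLARS <- list(
    KR413 = c("CCCc1ccccc1", "CCCCc1ccccc1", "OCCc1ccccc1",
        "CC(C)CCc1ccccc1"),
    KR848 = c("CNC(=O)C(C)NC(=O)C", "CCNC(=O)C(C)NC(=O)C",
        "CNC(=O)C(C)NC(=O)CC", "CCNC(=O)C(C)NC(=O)CC"),
    KR1798 = c("OCCc1ccc(F)cc1", "OCc1ccc(F)cc1", "CCCCc1ccc(F)cc1",
        "CC(C)c1ccc(F)cc1"),
    KR2444 = c("CN1CCN(C)CC1", "CCN1CCN(C)CC1", "CCCN1CCN(C)CC1",
        "OCCN1CCN(C)CC1"),
    KR3206 = c("c1ccc2[nH]cnc2c1", "Cc1nc2ccccc2[nH]1",
        "CCc1nc2ccccc2[nH]1", "Cc1ccc2[nH]cnc2c1"),
    KR3280 = c("CC(=O)c1ccc(N)cc1", "CCC(=O)c1ccc(N)cc1",
        "CCCC(=O)c1ccc(N)cc1", "CC(C)C(=O)c1ccc(N)cc1"),
    KR3540 = c("Cc1ccc(cc1)c2ccccc2", "CCc1ccc(cc1)c2ccccc2",
        "CCCc1ccc(cc1)c2ccccc2", "CC(C)c1ccc(cc1)c2ccccc2"),
    KR3548 = c("Cc1ccc(F)cc1", "CCc1ccc(F)cc1", "CCCc1ccc(F)cc1",
        "CC(C)Cc1ccc(F)cc1"),
    KR3586 = c("Cc1cccc(F)c1", "CCc1cccc(F)c1", "CCCc1cccc(F)c1",
        "CC(C)c1cccc(F)c1"),
    KR4029 = c("CSc1nc2ccccc2[nH]1", "CCSc1nc2ccccc2[nH]1",
        "CCCSc1nc2ccccc2[nH]1", "CSc1nc2ccc(C)cc2[nH]1"),
    KR4064 = c("Fc1cccc(C=O)c1", "Cc1cc(F)cc(C=O)c1",
        "CCc1cc(F)cc(C=O)c1", "CCCc1cc(F)cc(C=O)c1"),
    KR4065 = c("Fc1cccc(F)c1", "Cc1cc(F)cc(F)c1", "CCc1cc(F)cc(F)c1",
        "OCc1cc(F)cc(F)c1"),
    KR4081 = c("N#Cc1ccccc1", "N#Cc1ccccc1C", "N#Cc1ccc(C)cc1",
        "N#Cc1ccc(CC)cc1"),
    KR4252 = c("Nc1ccc(F)cc1", "CNc1ccc(F)cc1", "CCNc1ccc(F)cc1",
        "Nc1ccc(F)cc1C"),
    KR4556 = c("O=CNCCCCNC=O", "CC(=O)NCCCCNC=O", "CCC(=O)NCCCCNC=O",
        "CC(=O)NCCCCNC(=O)C"),
    KR4651 = c("OC(=O)C1CCCN1", "OC(=O)C1CCCN1C", "CCOC(=O)C1CCCN1",
        "OC(=O)C1CCCN1CC"))

# scaffolds free of every bundled alert pattern (no aromatics, no amides,
# no nitriles, no fluorine): plain alkyl/oxygen/amine chemistry
.CLEAN_SCAFFOLDS <- c(
    "CCO", "CCCO", "CCCCO", "CC(C)O", "CCOCC", "CCCOC", "CC(=O)CC",
    "CCC(=O)CC", "CCOC(=O)C", "CCCN", "CCNCC", "C1CCCCC1", "CC1CCCCC1",
    "OC1CCCCC1", "CCC(C)CC", "CCCCCC", "OCCO", "CCOCCO", "CC(C)CC(C)C",
    "CCCC(=O)OC", "CC(C)(C)CO", "OCC(O)CO", "CCCCC(C)O", "CC(O)C(C)O",
    "CCCCCCO", "CC(C)CO", "CCC(O)CC", "CCCC(C)O", "CCOC(C)C", "CCCOCC",
    "CCC(=O)CCC", "CCCC(=O)C", "CCC(=O)OC", "CCCOC(=O)C", "CCCCN",
    "CC(C)N", "CCN(C)C", "C1CCCC1", "CC1CCCC1", "C1CCOC1", "C1CCOCC1",
    "OC1CCCC1", "CC(O)CC(C)O", "CCCCCCC", "CCC(C)(C)O", "COCCOC",
    "CCCCOC", "CC(C)OC(C)C")

#' Generate a synthetic compound set carrying bundled alert substructures
#'
#' Positive (nephrotoxic) compounds are built from exemplar molecules that
#' contain one of the bundled alert substructures (alkyl-extended variants
#' of each pattern); negative compounds are drawn from plain
#' alkyl/ether/amine scaffolds guaranteed free of all bundled patterns.
#' Every emitted structure is verified against the catalog: a positive must
#' match its intended bit and a negative must match none (violations are
#' retried with a fresh scaffold, then raise an error). By construction the
#' bundled alerts perfectly separate the classes, so mining on the
#' generated set recovers the planted bits and the alert screen classifies
#' it perfectly.
#'
#' @param n_pos,n_neg class sizes.
#' @param bits which bundled alert bits to plant (default: all 16).
#' @param seed integer seed (single RNG stream, caller state untouched).
#' @return list with `set` (a [CompoundSet-class]; positives first) and
#'   `planted_bits` (character vector of the planted bit ids).
#' @examples
#' \dontrun{
#' g <- generateSyntheticCompounds(n_pos = 16, n_neg = 16, seed = 7)
#' fpm <- buildFingerprintMatrix(g$set, bundledAlertCatalog())
#' }
#' @export
generateSyntheticCompounds <- function(n_pos = 32, n_neg = 32, bits = NULL,
                                       seed = 1) {
    catalog <- bundledAlertCatalog()
    if (is.null(bits)) bits <- bitIds(catalog)
    unknown <- setdiff(bits, names(.ALERT_EXEMPLARS))
    if (length(unknown))
        stop("no exemplars for bit(s): ", paste(unknown, collapse = ", "))
    .with_seed(seed, {
        pos_bits <- rep_len(bits, n_pos)
        # draw each bit's exemplar variants without replacement while they
        # last, so small sets contain no duplicate structures
        pos_smi <- character(n_pos)
        for (b in unique(pos_bits)) {
            idx <- which(pos_bits == b)
            pool <- .ALERT_EXEMPLARS[[b]]
            take <- c(sample(pool, min(length(idx), length(pool))),
                if (length(idx) > length(pool))
                    sample(pool, length(idx) - length(pool),
                        replace = TRUE))
            pos_smi[idx] <- take
        }
        neg_smi <- sample(.CLEAN_SCAFFOLDS, n_neg,
            replace = n_neg > length(.CLEAN_SCAFFOLDS))
        # verification pass: negatives must be free of every pattern
        for (attempt in 1:5) {
            fpm <- buildFingerprintMatrix(neg_smi, catalog)
            dirty <- rowSums(presenceMatrix(fpm)) > 0
            if (!any(dirty)) break
            if (attempt == 5)
                stop("could not generate alert-free negatives after ",
                     "5 attempts")
            neg_smi[dirty] <- sample(.CLEAN_SCAFFOLDS, sum(dirty),
                replace = TRUE)
        }
        pos_fpm <- buildFingerprintMatrix(pos_smi, catalog)
        hit <- presenceMatrix(pos_fpm)[cbind(seq_len(n_pos),
            match(pos_bits, bitIds(catalog)))]
        if (any(hit == 0))
            stop("exemplar failed to match its intended bit: ",
                 paste(unique(pos_bits[hit == 0]), collapse = ", "))
        set <- CompoundSet(
            sprintf("syn%04d", seq_len(n_pos + n_neg)),
            c(pos_smi, neg_smi),
            rep(c(1L, 0L), c(n_pos, n_neg)),
            provenance = sprintf("synthetic alert carriers (seed %d)", seed))
        list(set = set, planted_bits = unique(pos_bits))
    })
}
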