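# Internal Open Babel helpers. All chemistry toolkit calls are funnelled
# through this file so the rest of the package never touches ChemmineOB
# directly.

# Parse a vector of SMILES into an SDFset; returns list(sdf, valid).
# Invalid entries are detected via ChemmineR::validSDF, never dropped
# silently.
.smiles_to_sdf <- function(smiles, ids = NULL) {
    if (is.null(ids)) ids <- sprintf("mol%04d", seq_along(smiles))
    x <- setNames(as.character(smiles), ids)
    sdf <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(x)),
        error = function(e) NULL)
    if (is.null(sdf))
        return(list(sdf = NULL, valid = rep(FALSE, length(x))))
    valid <- suppressWarnings(ChemmineR::validSDF(sdf))
    # a parse failure can also surface as an empty molecule
    natoms <- vapply(seq_along(sdf), function(i)
        tryCatch(nrow(ChemmineR::atomblock(sdf[[i]])), error = function(e) 0L),
        integer(1))
    valid <- valid & natoms > 0L
    list(sdf = sdf, valid = valid)
}

# Surface-level SMILES syntax check: balanced branches/brackets and paired
# ring-closure digits. Needed because the toolkit silently truncates some
# malformed strings (e.g. "C((") instead of rejecting them.
.smiles_syntax_ok <- function(s) {
    chars <- strsplit(s, "")[[1]]
    if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
    if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0)) return(FALSE)
    # ring closures outside brackets must pair up
    bare <- gsub("\\[[^]]*\\]", "", s)
    bare <- gsub("%[0-9]{2}", "R", bare)  # two-digit closures
    digits <- gregexpr("[0-9]", bare)[[1]]
    if (digits[1] != -1) {
        d <- substring(bare, digits, digits)
        if (any(table(d) %% 2 != 0)) return(FALSE)
    }
    TRUE
}

# TRUE iff the SMILES is well-formed and parses to at least one atom.
.smiles_valid <- function(smiles) {
    out <- rep(FALSE, length(smiles))
    ok <- !is.na(smiles) & nzchar(trimws(smiles))
    ok[ok] <- vapply(smiles[ok], .smiles_syntax_ok, logical(1))
    if (any(ok)) {
        parsed <- .smiles_to_sdf(smiles[ok])
        natoms <- vapply(seq_along(parsed$sdf), function(i)
            tryCatch(nrow(ChemmineR::atomblock(parsed$sdf[[i]])),
                error = function(e) 0L), integer(1))
        out[ok] <- natoms > 0L
    }
    out
}

# Canonical SMILES via Open Babel; input assumed parseable.
.canonical_smiles <- function(smiles) {
    vapply(smiles, function(s) {
        out <- ChemmineOB::convertFormat("SMI", "CAN", s)
        sub("[ \t].*$", "", trimws(out))
    }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES after neutralizing protonation states (e.g. carboxylates
# left behind once a counter-ion is stripped).
.neutral_canonical_smiles <- function(smiles) {
    vapply(smiles, function(s) {
        out <- ChemmineOB::convertFormat("SMI", "CAN", s,
            options = data.frame(names = "neutralize", args = "",
                stringsAsFactors = FALSE))
        sub("[ \t].*$", "", trimws(out))
    }, character(1), USE.NAMES = FALSE)
}

# TRUE iff the SMARTS pattern compiles.
.smarts_parses <- function(smarts) {
    if (is.na(smarts) || !nzchar(smarts)) return(FALSE)
    probe <- .smiles_to_sdf("CC")$sdf
    ok <- TRUE
    tryCatch(
        withCallingHandlers(
            ChemmineR::smartsSearchOB(probe, smarts, uniqueMatches = FALSE),
            warning = function(w) {
                ok <<- FALSE
                invokeRestart("muffleWarning")
            }),
        error = function(e) ok <<- FALSE)
    ok
}

# Embedding counts of one SMARTS over an SDFset (0 = absent).
.smarts_counts <- function(sdf, smarts, bit_id = smarts) {
    tryCatch(
        ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE),
        error = function(e)
            stop("SMARTS match failed for bit '", bit_id, "': ",
                 conditionMessage(e), call. = FALSE))
}

# Molecular formula -> named element counts ("C7H7F" -> c(C=7, H=7, F=1)).
.parse_formula <- function(formula) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    el <- sub("[0-9]*$", "", toks)
    n <- as.integer(sub("^[A-Za-z]+", "", toks))
    n[is.na(n)] <- 1L
    tapply(n, el, sum)
}

# Heavy-atom and carbon counts of canonical-SMILES fragments by token
# scanning (robust for single-atom fragments like [Na+] that the SDF path
# cannot represent). Two-letter organic-subset symbols (Cl, Br) are matched
# before single letters; bracket atoms contribute their element symbol.
.fragment_sizes <- function(smiles) {
    one <- function(s) {
        heavy <- 0L; carbons <- 0L
        # bracket atoms: [13CH3], [Na+], [nH], ...
        brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
        for (b in brackets) {
            el <- regmatches(b,
                regexpr("[A-IK-PR-Za-ik-pr-z][a-z]?", b))  # skip isotopes
            if (length(el) && el != "H") {
                heavy <- heavy + 1L
                if (toupper(el) %in% c("C", "CH")) carbons <- carbons + 1L
            }
        }
        bare <- gsub("\\[[^]]*\\]", "", s)
        toks <- regmatches(bare,
            gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", bare))[[1]]
        heavy <- heavy + length(toks)
        carbons <- carbons + sum(toks %in% c("C", "c"))
        c(heavy = heavy, carbons = carbons)
    }
    t(vapply(smiles, one, c(heavy = 0L, carbons = 0L)))
}

# MD5 of an in-memory character scalar (via a temp file; tools::md5sum is
# file-based).
.md5_of <- function(txt) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(txt, tf)
    unname(tools::md5sum(tf))
}

# Nearest integer as floor(x + 0.5): round-half-up, independent of the
# IEEE round-half-even used by base::round.
.nearest_int <- function(x) floor(x + 0.5)

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
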