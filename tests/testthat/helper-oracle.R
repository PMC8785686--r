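# Independent oracles used by the tests. These share no code with the
# package: a tiny SMILES/SMARTS graph parser plus a brute-force subgraph
# embedding enumerator (backtracking over injective atom mappings), an
# exhaustive pair-counting AUC, and a literal Fisher-score formula.
#
# The parser covers the vocabulary of the bundled alert patterns and the
# test fixtures: organic-subset atoms (C N O S P F I, Cl, Br; aromatic
# c n o s), bracket atoms ([nH], [NH], [CH2], [CH3], [CH], [cH], [Na+],
# [!#1]), bonds - = # :, branches, and single-digit ring closures.

.oracle_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
    I = 1, P = 3, B = 3)

oracle_parse <- function(s, smarts = FALSE) {
    chars <- strsplit(s, "")[[1]]
    atoms <- list()   # each: list(elem, aromatic, hcount, any)
    bonds <- list()   # each: c(a, b, code) 0=unspec 1,2,3 4=':'
    prev <- NA_integer_; pending <- 0L
    stack <- integer(); ring <- list()
    add_atom <- function(elem, aromatic, hcount, any = FALSE) {
        atoms[[length(atoms) + 1L]] <<- list(elem = elem,
            aromatic = aromatic, hcount = hcount, any = any)
        id <- length(atoms)
        if (!is.na(prev))
            bonds[[length(bonds) + 1L]] <<- c(prev, id, pending)
        prev <<- id; pending <<- 0L
        id
    }
    i <- 1L; n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
        else if (ch == ")") {
            prev <- stack[length(stack)]
            stack <- stack[-length(stack)]; i <- i + 1L
        }
        else if (ch %in% c("-", "/", "\\")) { pending <- 1L; i <- i + 1L }
        else if (ch == "=") { pending <- 2L; i <- i + 1L }
        else if (ch == "#") { pending <- 3L; i <- i + 1L }
        else if (ch == ":") { pending <- 4L; i <- i + 1L }
        else if (grepl("[0-9]", ch)) {
            if (!is.null(ring[[ch]])) {
                op <- ring[[ch]]
                code <- max(pending, op$pending)
                bonds[[length(bonds) + 1L]] <- c(op$atom, prev, code)
                ring[[ch]] <- NULL
            } else ring[[ch]] <- list(atom = prev, pending = pending)
            pending <- 0L; i <- i + 1L
        }
        else if (ch == "[") {
            j <- i
            while (chars[j] != "]") j <- j + 1L
            content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
            if (content == "!#1") {
                if (!smarts) stop("!#1 is SMARTS-only")
                add_atom(NA_character_, NA, NA_integer_, any = TRUE)
            } else {
                content <- sub("^[0-9]+", "", content)   # isotope
                el <- regmatches(content,
                    regexpr("^([A-Z][a-z]?|[a-z])", content))
                rest <- sub("^([A-Z][a-z]?|[a-z])", "", content)
                rest <- gsub("@", "", rest)
                hc <- if (grepl("H", rest)) {
                    hd <- regmatches(rest, regexpr("H[0-9]*", rest))
                    hd <- sub("H", "", hd)
                    if (nzchar(hd)) as.integer(hd) else 1L
                } else if (smarts) NA_integer_ else 0L
                aromatic <- el == tolower(el)
                elem <- paste0(toupper(substr(el, 1, 1)),
                    substr(el, 2, nchar(el)))
                add_atom(elem, aromatic, hc)
            }
            i <- j + 1L
        }
        else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
            add_atom(paste0(ch, chars[i + 1L]), FALSE, NA_integer_)
            i <- i + 2L
        }
        else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
            add_atom(ch, FALSE, NA_integer_); i <- i + 1L
        }
        else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
            add_atom(toupper(ch), TRUE, NA_integer_); i <- i + 1L
        }
        else stop("oracle parser: unexpected character '", ch, "' in ", s)
    }
    bonds <- if (length(bonds)) do.call(rbind, bonds)
        else matrix(integer(), 0, 3)
    list(atoms = atoms, bonds = bonds, smarts = smarts)
}

# is bond k part of a cycle? (still a path from a to b without it)
.oracle_in_cycle <- function(bonds, k, natoms) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj <- lapply(seq_len(natoms), function(x) integer())
    for (j in seq_len(nrow(bonds))) {
        if (j == k) next
        adj[[bonds[j, 1]]] <- c(adj[[bonds[j, 1]]], bonds[j, 2])
        adj[[bonds[j, 2]]] <- c(adj[[bonds[j, 2]]], bonds[j, 1])
    }
    seen <- rep(FALSE, natoms); queue <- a; seen[a] <- TRUE
    while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        if (x == b) return(TRUE)
        nxt <- adj[[x]][!seen[adj[[x]]]]
        seen[nxt] <- TRUE; queue <- c(queue, nxt)
    }
    FALSE
}

# finalize a molecule: resolve bond orders ("ar" for aromatic) and
# implicit hydrogen counts
oracle_molecule <- function(s) {
    g <- oracle_parse(s, smarts = FALSE)
    natoms <- length(g$atoms)
    nb <- nrow(g$bonds)
    order <- character(nb)
    for (k in seq_len(nb)) {
        code <- g$bonds[k, 3]
        a <- g$atoms[[g$bonds[k, 1]]]; b <- g$atoms[[g$bonds[k, 2]]]
        order[k] <- if (code == 4) "ar"
            else if (code %in% 1:3) as.character(code)
            else if (isTRUE(a$aromatic) && isTRUE(b$aromatic) &&
                     .oracle_in_cycle(g$bonds, k, natoms)) "ar"
            else "1"
    }
    h <- integer(natoms)
    for (v in seq_len(natoms)) {
        at <- g$atoms[[v]]
        if (!is.na(at$hcount)) { h[v] <- at$hcount; next }
        val <- .oracle_valence[[at$elem]]
        if (is.null(val)) { h[v] <- 0L; next }
        inc <- which(g$bonds[, 1] == v | g$bonds[, 2] == v)
        deg <- sum(vapply(inc, function(k)
            if (order[k] == "ar") 1 else as.integer(order[k]), numeric(1)))
        if (isTRUE(at$aromatic)) deg <- deg + 1  # delocalized bond share
        h[v] <- max(0L, as.integer(val - deg))
    }
    list(atoms = g$atoms, bonds = g$bonds, order = order, h = h)
}

.oracle_atom_ok <- function(p, mol, v) {
    if (isTRUE(p$any)) return(TRUE)
    m <- mol$atoms[[v]]
    if (p$elem != m$elem) return(FALSE)
    if (!identical(p$aromatic, m$aromatic)) return(FALSE)
    is.na(p$hcount) || p$hcount == mol$h[v]
}

.oracle_bond_ok <- function(code, morder) {
    switch(as.character(code),
        "0" = morder %in% c("1", "ar"),
        "1" = morder == "1",
        "2" = morder == "2",
        "3" = morder == "3",
        "4" = morder == "ar")
}

# count subgraph embeddings (injective atom maps, non-induced) of a SMARTS
# pattern in a molecule by exhaustive backtracking
oracle_count_embeddings <- function(molecule_smiles, smarts) {
    mol <- oracle_molecule(molecule_smiles)
    pat <- oracle_parse(smarts, smarts = TRUE)
    np <- length(pat$atoms); nm <- length(mol$atoms)
    if (np == 0 || np > nm) return(0L)
    # molecule bond lookup
    bkey <- function(a, b) paste(min(a, b), max(a, b))
    mbond <- setNames(mol$order,
        vapply(seq_len(nrow(mol$bonds)), function(k)
            bkey(mol$bonds[k, 1], mol$bonds[k, 2]), character(1)))
    # pattern bonds incident to each atom
    pb <- pat$bonds
    count <- 0L
    map <- integer(np)
    extend <- function(depth) {
        if (depth > np) { count <<- count + 1L; return(invisible()) }
        for (v in seq_len(nm)) {
            if (v %in% map[seq_len(depth - 1L)]) next
            if (!.oracle_atom_ok(pat$atoms[[depth]], mol, v)) next
            ok <- TRUE
            for (k in seq_len(nrow(pb))) {
                a <- pb[k, 1]; b <- pb[k, 2]
                if (a == depth && b < depth) { o <- b }
                else if (b == depth && a < depth) { o <- a }
                else next
                mo <- mbond[bkey(v, map[o])]
                if (is.na(mo) || !.oracle_bond_ok(pb[k, 3], mo)) {
                    ok <- FALSE; break
                }
            }
            if (ok) { map[depth] <<- v; extend(depth + 1L) }
        }
        invisible()
    }
    extend(1L)
    count
}

oracle_matches <- function(molecule_smiles, smarts)
    as.integer(oracle_count_embeddings(molecule_smiles, smarts) > 0)

# AUC by exhaustive positive/negative pair counting (ties count half)
oracle_auc <- function(scores, labels) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

# Fisher score computed literally from its definition, one bit at a time
oracle_fisher <- function(x, labels) {
    xp <- x[labels == 1]; xn <- x[labels == 0]
    m <- mean(x); mp <- mean(xp); mn <- mean(xn)
    num <- (mp - m)^2 + (mn - m)^2
    den <- sum((xp - mp)^2) / (length(xp) - 1) +
        sum((xn - mn)^2) / (length(xn) - 1)
    if (den == 0) { if (num > 0) Inf else 0 } else num / den
}
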