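test_that("the bundled catalog loads and every pattern parses", {
    cat16 <- bundledAlertCatalog()
    expect_identical(length(cat16), 16L)
    expect_identical(anyDuplicated(bitIds(cat16)), 0L)
    expect_true(all(nzchar(catalogSmarts(cat16))))
})

test_that("a catalog with a broken pattern errors naming the bit", {
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(bit_id = c("ok", "broken"),
        smarts = c("c1ccccc1", "[!#1")), f, row.names = FALSE)
    expect_error(readSmartsCatalog(f), "broken")
    cat2 <- readSmartsCatalog(f, validate = FALSE)  # opt-out still loads
    expect_identical(length(cat2), 2L)
})

test_that("matchSmarts reports presence, not counts", {
    expect_identical(matchSmarts("Cc1ccc(F)cc1", "Cc1ccc(F)cc1"), 1L)
    expect_identical(matchSmarts("CCO", "N#Cc1ccccc1"), 0L)
    # benzene has 12 embeddings of its own ring but presence is 1
    expect_identical(matchSmarts("c1ccccc1", "c1ccccc1"), 1L)
    expect_error(matchSmarts("C((", "c1ccccc1"), "unparseable")
})

test_that("fingerprints set the expected alert bits", {
    cat16 <- bundledAlertCatalog()
    fp <- computeFingerprint("c1ccc2[nH]cnc2c1", cat16)
    expect_identical(unname(fp["KR3206"]), 1L)
    expect_identical(sum(fp), 1L)  # plain benzimidazole carries only KR3206

    fp2 <- computeFingerprint("CCO", cat16)
    expect_identical(sum(fp2), 0L)
})

test_that("fingerprints are permutation-equivariant in the catalog", {
    cat16 <- bundledAlertCatalog()
    perm <- rev(seq_len(length(cat16)))
    fp <- computeFingerprint("CSc1nc2ccccc2[nH]1", cat16)
    fp_perm <- computeFingerprint("CSc1nc2ccccc2[nH]1", cat16[perm])
    expect_identical(fp_perm, fp[perm])
})

test_that("fingerprints depend on the structure, not atom ordering", {
    cat16 <- bundledAlertCatalog()
    aliases <- list(
        c("Cc1ccc(F)cc1", "Fc1ccc(C)cc1"),
        c("CC(=O)c1ccc(N)cc1", "Nc1ccc(cc1)C(C)=O"),
        c("OC(=O)C1CCCN1", "C1CC(C(=O)O)NC1"))
    for (pair in aliases)
        expect_identical(computeFingerprint(pair[1], cat16),
            computeFingerprint(pair[2], cat16))
})

test_that("empty inputs produce empty, well-formed results", {
    empty_cat <- SmartsCatalog(character(), character())
    fp <- computeFingerprint("CCO", empty_cat)
    expect_identical(length(fp), 0L)
    cs <- CompoundSet(character(), character(), integer())
    m <- buildFingerprintMatrix(cs, bundledAlertCatalog())
    expect_identical(dim(m), c(0L, 16L))
})

test_that("matrix rows equal per-compound fingerprints; column sums are
           support recounts", {
    cat16 <- bundledAlertCatalog()
    smi <- oracle_fixture_smiles()[1:8]
    cs <- CompoundSet(names(smi), unname(smi), rep(0L, length(smi)))
    m <- buildFingerprintMatrix(cs, cat16)
    for (i in seq_along(smi))
        expect_identical(unname(presenceMatrix(m)[i, ]),
            unname(computeFingerprint(smi[[i]], cat16)))
    # support recount: column sums vs an explicit per-bit loop
    recount <- vapply(catalogSmarts(cat16), function(pat)
        sum(vapply(smi, function(s) matchSmarts(s, pat), integer(1))),
        integer(1))
    expect_identical(unname(colSums(presenceMatrix(m))),
        as.numeric(recount))
})

test_that("tanimoto handles the standard identities", {
    expect_identical(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
    expect_identical(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
    expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
    expect_identical(tanimoto(c(0, 0), c(0, 0)), 0)   # 0/0 convention
    expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("mean pairwise TSI matches pair enumeration and is symmetric", {
    m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 1, 0))
    expected <- mean(c(tanimoto(m[1, ], m[2, ]), tanimoto(m[1, ], m[3, ]),
        tanimoto(m[2, ], m[3, ])))
    expect_equal(meanPairwiseTsi(m), expected)
    expect_equal(meanPairwiseTsi(m[c(3, 1, 2), ]), expected)
    ident <- matrix(1, 4, 5, dimnames = list(paste0("c", 1:4), NULL))
    expect_equal(meanPairwiseTsi(ident), 1)
    expect_error(meanPairwiseTsi(m[1, , drop = FALSE]), "at least 2")
})

test_that("ECFP4 diversity fingerprints feed the TSI summary", {
    smi <- oracle_fixture_smiles()[1:6]
    fpm <- ecfpFingerprints(unname(smi))
    expect_identical(nrow(presenceMatrix(fpm)), 6L)
    tsi <- meanPairwiseTsi(fpm)
    expect_true(tsi > 0 && tsi < 1)   # related but non-identical molecules
    # identical structures are maximally similar
    expect_equal(meanPairwiseTsi(ecfpFingerprints(rep("CCO", 3))), 1)
})

test_that("fingerprint matrices round-trip through wide and triplet CSV", {
    cat16 <- bundledAlertCatalog()
    g <- generateSyntheticCompounds(6, 6, seed = 5)
    m <- buildFingerprintMatrix(g$set, cat16)
    labels <- unname(compoundLabels(g$set))

    wide <- tempfile(fileext = ".csv")
    writeFingerprintMatrix(m, wide, labels = labels)
    back <- readFingerprintMatrix(wide)
    expect_identical(presenceMatrix(back$matrix), presenceMatrix(m))
    expect_identical(back$labels, labels)

    trip <- tempfile(fileext = ".csv")
    writeFingerprintTriplets(m, trip)
    back2 <- readFingerprintTriplets(trip)
    expect_identical(presenceMatrix(back2), presenceMatrix(m))
})
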