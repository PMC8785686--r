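test_that("CSV compound tables read in file order with strict labels", {
    p <- write_compound_csv(small_compound_df())
    cs <- loadCompounds(p)
    expect_s4_class(cs, "CompoundSet")
    expect_identical(compoundIds(cs), c("c1", "c2", "c3"))
    expect_identical(unname(compoundLabels(cs)), c(1L, 0L, 1L))
    expect_identical(nrow(rejects(cs)), 0L)

    # text labels decode; unknown encodings never coerce
    d <- small_compound_df()
    d$label <- c("nephrotoxic", "non-nephrotoxic", "1")
    cs2 <- loadCompounds(write_compound_csv(d))
    expect_identical(unname(compoundLabels(cs2)), c(1L, 0L, 1L))
    d$label <- c("yes", "no", "1")
    expect_error(loadCompounds(write_compound_csv(d)), "unrecognized label")
})

test_that("unparseable structures become rejects, never silent drops", {
    d <- data.frame(compound_id = paste0("c", 1:4),
        smiles = c("CCO", "C((", "c1ccccc1", "CCN"),
        label = c(1, 1, 0, 0))
    cs <- loadCompounds(write_compound_csv(d))
    expect_identical(length(cs), 3L)
    expect_identical(rejects(cs)$compound_id, "c2")
    expect_match(rejects(cs)$reason, "unparseable")

    # all-bad input is an explicit error, not an empty set
    d$smiles <- rep("C((", 4)
    expect_error(loadCompounds(write_compound_csv(d)), "no parseable")
})

test_that("missing label column is a configuration error", {
    d <- small_compound_df()
    d$label <- NULL
    expect_error(loadCompounds(write_compound_csv(d)), "label")
})

test_that("SDF and SMI round trips reproduce the set field-for-field", {
    cs <- CompoundSet(c("a", "b", "c"),
        c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
        c(1, 0, 1), split = c("train", "validation", "train"))
    for (fmt in c("csv", "sdf", "smi")) {
        f <- tempfile(fileext = paste0(".", fmt))
        writeCompounds(cs, f)
        back <- loadCompounds(f)
        expect_identical(compoundIds(back), compoundIds(cs), label = fmt)
        expect_identical(compoundLabels(back), compoundLabels(cs),
            label = fmt)
        expect_identical(compoundSplits(back), compoundSplits(cs),
            label = fmt)
        # SDF re-derives SMILES from the connection table; compare
        # standardized forms rather than strings
        expect_identical(standardizeSmiles(unname(compoundSmiles(back))),
            standardizeSmiles(unname(compoundSmiles(cs))), label = fmt)
    }
})

test_that("standardization strips salts and keeps the larger organic part", {
    expect_identical(as.character(standardizeSmiles("CC(=O)O.[Na+]")),
        as.character(standardizeSmiles("CC(=O)O")))
    # benzene is already standard
    expect_identical(as.character(standardizeSmiles("c1ccccc1")),
        as.character(standardizeSmiles("c1ccccc1")))
    # mixture: phenol (7 heavy atoms) beats ethanol (3)
    expect_identical(as.character(standardizeSmiles("CCO.c1ccccc1O")),
        as.character(standardizeSmiles("Oc1ccccc1")))
    # counter-ion stripping neutralizes the parent
    expect_identical(as.character(standardizeSmiles("CC(=O)[O-].[Na+]")),
        as.character(standardizeSmiles("CC(=O)O")))
})

test_that("purely inorganic input is flagged, not guessed", {
    out <- standardizeSmiles(c("[Na+].[Cl-]", "CCO"))
    expect_true(is.na(out[1]))
    expect_match(attr(out, "errors")[1], "no organic fragment")
    expect_false(is.na(out[2]))

    cs <- CompoundSet(c("a", "b"), c("[Na+].[Cl-]", "CCO"), c(1, 0))
    std <- standardizeCompounds(cs)
    expect_identical(length(std), 1L)
    expect_identical(rejects(std)$compound_id, "a")
})

test_that("standardization is idempotent on the fixture structures", {
    smi <- unname(oracle_fixture_smiles())
    once <- as.character(standardizeSmiles(smi))
    twice <- as.character(standardizeSmiles(once))
    expect_identical(twice, once)
})

test_that("duplicates collapse on the standardized canonical form", {
    cs <- CompoundSet(paste0("c", 1:4),
        c("CCO", "OCC", "c1ccccc1", "CC(=O)[O-].[Na+]"),
        c(1, 1, 0, 0))
    std <- standardizeCompounds(cs)
    ded <- deduplicateCompounds(std)
    # OCC standardizes to the same canonical ethanol as CCO
    expect_identical(length(ded), 3L)
    expect_identical(rejects(ded)$compound_id, "c2")
    expect_match(rejects(ded)$reason, "duplicate of c1")

    # duplicate-free input passes through unchanged
    again <- deduplicateCompounds(ded)
    expect_identical(compoundData(again), compoundData(ded))
})

test_that("splitting draws exact class counts and conserves totals", {
    n_pos <- 287L; n_neg <- 278L
    cs <- CompoundSet(sprintf("c%03d", 1:(n_pos + n_neg)),
        rep(c("CCO", "CCN"), c(n_pos, n_neg)),
        rep(c(1, 0), c(n_pos, n_neg)))
    sp <- splitDataset(cs, 232, 224, seed = 42)
    d <- compoundData(sp)
    expect_identical(sum(d$split == "train" & d$label == 1), 232L)
    expect_identical(sum(d$split == "train" & d$label == 0), 224L)
    # remainder is the validation set: 55 positives, 54 negatives
    expect_identical(sum(d$split == "validation" & d$label == 1), 55L)
    expect_identical(sum(d$split == "validation" & d$label == 0), 54L)
    # conservation
    expect_identical(sum(d$label == 1), n_pos)
    expect_identical(sum(d$label == 0), n_neg)

    # determinism and seed sensitivity
    sp2 <- splitDataset(cs, 232, 224, seed = 42)
    expect_identical(compoundData(sp2), compoundData(sp))
    sp3 <- splitDataset(cs, 232, 224, seed = 43)
    expect_false(identical(compoundData(sp3)$split, d$split))
})

test_that("split boundaries and overdraws are handled", {
    cs <- CompoundSet(paste0("c", 1:6), rep("CCO", 6), c(1, 1, 1, 0, 0, 0))
    all_pos <- splitDataset(cs, 3, 1, seed = 1)
    d <- compoundData(all_pos)
    expect_identical(sum(d$split == "validation" & d$label == 1), 0L)
    expect_error(splitDataset(cs, 4, 1), "training positives")
    expect_error(splitDataset(cs, 1, 4), "training negatives")
})
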