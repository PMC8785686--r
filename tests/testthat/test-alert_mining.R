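test_that("bitCounts tallies carriers per class and survives recounting", {
    m <- matrix(c(1, 1, 1, 0, 0,
                  0, 0, 0, 0, 0,
                  1, 0, 0, 1, 1), ncol = 3,
        dimnames = list(paste0("c", 1:5), c("bitA", "bitB", "bitC")))
    labels <- c(1, 1, 1, 0, 0)
    cnt <- bitCounts(m, labels)
    expect_identical(cnt$n_pos, c(3, 0, 1))
    expect_identical(cnt$n_neg, c(0, 0, 2))
    expect_identical(cnt$n_total, cnt$n_pos + cnt$n_neg)

    # independent recount by transposed iteration
    for (j in seq_len(ncol(m))) {
        np <- 0; nn <- 0
        for (i in seq_len(nrow(m))) {
            if (m[i, j] == 1 && labels[i] == 1) np <- np + 1
            if (m[i, j] == 1 && labels[i] == 0) nn <- nn + 1
        }
        expect_identical(c(cnt$n_pos[j], cnt$n_neg[j]), c(np, nn))
    }
    expect_error(bitCounts(m, labels[-1]), "length")
})

test_that("positive rate follows its definition incl. edge cases", {
    expect_identical(positiveRate(9, 0), 1)
    expect_identical(positiveRate(0, 7), 0)
    expect_identical(positiveRate(3, 1), 0.75)
    expect_true(is.na(positiveRate(0, 0)))
    # vectorized, monotone in n_pos at fixed total
    pr <- positiveRate(0:6, 6:0)
    expect_true(all(diff(pr) > 0))
})

test_that("Fisher score matches the literal formula and its limits", {
    labels <- rep(c(1, 0), c(6, 6))
    # identical class frequencies: score 0
    bal <- rep(c(1, 0, 1, 0), 3)
    expect_identical(unname(fisherScore(bal, labels)), 0)
    # perfect separator: +Inf
    sep <- rep(c(1, 0), c(6, 6))
    expect_identical(unname(fisherScore(sep, labels)), Inf)
    # 10-compound hand example vs the direct spreadsheet-style computation
    x <- c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0)
    l <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
    expect_equal(unname(fisherScore(x, l)), oracle_fisher(x, l))
    # more mixed cases under a fixed seed
    set.seed(19)
    for (k in 1:10) {
        x <- rbinom(12, 1, 0.4); l <- rep(c(1, 0), c(6, 6))
        expect_equal(unname(fisherScore(x, l)), oracle_fisher(x, l))
    }
    expect_error(fisherScore(x, rep(1, 12)), "both classes")
})

test_that("mining selects planted bits and orders by score", {
    set.seed(7)
    sp <- SyntheticSpec(n_pos = 40, n_neg = 40, n_bits = 300,
        background_rate = 0.05, seed = 7,
        planted = data.frame(bit_id = c("bit0010", "bit0020", "bit0030"),
            support = c(10, 8, 12), pr_target = c(1, 0.9, 0.8)))
    g <- generatePlantedMatrix(sp)
    al <- mineAlerts(g$matrix, g$labels)
    tab <- alertTable(al)
    expect_identical(nrow(tab), 300L)   # one candidate per bit
    expect_true(all(sp@planted$bit_id %in% selectedBits(al)))
    # sorted by f-score descending, infinite first, ties by bit id
    d <- diff(rev(tab$f_score))   # NaN where consecutive scores are both Inf
    expect_true(all(d >= 0 | is.na(d)))
    inf_rows <- which(is.infinite(tab$f_score))
    if (length(inf_rows)) {
        expect_identical(inf_rows, seq_along(inf_rows))
        expect_identical(tab$bit_id[inf_rows],
            sort(tab$bit_id[inf_rows]))
    }
    # exclusive flag: selected and absent from negatives
    expect_identical(tab$exclusive, tab$selected & tab$n_neg == 0)
})

test_that("selection respects its invariant and unreachable thresholds", {
    g <- generatePlantedMatrix(SyntheticSpec(n_pos = 30, n_neg = 30,
        n_bits = 100, seed = 3,
        planted = data.frame(bit_id = "bit0005", support = 10,
            pr_target = 1)))
    al <- mineAlerts(g$matrix, g$labels)
    tab <- alertTable(al)
    cfg <- miningConfig(al)
    expect_identical(tab$selected,
        !is.na(tab$positive_rate) &
            tab$n_total >= cfg@min_support &
            tab$f_score >= cfg@f_min &
            tab$positive_rate >= cfg@pr_min)
    none <- mineAlerts(g$matrix, g$labels, MiningConfig(pr_min = 1.01))
    expect_identical(length(selectedBits(none)), 0L)
})

test_that("selection is monotone: raising any threshold never adds", {
    g <- generatePlantedMatrix(SyntheticSpec(n_pos = 50, n_neg = 50,
        n_bits = 200, background_rate = 0.15, seed = 11))
    base <- selectedBits(mineAlerts(g$matrix, g$labels,
        MiningConfig(min_support = 2, f_min = 0.001, pr_min = 0.5)))
    for (cfg in list(MiningConfig(min_support = 5, f_min = 0.001,
            pr_min = 0.5),
        MiningConfig(min_support = 2, f_min = 0.01, pr_min = 0.5),
        MiningConfig(min_support = 2, f_min = 0.001, pr_min = 0.8))) {
        tighter <- selectedBits(mineAlerts(g$matrix, g$labels, cfg))
        expect_true(all(tighter %in% base))
    }
})

test_that("threshold comparisons are inclusive at the boundary", {
    # bit in exactly 3 of 4 carriers positive: PR = 0.75 must pass
    m <- cbind(bit = c(1, 1, 1, 1, rep(0, 8)))
    rownames(m) <- paste0("c", 1:12)
    labels <- c(1, 1, 1, 0, rep(c(1, 0), 4))
    al <- mineAlerts(m, labels, MiningConfig(min_support = 4, f_min = 0))
    expect_identical(alertTable(al)$positive_rate, 0.75)
    expect_true(alertTable(al)$selected)
})

test_that("the F1 scoring alternative is available and sane", {
    m <- cbind(a = c(1, 1, 1, 0, 0, 0), b = c(1, 1, 1, 1, 1, 1))
    rownames(m) <- paste0("c", 1:6)
    labels <- c(1, 1, 1, 0, 0, 0)
    al <- mineAlerts(m, labels, MiningConfig(min_support = 1,
        score_method = "f1"))
    tab <- alertTable(al)
    # bit a: perfect one-rule classifier -> F1 = 1; bit b: predicts all
    # positive -> F1 = 2*3/(2*3+3+0) = 2/3
    expect_equal(tab$f_score[tab$bit_id == "a"], 1)
    expect_equal(tab$f_score[tab$bit_id == "b"], 2 / 3)
})

test_that("alert tables round-trip through CSV and JSON", {
    g <- generatePlantedMatrix(SyntheticSpec(n_pos = 20, n_neg = 20,
        n_bits = 40, seed = 2,
        planted = data.frame(bit_id = "bit0003", support = 8,
            pr_target = 1)))
    al <- mineAlerts(g$matrix, g$labels)
    fj <- tempfile(fileext = ".json")
    writeAlertTable(al, fj, format = "json")
    back <- readAlertTable(fj)
    expect_equal(alertTable(back), alertTable(al), tolerance = 1e-12)
    fc <- tempfile(fileext = ".csv")
    writeAlertTable(al, fc)
    back2 <- readAlertTable(fc)
    expect_identical(back2@table$bit_id, al@table$bit_id)
})
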