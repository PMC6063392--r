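test_that("structure Dice is exact on identity and hand-built overlaps", {
    ph <- makePhantom(smallSpec(), id = "p")
    tab <- suppressMessages(phantomHierarchy())
    sd <- structureDice(atlasFine(ph), atlasFine(ph), tab, "C")
    present <- sd$dice[!is.na(sd$dice)]
    expect_gt(length(present), 0)
    expect_true(all(present == 1))
    # hippocampus_L proxy: 8 vs 6 voxels overlapping in 5 -> 10/14
    seg <- labelVolumeFrom(4, list("8" = 1:8))
    truth <- labelVolumeFrom(4, list("8" = 4:9))
    sd2 <- structureDice(seg, truth, tab, "C")
    expect_equal(sd2$dice[sd2$structure == "Hippocampus_L"], 10 / 14)
    # a structure absent from the truth is reported NA, not zero
    expect_true(is.na(sd2$dice[sd2$structure == "Hippocampus_R"]))
    # symmetry per structure
    sd3 <- structureDice(truth, seg, tab, "C")
    expect_equal(sd2$dice, sd3$dice)
})

test_that("poor-outcome ratio counts strictly-below-threshold cases", {
    expect_equal(poorOutcomeRatio(c(0.8, 0.69, 0.9, 0.71, 0.5)), 0.4)
    expect_equal(poorOutcomeRatio(c(0.7, 0.8, 0.95)), 0)
    expect_equal(poorOutcomeRatio(c(0.1, 0.3)), 1)
    expect_equal(poorOutcomeRatio(c(0.5, 0.9, NA)), 0.5)
    expect_equal(poorOutcomeRatio(rev(c(0.8, 0.69, 0.9, 0.71, 0.5))), 0.4)
    expect_error(poorOutcomeRatio(NA_real_), "empty")
})

test_that("paired comparison matches hand-computed t and guards", {
    expect_equal(pairedCompare(c(1, 2, 3), c(1, 2, 3)),
                 list(t = 0, p = 1, df = 2L, meanDiff = 0))
    expect_warning(res <- pairedCompare(c(2, 2, 2, 2), c(1, 1, 1, 1)),
                   "zero variance")
    expect_identical(res$t, Inf)
    expect_equal(res$p, 0)
    # differences (0.5, -0.5, 1.5, 0.5): t = 0.5 / (0.8165 / 2)
    b <- c(1, 2, 1, 3)
    a <- b + c(0.5, -0.5, 1.5, 0.5)
    res <- pairedCompare(a, b)
    expect_equal(res$t, 0.5 / (sqrt(2 / 3) / 2), tolerance = 1e-6)
    expect_equal(res$meanDiff, 0.5)
    expect_error(pairedCompare(1:3, 1:4), "length mismatch")
    expect_error(pairedCompare(1, 2), "at least 2")
})

test_that("a small sweep produces complete, well-formed records", {
    lb <- makeLibrary(librarySpec(nAtlases = 6, base = smallSpec(),
                                  seed = 4))
    lib <- lb$library
    rep <- suppressMessages(runSweep(lib, list(lib[["a03"]]),
        methods = c("LV", "random"), ks = c(2, 4), seed = 9,
        coarse = "truth"))
    recs <- sweepRecords(rep)
    expect_setequal(unique(recs$method), c("LV", "random"))
    expect_setequal(unique(recs$k), c(2, 4))
    expect_setequal(unique(recs$level), c("A", "B", "C"))
    present <- recs$dice[!is.na(recs$dice)]
    expect_true(all(present >= 0 & present <= 1))
    # summaries cover every (method, k, level) cell
    expect_equal(nrow(sweepSummaries(rep)), 2 * 2 * 3)
    expect_equal(nrow(sweepPoorRatio(rep)), 4)
    pr <- sweepPoorRatio(rep)$poor_ratio
    expect_true(all(pr >= 0 & pr <= 1))
})

test_that("saturated subsets make all methods coincide", {
    lb <- makeLibrary(librarySpec(nAtlases = 5, base = smallSpec(),
                                  seed = 4))
    lib <- lb$library
    rep <- suppressMessages(runSweep(lib, list(lib[["a02"]]),
        methods = c("4L", "random"), ks = 4, seed = 9, coarse = "truth"))
    s <- sweepSummaries(rep)
    for (lv in c("A", "B", "C"))
        expect_equal(s$mean_dice[s$method == "4L" & s$level == lv],
                     s$mean_dice[s$method == "random" & s$level == lv])
})
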