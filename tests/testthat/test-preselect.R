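test_that("an exact copy of the target ranks first under every method", {
    lb <- noiselessLibrary()
    lib <- lb$library
    target <- lib[["a04"]]
    r4 <- rankAtlases(lib, "4L", targetCoarse = atlasCoarse(target))
    rl <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target))
    rm <- rankAtlases(lib, "MI", targetImage = atlasIntensity(target))
    expect_identical(rankingOrder(r4)[1], "a04")
    expect_identical(rankingOrder(rl)[1], "a04")
    expect_identical(rankingOrder(rm)[1], "a04")
    expect_equal(max(rankingScores(r4)$value), 1.0)
    expect_equal(max(rankingScores(rm)$value), 2.0)
})

test_that("ties are broken by ascending atlas id", {
    # a01 and a03 are identical phantoms; a02 differs
    base <- smallSpec(noiseSd = 0, biasAmplitude = 0)
    big <- base; big@ventricleSemiaxes <- base@ventricleSemiaxes * 1.4
    lib <- AtlasLibrary(list(
        makePhantom(base, id = "a01"), makePhantom(big, id = "a02"),
        makePhantom(base, id = "a03")))
    target <- makePhantom(base, id = "t")
    r <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target))
    expect_identical(rankingOrder(r), c("a01", "a03", "a02"))
})

test_that("LV ranking equals an exhaustive pairwise-Dice oracle", {
    lb <- makeLibrary(librarySpec(nAtlases = 5,
        base = smallSpec(noiseSd = 0, biasAmplitude = 0),
        ventricleScaleRange = c(0.8, 1.6), seed = 3))
    lib <- lb$library
    target <- lib[["a03"]]
    r <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target),
                     targetId = "a03")
    # brute-force oracle: per-atlas ventricle Dice by direct voxel counting
    tv <- labelArray(atlasCoarse(target)) == 4L
    ids <- setdiff(atlasIds(lib), "a03")
    oracle <- vapply(ids, function(i) {
        av <- labelArray(atlasCoarse(lib[[i]])) == 4L
        2 * sum(tv & av) / (sum(tv) + sum(av))
    }, numeric(1))
    oracleOrder <- ids[order(-oracle, ids)]
    expect_identical(rankingOrder(r), oracleOrder)
    expect_equal(unname(sort(rankingScores(r)$value, decreasing = TRUE)),
                 unname(sort(oracle, decreasing = TRUE)))
    # top-k nesting across the whole range
    for (k in 1:3)
        expect_identical(selectTopK(r, k),
                         selectTopK(r, k + 1)[seq_len(k)])
})

test_that("the target is excluded from its own ranking", {
    lib <- noiselessLibrary()$library
    target <- lib[["a05"]]
    r <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target),
                     targetId = "a05")
    expect_false("a05" %in% rankingOrder(r))
    keep <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target),
                        targetId = "a05", excludeTarget = FALSE)
    expect_true("a05" %in% rankingOrder(keep))
})

test_that("ranking is invariant to library order", {
    lib <- noiselessLibrary()$library
    target <- lib[["a02"]]
    shuffled <- lib[withr::with_seed(5, sample(length(lib)))]
    r1 <- rankAtlases(lib, "LV", targetCoarse = atlasCoarse(target),
                      targetId = "a02")
    r2 <- rankAtlases(shuffled, "LV", targetCoarse = atlasCoarse(target),
                      targetId = "a02")
    expect_identical(rankingOrder(r1), rankingOrder(r2))
})

test_that("top-k selection saturates and handles edge sizes", {
    lib <- noiselessLibrary()$library
    r <- rankAtlases(lib, "LV",
                     targetCoarse = atlasCoarse(lib[["a01"]]),
                     targetId = "a01")
    expect_identical(selectTopK(r, 0), character(0))
    expect_warning(all8 <- selectTopK(r, 99), "exceeds")
    expect_identical(sort(all8), sort(setdiff(atlasIds(lib), "a01")))
})

test_that("random selection is seeded, exhaustive and uniform", {
    lib <- noiselessLibrary()$library[1:5]
    expect_identical(selectRandom(lib, 3, seed = 11),
                     selectRandom(lib, 3, seed = 11))
    expect_setequal(selectRandom(lib, 5, seed = 2), atlasIds(lib))
    expect_error(selectRandom(lib, 6, seed = 1), "exceeds")
    expect_false("a02" %in% selectRandom(lib, 4, seed = 3,
                                         exclude = "a02"))
    draws <- vapply(1:2000, function(s) selectRandom(lib, 1, seed = s),
                    character(1))
    freq <- table(draws) / 2000
    expect_true(all(abs(freq - 0.2) <= 0.03))
})
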