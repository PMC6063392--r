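mask3 <- function(idx, n = 4) {
    m <- array(FALSE, c(n, n, n)); m[idx] <- TRUE; m
}

test_that("Dice matches voxel-counting on constructed masks", {
    a <- mask3(1:4); b <- mask3(3:8)
    expect_equal(diceCoefficient(a, b), 2 * 2 / (4 + 6))
    expect_equal(diceCoefficient(mask3(c(1, 5, 9)), mask3(c(1, 5, 9))), 1)
    expect_equal(diceCoefficient(mask3(1:3), mask3(10:12)), 0)
    expect_warning(d0 <- diceCoefficient(mask3(integer(0)),
                                         mask3(integer(0))), "empty")
    expect_equal(d0, 1.0)
    expect_equal(diceCoefficient(mask3(1:3), mask3(integer(0))), 0)
    expect_error(diceCoefficient(mask3(1, n = 4), mask3(1, n = 5)),
                 "incompatible")
})

test_that("Dice is symmetric and reflexive on random masks", {
    withr::with_seed(101, {
        for (rep in 1:20) {
            a <- array(runif(64) < 0.4, c(4, 4, 4))
            b <- array(runif(64) < 0.4, c(4, 4, 4))
            if (!any(a) || !any(b)) next
            expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
            expect_equal(diceCoefficient(a, a), 1)
        }
    })
})

test_that("entropy reproduces closed-form histogram values", {
    expect_equal(intensityEntropy(array(5, c(3, 3, 3))), 0)
    # 8 bins filled equally -> 3 bits
    x <- array(rep(seq(0.5, 7.5), each = 8), c(8, 8, 1))
    expect_equal(intensityEntropy(x, nBins = 8L), 3)
    # two bins p = (0.25, 0.75) -> 0.25*2 + 0.75*log2(4/3)
    y <- array(c(rep(0, 16), rep(1, 48)), c(4, 4, 4))
    expect_equal(intensityEntropy(y, nBins = 2L), 0.811278, tolerance = 1e-6)
    expect_error(intensityEntropy(y, mask = array(FALSE, c(4, 4, 4))),
                 "empty mask")
})

test_that("entropy depends only on the multiset of bin probabilities", {
    a <- array(rep(1:4, times = c(10, 20, 30, 4)), c(4, 4, 4))
    b <- array(rep(1:4, times = c(30, 4, 10, 20)), c(4, 4, 4))
    expect_equal(intensityEntropy(a, nBins = 4L),
                 intensityEntropy(b, nBins = 4L))
})

test_that("normalized MI is 2 for self, ~1 for independence, and bounded", {
    withr::with_seed(7, {
        a <- array(rnorm(4096), c(16, 16, 16))
        expect_equal(normalizedMI(a, a), 2)
        # destroying the spatial pairing leaves equal marginals but
        # independent joints
        b <- array(sample(a), dim(a))
        expect_equal(normalizedMI(a, b, nBins = 8L), 1, tolerance = 0.02)
        for (rep in 1:10) {
            u <- array(rnorm(512), c(8, 8, 8))
            v <- array(rnorm(512, sd = 3), c(8, 8, 8))
            nmi <- normalizedMI(u, v)
            expect_gte(nmi, 1); expect_lte(nmi, 2)
            expect_equal(nmi, normalizedMI(v, u))
        }
    })
    expect_error(normalizedMI(array(1, c(2, 2, 2)),
                              array(rnorm(8), c(2, 2, 2))), "constant")
})

test_that("4L decomposes into the mean of four per-label Dices", {
    withr::with_seed(31, {
        for (rep in 1:5) {
            a <- LabelVolume(array(sample(0:4, 216, TRUE), c(6, 6, 6)),
                             table = coarseScheme()[-1, ])
            b <- LabelVolume(array(sample(0:4, 216, TRUE), c(6, 6, 6)),
                             table = coarseScheme()[-1, ])
            per <- vapply(1:4, function(id) labelDice(a, b, id), numeric(1))
            expect_equal(score4L(a, b), mean(per))
        }
    })
})

test_that("4L and LV agree with hand-counted examples", {
    ph <- makePhantom(smallSpec(noiseSd = 0), id = "p")
    expect_equal(score4L(atlasCoarse(ph), atlasCoarse(ph)), 1.0)
    # ventricle masks: 100 vs 140 voxels sharing 90 -> 180/240
    a <- labelVolumeFrom(10, list("4" = 1:100), table = coarseScheme()[-1, ])
    b <- labelVolumeFrom(10, list("4" = 11:150), table = coarseScheme()[-1, ])
    expect_equal(scoreLV(a, b), 180 / 240)
    # ventricle-free pair: absent structure counts as agreement
    e1 <- labelVolumeFrom(4, list("2" = 1:8), table = coarseScheme()[-1, ])
    e2 <- labelVolumeFrom(4, list("2" = 1:8), table = coarseScheme()[-1, ])
    expect_warning(lv <- scoreLV(e1, e2), "empty")
    expect_equal(lv, 1.0)
    bad <- labelVolumeFrom(4, list("9" = 1:4))
    expect_error(score4L(e1, bad), "non-coarse")
})
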