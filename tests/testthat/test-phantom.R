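test_that("noiseless phantom intensity equals the class means exactly", {
    ph <- makePhantom(smallSpec(noiseSd = 0, biasAmplitude = 0), id = "p")
    means <- defaultClassMeans()
    vals <- voxelValues(atlasIntensity(ph))
    coarse <- labelArray(atlasCoarse(ph))
    for (id in 0:6)
        if (any(coarse == id))
            expect_equal(unique(vals[coarse == id]),
                         unname(means[as.character(id)]))
})

test_that("ventricle voxel count matches a brute-force ellipsoid oracle", {
    spec <- smallSpec(ventricleSemiaxes = c(2.5, 2, 2), noiseSd = 0)
    ph <- makePhantom(spec, id = "p")
    fine <- labelArray(atlasFine(ph))
    # independent oracle: voxel-centre-in-ellipsoid test at both centres
    grid <- volumeGrid(ph)
    centre <- gridOrigin(grid) + (dim(grid) - 1) * voxelSpacing(grid) / 2
    x <- gridOrigin(grid)[1] + (seq_len(dim(grid)[1]) - 1) *
        voxelSpacing(grid)[1]
    count <- 0L
    for (side in c(-1, 1)) {
        c0 <- centre + c(side * 3.5, 0, 1)
        for (i in seq_along(x)) for (j in seq_along(x))
            for (k in seq_along(x)) {
                p <- c(x[i], x[j], x[k])
                if (sum(((p - c0) / c(2.5, 2, 2))^2) <= 1)
                    count <- count + 1L
            }
    }
    nLat <- sum(fine %in% c(5L, 6L))
    expect_identical(nLat, count)
})

test_that("phantom generation is bit-identical for identical specs", {
    a <- makePhantom(smallSpec(seed = 42), id = "p")
    b <- makePhantom(smallSpec(seed = 42), id = "p")
    expect_identical(voxelValues(atlasIntensity(a)),
                     voxelValues(atlasIntensity(b)))
    expect_identical(labelArray(atlasFine(a)), labelArray(atlasFine(b)))
    c <- makePhantom(smallSpec(seed = 43), id = "p")
    expect_false(identical(voxelValues(atlasIntensity(a)),
                           voxelValues(atlasIntensity(c))))
})

test_that("coarse map is an idempotent projection of the fine map", {
    ph <- makePhantom(smallSpec(), id = "p")
    coarse <- atlasCoarse(ph)
    identityMap <- structure(1:6, names = as.character(1:6))
    again <- projectFineToCoarse(coarse, identityMap)
    expect_identical(labelArray(again), labelArray(coarse))
    # and the projection law itself
    expect_identical(labelArray(coarse),
                     labelArray(projectFineToCoarse(atlasFine(ph),
                                                    phantomFineToCoarse())))
})

test_that("brain interior is fully partitioned by fine labels", {
    spec <- smallSpec()
    ph <- makePhantom(spec, id = "p")
    grid <- volumeGrid(ph)
    co <- expand.grid(
        x = gridOrigin(grid)[1] + (seq_len(dim(grid)[1]) - 1),
        y = gridOrigin(grid)[2] + (seq_len(dim(grid)[2]) - 1),
        z = gridOrigin(grid)[3] + (seq_len(dim(grid)[3]) - 1))
    centre <- gridOrigin(grid) + (dim(grid) - 1) / 2
    r2 <- (co$x - centre[1])^2 + (co$y - centre[2])^2 +
        (co$z - centre[3])^2
    inside <- r2 <= (11 + 1.5)^2      # within the CSF shell outer radius
    fine <- as.vector(labelArray(atlasFine(ph)))
    expect_true(all(fine[inside] > 0L))
})

test_that("library ventricle volumes are monotone and truth-table exact", {
    lb <- noiselessLibrary()
    expect_identical(atlasIds(lb$library), sprintf("a%02d", 1:9))
    expect_true(all(diff(lb$truth$ventricle_volume_mm3) > 0))
    # oracle: recount ventricle voxels from the fine maps
    for (i in seq_len(9)) {
        fine <- labelArray(atlasFine(lb$library[[i]]))
        expect_equal(lb$truth$ventricle_voxels[i],
                     sum(fine %in% c(5L, 6L, 7L)))
    }
    one <- makeLibrary(librarySpec(nAtlases = 1, base = smallSpec(),
                                   ventricleScaleRange = c(0.8, 1.6),
                                   seed = 2))
    expect_equal(one$truth$ventricle_scale, 1.2)
    expect_equal(length(one$library), 1L)
})

test_that("impossible geometry is rejected", {
    expect_error(makePhantom(smallSpec(ventricleSemiaxes = c(9, 9, 9))),
                 "inside the white matter")
    expect_error(phantomSpec(grid = VolumeGrid(c(16, 16, 16))),
                 "fit inside")
})
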