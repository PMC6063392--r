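# compact phantom geometry for fast unit tests (32^3 voxels, 1 mm);
# any phantomSpec() argument can be overridden
smallSpec <- function(...) {
    args <- list(grid = VolumeGrid(c(32, 32, 32)),
                 brainRadius = 11, cortexThickness = 2.5,
                 csfThickness = 1.5,
                 ventricleSemiaxes = c(2.2, 1.8, 1.8),
                 ventricleOffset = c(3.5, 0, 1),
                 skullBaseRadius = 1.2, skinThickness = 1)
    over <- list(...)
    args[names(over)] <- over
    do.call(phantomSpec, args)
}

# noiseless 9-member library with evenly spaced ventricle scales, built
# once per run; default-size geometry so the discretised ventricle volumes
# are strictly monotone
noiselessLibrary <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- makeLibrary(librarySpec(
                nAtlases = 9,
                base = phantomSpec(noiseSd = 0, biasAmplitude = 0),
                ventricleScaleRange = c(0.7, 1.5), seed = 7))
        cache
    }
})

# quick hand-made label volume on an n^3 grid from a named list id -> voxel
# index vector
labelVolumeFrom <- function(n, assign, table = NULL) {
    arr <- array(0L, c(n, n, n))
    for (id in names(assign)) arr[assign[[id]]] <- as.integer(id)
    LabelVolume(arr, table = table)
}
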