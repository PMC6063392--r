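#' @include AllGenerics.R
NULL

# ---- grid helpers ----

#' Test exact grid compatibility
#'
#' Two grids are compatible iff shape, spacing and origin agree exactly
#' (spacing/origin to within 1e-6 mm, absorbing float round-trip error).
#'
#' @param g1,g2 [VolumeGrid-class] objects.
#' @return logical scalar.
#' @export
gridsCompatible <- function(g1, g2) {
    identical(g1@shape, g2@shape) &&
        all(abs(g1@spacing - g2@spacing) <= 1e-6) &&
        all(abs(g1@origin - g2@origin) <= 1e-6)
}

stopIfIncompatible <- function(g1, g2) {
    if (!gridsCompatible(g1, g2))
        stop("incompatible grids (shape/spacing/origin must agree exactly)")
    invisible(TRUE)
}

# extract a bare array from volumes or arrays
asValues <- function(x) {
    if (is(x, "IntensityVolume")) x@values
    else if (is(x, "LabelVolume")) x@labels
    else as.array(x)
}

gridOf <- function(x) {
    if (is(x, "IntensityVolume") || is(x, "LabelVolume")) x@grid else NULL
}

checkPairGrids <- function(a, b) {
    ga <- gridOf(a); gb <- gridOf(b)
    if (!is.null(ga) && !is.null(gb)) stopIfIncompatible(ga, gb)
    else if (!identical(dim(asValues(a)), dim(asValues(b))))
        stop("incompatible grids (array dims differ)")
    invisible(TRUE)
}

# ---- accessors ----

#' @rdname accessors
#' @aliases volumeGrid,IntensityVolume-method
setMethod("volumeGrid", "IntensityVolume", function(x) x@grid)
#' @rdname accessors
setMethod("volumeGrid", "LabelVolume", function(x) x@grid)
#' @rdname accessors
setMethod("volumeGrid", "Atlas", function(x) x@intensity@grid)
#' @rdname accessors
setMethod("volumeGrid", "AtlasLibrary", function(x) x@grid)

#' @rdname accessors
setMethod("voxelValues", "IntensityVolume", function(x) x@values)
#' @rdname accessors
setMethod("labelArray", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("labelTable", "LabelVolume", function(x) x@table)

#' @rdname accessors
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "IntensityVolume", function(x) x@grid@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LabelVolume", function(x) x@grid@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VolumeGrid", function(x) x@origin)

#' @rdname accessors
setMethod("dim", "VolumeGrid", function(x) x@shape)
#' @rdname accessors
setMethod("dim", "IntensityVolume", function(x) x@grid@shape)
#' @rdname accessors
setMethod("dim", "LabelVolume", function(x) x@grid@shape)

#' @rdname accessors
setMethod("atlasId", "Atlas", function(x) x@id)
#' @rdname accessors
setMethod("atlasIntensity", "Atlas", function(x) x@intensity)
#' @rdname accessors
setMethod("atlasCoarse", "Atlas", function(x) x@coarse)
#' @rdname accessors
setMethod("atlasFine", "Atlas", function(x) x@fine)
#' @rdname accessors
setMethod("atlasMeta", "Atlas", function(x) x@meta)

#' @rdname accessors
setMethod("atlases", "AtlasLibrary", function(x) x@atlases)
#' @rdname accessors
setMethod("atlasIds", "AtlasLibrary",
    function(x) vapply(x@atlases, function(a) a@id, character(1)))
#' @rdname accessors
setMethod("length", "AtlasLibrary", function(x) length(x@atlases))

#' Extract atlases from a library by index or id
#'
#' @param x an [AtlasLibrary-class].
#' @param i integer, logical or character (atlas id) index.
#' @param j,...,drop unused.
#' @return `[[` returns an [Atlas-class]; `[` returns a sub-library.
#' @export
setMethod("[[", "AtlasLibrary", function(x, i, j, ...) {
    if (is.character(i)) {
        pos <- match(i, atlasIds(x))
        if (is.na(pos)) stop(sprintf("no atlas with id '%s'", i))
        i <- pos
    }
    x@atlases[[i]]
})

#' @rdname sub-sub-AtlasLibrary-method
#' @export
setMethod("[", "AtlasLibrary", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        pos <- match(i, atlasIds(x))
        if (anyNA(pos))
            stop(sprintf("no atlas with id '%s'",
                         paste(i[is.na(pos)], collapse = "', '")))
        i <- pos
    }
    new("AtlasLibrary", atlases = x@atlases[i], grid = x@grid)
})

#' @rdname accessors
setMethod("rankingMethod", "Ranking", function(x) x@method)
#' @rdname accessors
setMethod("rankingScores", "Ranking", function(x) x@scores)
#' @rdname accessors
setMethod("rankingOrder", "Ranking", function(x) x@order)

#' @rdname accessors
setMethod("coarseMap", "CoarseSegResult", function(x) x@coarse)
#' @rdname accessors
setMethod("coarseMap", "Atlas", function(x) x@coarse)

#' @rdname accessors
setMethod("sweepRecords", "SweepReport", function(x) x@records)
#' @rdname accessors
setMethod("sweepSummaries", "SweepReport", function(x) x@summaries)
#' @rdname accessors
setMethod("sweepPoorRatio", "SweepReport", function(x) x@poorRatio)
#' @rdname accessors
setMethod("sweepPairedStats", "SweepReport", function(x) x@pairedStats)

# ---- show methods ----

setMethod("show", "VolumeGrid", function(object) {
    cat(sprintf("VolumeGrid %s, spacing %s mm, origin %s mm\n",
        paste(object@shape, collapse = "x"),
        paste(format(object@spacing), collapse = "x"),
        paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "IntensityVolume", function(object) {
    cat(sprintf("IntensityVolume %s, spacing %s mm, range [%.3g, %.3g]\n",
        paste(dim(object), collapse = "x"),
        paste(format(voxelSpacing(object)), collapse = "x"),
        min(object@values), max(object@values)))
})

setMethod("show", "LabelVolume", function(object) {
    ids <- setdiff(sort(unique(as.integer(object@labels))), 0L)
    cat(sprintf("LabelVolume %s, %d nonzero label(s): %s\n",
        paste(dim(object), collapse = "x"), length(ids),
        paste(utils::head(ids, 10), collapse = ", ")))
})

setMethod("show", "Atlas", function(object) {
    cat(sprintf("Atlas '%s' (%s voxels", object@id,
                paste(dim(object@intensity), collapse = "x")))
    if (!is.null(object@meta$age))
        cat(sprintf(", age %.1f", as.numeric(object@meta$age)))
    cat(")\n")
})

setMethod("show", "AtlasLibrary", function(object) {
    cat(sprintf("AtlasLibrary of %d atlas(es) on %s grid\n  ids: %s\n",
        length(object), paste(object@grid@shape, collapse = "x"),
        paste(utils::head(atlasIds(object), 12), collapse = ", ")))
})

setMethod("show", "Ranking", function(object) {
    cat(sprintf("Ranking (%s): %s\n", object@method,
        paste(utils::head(object@order, 8), collapse = " > ")))
    if (nrow(object@scores))
        cat(sprintf("  best score %.4f, worst %.4f\n",
            max(object@scores$value), min(object@scores$value)))
})

setMethod("show", "CoarseSegResult", function(object) {
    cat(sprintf("CoarseSegResult: %d brain-mask voxels, class means %s\n",
        object@brainMaskVoxels,
        paste(sprintf("%s=%.1f", names(object@classMeans),
                      object@classMeans), collapse = ", ")))
})

setMethod("show", "SweepReport", function(object) {
    cat(sprintf("SweepReport: %d records (%d target(s), methods %s, k in {%s})\n",
        nrow(object@records),
        length(unique(object@records$target_id)),
        paste(unique(object@records$method), collapse = "/"),
        paste(sort(unique(object@records$k)), collapse = ", ")))
    if (nrow(object@summaries)) {
        cat("Mean Dice per (method, k, level):\n")
        print(utils::head(object@summaries, 12))
    }
})
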