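#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's classes; slot access by users
#' is discouraged.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeGrid", function(x) standardGeneric("volumeGrid"))

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("atlasId", function(x) standardGeneric("atlasId"))

#' @rdname accessors
#' @export
setGeneric("atlasIntensity", function(x) standardGeneric("atlasIntensity"))

#' @rdname accessors
#' @export
setGeneric("atlasCoarse", function(x) standardGeneric("atlasCoarse"))

#' @rdname accessors
#' @export
setGeneric("atlasFine", function(x) standardGeneric("atlasFine"))

#' @rdname accessors
#' @export
setGeneric("atlasMeta", function(x) standardGeneric("atlasMeta"))

#' @rdname accessors
#' @export
setGeneric("atlases", function(x) standardGeneric("atlases"))

#' @rdname accessors
#' @export
setGeneric("atlasIds", function(x) standardGeneric("atlasIds"))

#' @rdname accessors
#' @export
setGeneric("rankingMethod", function(x) standardGeneric("rankingMethod"))

#' @rdname accessors
#' @export
setGeneric("rankingScores", function(x) standardGeneric("rankingScores"))

#' @rdname accessors
#' @export
setGeneric("rankingOrder", function(x) standardGeneric("rankingOrder"))

#' @rdname accessors
#' @export
setGeneric("coarseMap", function(x) standardGeneric("coarseMap"))

#' @rdname accessors
#' @export
setGeneric("sweepRecords", function(x) standardGeneric("sweepRecords"))

#' @rdname accessors
#' @export
setGeneric("sweepSummaries", function(x) standardGeneric("sweepSummaries"))

#' @rdname accessors
#' @export
setGeneric("sweepPoorRatio", function(x) standardGeneric("sweepPoorRatio"))

#' @rdname accessors
#' @export
setGeneric("sweepPairedStats", function(x) standardGeneric("sweepPairedStats"))
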