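#' Rank an atlas library against a target
#'
#' Scores every library member under one similarity criterion and sorts
#' descending; exact ties are broken by ascending atlas id so pipelines are
#' reproducible. If `targetId` matches a library member it is excluded
#' before ranking (leave-one-out), unless `excludeTarget = FALSE`.
#'
#' @param lib an [AtlasLibrary-class].
#' @param method "4L" or "LV" (coarse-label Dice; require `targetCoarse`)
#'   or "MI" (normalized mutual information; requires `targetImage`).
#' @param targetCoarse the target's coarse map: a [LabelVolume-class] or a
#'   [CoarseSegResult-class] from [quickCoarseSegment()].
#' @param targetImage the target's [IntensityVolume-class] (MI only).
#' @param targetId optional id of the target within the library.
#' @param excludeTarget drop `targetId` from the candidates?
#' @param nBins histogram bins for MI.
#' @return a [Ranking-class].
#' @export
rankAtlases <- function(lib, method = c("4L", "LV", "MI"),
                        targetCoarse = NULL, targetImage = NULL,
                        targetId = NULL, excludeTarget = TRUE,
                        nBins = 64L) {
    method <- match.arg(method)
    cand <- atlases(lib)
    if (!is.null(targetId) && excludeTarget)
        cand <- Filter(function(a) atlasId(a) != targetId, cand)
    if (!length(cand)) stop("no candidate atlases to rank")
    if (method %in% c("4L", "LV")) {
        if (is.null(targetCoarse))
            stop("method ", method, " requires targetCoarse")
        if (is(targetCoarse, "CoarseSegResult"))
            targetCoarse <- coarseMap(targetCoarse)
        stopIfIncompatible(volumeGrid(targetCoarse), volumeGrid(lib))
        scorer <- if (method == "4L") score4L else scoreLV
        values <- vapply(cand,
            function(a) scorer(targetCoarse, atlasCoarse(a)), numeric(1))
    } else {
        if (is.null(targetImage)) stop("method MI requires targetImage")
        stopIfIncompatible(volumeGrid(targetImage), volumeGrid(lib))
        values <- vapply(cand,
            function(a) normalizedMI(targetImage, atlasIntensity(a),
                                     nBins = nBins), numeric(1))
    }
    ids <- vapply(cand, atlasId, character(1))
    scores <- data.frame(atlas_id = ids, value = values,
                         stringsAsFactors = FALSE)
    ord <- order(-values, ids)
    new("Ranking", method = method, scores = scores,
        order = ids[ord], seed = NA_integer_)
}

#' Select the top-k atlases of a ranking
#'
#' Returns the first `min(k, N)` ids, so `selectTopK(r, k)` is always a
#' prefix of `selectTopK(r, k + 1)` (nested subsets). `k > N` returns all
#' ids with a warning.
#'
#' @param ranking a [Ranking-class].
#' @param k number of atlases (>= 0).
#' @return character vector of atlas ids, best first.
#' @export
selectTopK <- function(ranking, k) {
    stopifnot(k >= 0)
    n <- length(ranking@order)
    if (k > n)
        warning(sprintf("k = %d exceeds library size %d; returning all", k, n))
    ranking@order[seq_len(min(k, n))]
}

#' Random atlas subset (baseline)
#'
#' Uniform sample of `k` ids without replacement from a seeded generator;
#' the same seed always reproduces the same subset.
#'
#' @param lib an [AtlasLibrary-class].
#' @param k subset size; must not exceed the candidates after exclusion.
#' @param seed integer RNG seed.
#' @param exclude optional id to leave out (the target itself).
#' @return character vector of atlas ids in sampled order.
#' @export
selectRandom <- function(lib, k, seed, exclude = NULL) {
    ids <- setdiff(atlasIds(lib), exclude)
    if (k > length(ids))
        stop(sprintf("k = %d exceeds available atlases (%d)", k, length(ids)))
    withr::with_seed(as.integer(seed), sample(ids, k))
}

#' Write a ranking (with selection) to JSON
#'
#' Records method, parameters, per-atlas scores, the full order and the
#' selected top-k ids in a machine-readable file consumed by the `segment`
#' command.
#'
#' @param ranking a [Ranking-class].
#' @param path output JSON path.
#' @param k subset size recorded in the file (default: all).
#' @param nBins histogram bin parameter echoed into the file.
#' @return `path`, invisibly.
#' @export
writeRanking <- function(ranking, path, k = length(ranking@order),
                         nBins = 64L) {
    obj <- list(method = ranking@method,
                params = list(n_bins = nBins),
                scores = ranking@scores,
                order = ranking@order,
                selected = selectTopK(ranking, k),
                seed = if (is.na(ranking@seed)) NULL else ranking@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(path)
}

#' Read a ranking JSON written by [writeRanking()]
#'
#' @param path JSON path.
#' @return list with elements `method`, `params`, `scores`, `order`,
#'   `selected`.
#' @export
readRanking <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
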