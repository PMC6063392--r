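#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary region masks on compatible
#' grids. Symmetric. If both masks are empty the structure is absent from
#' both volumes and the agreement is perfect: 1.0 is returned with a
#' warning; if exactly one is empty, 0.0.
#'
#' @param a,b logical arrays of equal dimensions (region masks).
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
    if (!identical(dim(a), dim(b)))
        stop("incompatible grids (mask dims differ)")
    na <- sum(a); nb <- sum(b)
    if (na == 0L && nb == 0L) {
        warning("both masks empty; Dice defined as 1.0")
        return(1.0)
    }
    2 * sum(a & b) / (na + nb)
}

#' Per-id Dice between two label volumes
#'
#' @param a,b [LabelVolume-class] objects on compatible grids.
#' @param id label id whose region masks are compared.
#' @return Dice coefficient in `[0, 1]`.
#' @export
labelDice <- function(a, b, id) {
    checkPairGrids(a, b)
    diceCoefficient(asValues(a) == id, asValues(b) == id)
}

#' Intensity entropy (bits)
#'
#' Shannon entropy `-sum p log2 p` of the voxel-intensity distribution,
#' estimated from an equal-width histogram over the in-mask `[min, max]`
#' range, with `0 log 0 := 0`.
#'
#' @param img an [IntensityVolume-class] or numeric array.
#' @param mask optional logical array restricting the voxels used (must be
#'   nonempty); default uses the whole grid.
#' @param nBins number of histogram bins (>= 2).
#' @return entropy in bits (non-negative).
#' @export
intensityEntropy <- function(img, mask = NULL, nBins = 64L) {
    stopifnot(nBins >= 2L)
    x <- as.vector(asValues(img))
    if (!is.null(mask)) {
        x <- x[as.vector(mask)]
        if (!length(x)) stop("empty mask")
    }
    counts <- tabulate(binIndex(x, min(x), max(x), nBins), nbins = nBins)
    entropyFromCounts(counts)
}

#' Normalized mutual information between two intensity volumes
#'
#' `NMI(A, B) = (H(A) + H(B)) / H(A, B)` from the joint intensity histogram
#' over the full common grid (`nBins x nBins` equal-width bins, each axis
#' binned over its own volume's range; marginals are the joint margins, so
#' the estimator is internally consistent and bounded in `[1, 2]`).
#' Symmetric; `NMI(A, A) = 2`.
#'
#' @param a,b [IntensityVolume-class] objects (or arrays) on compatible
#'   grids; both must be non-constant.
#' @param nBins histogram bins per axis.
#' @param mask optional logical array restricting the evaluation domain
#'   (the default, whole-grid, matches intensity selection on whole-head
#'   images).
#' @return NMI in `[1, 2]`.
#' @export
normalizedMI <- function(a, b, nBins = 64L, mask = NULL) {
    checkPairGrids(a, b)
    va <- as.vector(asValues(a)); vb <- as.vector(asValues(b))
    if (!is.null(mask)) {
        va <- va[as.vector(mask)]; vb <- vb[as.vector(mask)]
    }
    if (min(va) == max(va) || min(vb) == max(vb))
        stop("constant volume: joint entropy degenerate")
    bi <- binIndex(va, min(va), max(va), nBins)
    bj <- binIndex(vb, min(vb), max(vb), nBins)
    joint <- tabulate((bi - 1L) * nBins + bj, nbins = nBins * nBins)
    jm <- matrix(joint, nBins, nBins)   # rows: b bins, cols: a bins
    hj <- entropyFromCounts(joint)
    ha <- entropyFromCounts(colSums(jm))
    hb <- entropyFromCounts(rowSums(jm))
    (ha + hb) / hj
}

checkCoarseIds <- function(x) {
    bad <- setdiff(unique(as.integer(asValues(x))), 0:6)
    if (length(bad))
        stop(sprintf("non-coarse ids present: %s",
                     paste(bad, collapse = ", ")))
    invisible(TRUE)
}

#' Four-label (4L) coarse-segmentation similarity
#'
#' Unweighted arithmetic mean of the per-label Dice over the four brain
#' tissue classes of the coarse scheme: CSF space (1), gray matter (2),
#' white matter (3) and ventricles (4). Per-label empty-empty cases
#' contribute 1.0, as in [diceCoefficient()].
#'
#' @param targetCoarse,atlasCoarse coarse [LabelVolume-class] maps on
#'   compatible grids.
#' @return similarity in `[0, 1]`.
#' @export
score4L <- function(targetCoarse, atlasCoarse) {
    checkPairGrids(targetCoarse, atlasCoarse)
    checkCoarseIds(targetCoarse); checkCoarseIds(atlasCoarse)
    mean(vapply(c(CS_CSF, CS_GM, CS_WM, CS_VENT),
                function(id) labelDice(targetCoarse, atlasCoarse, id),
                numeric(1)))
}

#' Lateral-ventricle (LV) coarse-segmentation similarity
#'
#' Dice restricted to the ventricle class (coarse id 4) alone.
#'
#' @inheritParams score4L
#' @return similarity in `[0, 1]`.
#' @export
scoreLV <- function(targetCoarse, atlasCoarse) {
    checkPairGrids(targetCoarse, atlasCoarse)
    checkCoarseIds(targetCoarse); checkCoarseIds(atlasCoarse)
    labelDice(targetCoarse, atlasCoarse, CS_VENT)
}
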