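#' Fuse atlas label maps by (weighted) voting
#'
#' Registration-free label fusion on a common grid: each voxel takes the
#' label with the greatest vote count (majority mode) or the greatest sum
#' of atlas weights (weighted mode; weights default to the pre-selection
#' similarity scores when driven from a ranking). Ties go to the lowest
#' label id, which makes the result independent of atlas order. The output
#' label table is the union of the input tables.
#'
#' @param fines list of [LabelVolume-class] on compatible grids (>= 1).
#' @param mode "majority" or "weighted".
#' @param weights numeric vector, one non-negative weight per atlas
#'   (weighted mode; at least one must be positive).
#' @return fused [LabelVolume-class].
#' @export
fuseLabels <- function(fines, mode = c("majority", "weighted"),
                       weights = NULL) {
    mode <- match.arg(mode)
    if (!length(fines)) stop("empty atlas list")
    grid <- volumeGrid(fines[[1]])
    for (f in fines) stopIfIncompatible(volumeGrid(f), grid)
    n <- length(fines)
    if (mode == "majority") {
        w <- rep(1, n)
    } else {
        if (is.null(weights) || length(weights) != n)
            stop("weighted mode needs one weight per atlas")
        if (any(weights < 0) || !any(weights > 0))
            stop("weights must be non-negative with at least one positive")
        w <- weights
    }
    arrs <- lapply(fines, labelArray)
    allIds <- sort(unique(unlist(lapply(arrs,
        function(a) unique(as.integer(a))))))
    shape <- grid@shape
    bestLab <- array(0L, shape)
    bestVotes <- array(-1, shape)
    for (id in allIds) {           # ascending: ties keep the lowest id
        votes <- array(0, shape)
        for (i in seq_len(n)) votes <- votes + w[i] * (arrs[[i]] == id)
        upd <- votes > bestVotes
        bestLab[upd] <- id
        bestVotes[upd] <- votes[upd]
    }
    tabs <- unique(do.call(rbind, lapply(fines, labelTable)))
    if (anyDuplicated(tabs$id))
        stop("conflicting label tables across atlases")
    LabelVolume(bestLab, grid = grid, table = tabs)
}
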