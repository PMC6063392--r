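#' Project a fine label map onto a coarser scheme
#'
#' Voxelwise substitution of fine ids by mapped ids; the grid is preserved.
#' Every nonzero fine id present in the volume must have a mapping entry
#' (id 0 always maps to 0).
#'
#' @param fine a [LabelVolume-class].
#' @param mapping named integer vector: names are fine ids, values target
#'   ids (e.g. [phantomFineToCoarse()]).
#' @param table label table for the output; defaults to the coarse scheme.
#' @return a [LabelVolume-class].
#' @export
projectFineToCoarse <- function(fine, mapping, table = coarseTable()) {
    lab <- labelArray(fine)
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)
    missing <- setdiff(as.character(ids), names(mapping))
    if (length(missing))
        stop(sprintf("unmapped id %s", paste(missing, collapse = ", ")))
    lut <- integer(max(c(ids, 0L)) + 1L)  # lut[id + 1] -> coarse id
    lut[ids + 1L] <- as.integer(mapping[as.character(ids)])
    out <- array(lut[lab + 1L], dim(lab))
    LabelVolume(out, grid = volumeGrid(fine), table = table)
}

#' Fast 7-label coarse tissue segmentation
#'
#' A lightweight, atlas-free estimate of the coarse tissue map that the
#' selection criteria consume: (1) brain mask = largest 6-connected
#' component above an Otsu threshold, morphologically closed and with
#' interior cavities filled (so ventricles stay in-mask whatever their
#' contrast); (2) seeded
#' 3-class k-means on in-mask intensities, classes assigned to CSF < GM < WM
#' by ascending mean (T1-like contrast; `contrast = "t2"` reverses the
#' ordering); (3) CSF-class connected components that do not touch the
#' brain-mask boundary become ventricles (id 4), the rest CSF space (id 1);
#' (4) out-of-mask voxels are background (id 0). Skull-base and skin labels
#' are not estimated from raw intensities. When a precomputed coarse map
#' exists, bypass this stage and use it directly.
#'
#' @param img an [IntensityVolume-class].
#' @param kClasses number of tissue classes (fixed at 3: CSF/GM/WM).
#' @param seed integer seed for k-means.
#' @param contrast "t1" (CSF darkest) or "t2" (CSF brightest).
#' @return a [CoarseSegResult-class].
#' @export
quickCoarseSegment <- function(img, kClasses = 3L, seed = 1L,
                               contrast = c("t1", "t2")) {
    contrast <- match.arg(contrast)
    stopifnot(kClasses == 3L)
    x <- voxelValues(img)
    thr <- otsuThreshold(as.vector(x))
    mask <- fillHoles3D(close6(largestComponent(x > thr)))
    nMask <- sum(mask)
    if (nMask == 0L) stop("empty brain mask")
    vals <- x[mask]
    if (length(unique(vals)) < kClasses)
        stop("fewer than k distinct intensity levels in mask")
    km <- withr::with_seed(as.integer(seed),
        stats::kmeans(vals, centers = kClasses, nstart = 5L,
                      iter.max = 100L))
    ord <- order(km$centers)          # ascending mean intensity
    if (contrast == "t2") ord <- rev(ord)
    tissue <- integer(kClasses)       # cluster -> coarse id
    tissue[ord] <- c(CS_CSF, CS_GM, CS_WM)
    coarse <- array(0L, dim(x))
    coarse[mask] <- tissue[km$cluster]

    # interior CSF components are ventricles
    boundary <- mask & !erode6(mask)
    csfMask <- coarse == CS_CSF
    cc <- labelComponents3D(csfMask)
    if (any(cc > 0L)) {
        touching <- unique(cc[cc > 0L & boundary])
        interior <- setdiff(seq_len(max(cc)), touching)
        coarse[cc %in% interior] <- CS_VENT
    }
    centers <- as.vector(km$centers)
    classMeans <- c("0" = if (nMask < length(x)) mean(x[!mask]) else NA_real_,
                    "1" = centers[ord[1]], "2" = centers[ord[2]],
                    "3" = centers[ord[3]],
                    "4" = centers[ord[1]])
    classMeans <- classMeans[!is.na(classMeans)]
    new("CoarseSegResult",
        coarse = LabelVolume(coarse, grid = volumeGrid(img),
                             table = coarseTable()),
        classMeans = classMeans,
        brainMaskVoxels = as.integer(nMask))
}
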