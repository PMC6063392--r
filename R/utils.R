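#' The 7-label coarse tissue scheme
#'
#' Fixed id assignment for coarse whole-head maps: 0 remaining space,
#' 1 CSF space, 2 gray matter, 3 white matter, 4 ventricles, 5 skull-base
#' tissues, 6 skin. A coarse [LabelVolume-class] uses no other ids.
#'
#' @return data.frame with columns `id`, `name`.
#' @export
coarseScheme <- function() {
    data.frame(
        id = 0:6,
        name = c("remaining_space", "csf", "gray_matter", "white_matter",
                 "ventricles", "skull_base", "skin"),
        stringsAsFactors = FALSE)
}

# coarse ids used by the selection criteria
CS_CSF <- 1L; CS_GM <- 2L; CS_WM <- 3L; CS_VENT <- 4L
CS_SKULLBASE <- 5L; CS_SKIN <- 6L

coarseTable <- function() {
    tab <- coarseScheme()
    tab[tab$id != 0L, , drop = FALSE]
}

# ---- histogramming ----

# equal-width bin index over [lo, hi]; values at hi land in the last bin
binIndex <- function(x, lo, hi, nBins) {
    if (hi <= lo) return(rep.int(1L, length(x)))
    idx <- floor((x - lo) / (hi - lo) * nBins) + 1L
    pmin.int(pmax.int(idx, 1L), nBins)
}

entropyFromCounts <- function(counts) {
    p <- counts[counts > 0]
    p <- p / sum(p)
    -sum(p * log2(p))
}

# ---- Otsu threshold ----

# maximize between-class variance on a 256-bin histogram; returns the
# threshold value (voxels strictly above it are foreground)
otsuThreshold <- function(x, nBins = 256L) {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) return(lo)
    cnt <- tabulate(binIndex(x, lo, hi, nBins), nbins = nBins)
    p <- cnt / sum(cnt)
    centers <- lo + (seq_len(nBins) - 0.5) * (hi - lo) / nBins
    w0 <- cumsum(p)
    mu <- cumsum(p * centers)
    muT <- mu[nBins]
    w1 <- 1 - w0
    valid <- w0 > 0 & w1 > 0
    sigmaB <- rep(-Inf, nBins)
    sigmaB[valid] <- (muT * w0[valid] - mu[valid])^2 /
        (w0[valid] * w1[valid])
    kstar <- which.max(sigmaB)
    lo + kstar * (hi - lo) / nBins
}

# ---- 3D binary morphology (6-neighbourhood, shift-based) ----

shiftArr <- function(a, axis, by, fill) {
    d <- dim(a)
    out <- array(fill, d)
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[axis]
    if (by == 1L) { idx[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    else          { idx[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

dilate6 <- function(mask) {
    out <- mask
    for (ax in 1:3) for (by in c(1L, -1L))
        out <- out | shiftArr(mask, ax, by, FALSE)
    out
}

erode6 <- function(mask) {
    out <- mask
    for (ax in 1:3) for (by in c(1L, -1L))
        out <- out & shiftArr(mask, ax, by, TRUE)
    out
}

close6 <- function(mask, iterations = 1L) {
    for (i in seq_len(iterations)) mask <- dilate6(mask)
    for (i in seq_len(iterations)) mask <- erode6(mask)
    mask
}

# ---- 3D connected components (6-connectivity, vectorised BFS) ----

# returns an integer array: 0 outside mask, 1..n component labels
labelComponents3D <- function(mask) {
    d <- dim(mask)
    n <- prod(d)
    lab <- integer(n)
    m <- as.logical(mask)
    # voxel coordinates for boundary-safe neighbour moves
    ix <- rep.int(seq_len(d[1]), d[2] * d[3])
    iy <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
    iz <- rep(seq_len(d[3]), each = d[1] * d[2])
    strides <- c(1L, d[1], d[1] * d[2])
    comp <- 0L
    todo <- which(m)
    seen <- logical(n)
    for (start in todo) {
        if (seen[start]) next
        comp <- comp + 1L
        frontier <- start
        seen[start] <- TRUE
        lab[start] <- comp
        while (length(frontier)) {
            nxt <- integer(0)
            for (ax in 1:3) {
                co <- switch(ax, ix, iy, iz)
                up <- frontier[co[frontier] < d[ax]] + strides[ax]
                dn <- frontier[co[frontier] > 1L] - strides[ax]
                nxt <- c(nxt, up, dn)
            }
            nxt <- unique(nxt[m[nxt] & !seen[nxt]])
            seen[nxt] <- TRUE
            lab[nxt] <- comp
            frontier <- nxt
        }
    }
    array(lab, d)
}

# fill interior cavities: background components not touching the border
fillHoles3D <- function(mask) {
    cc <- labelComponents3D(!mask)
    if (!any(cc > 0L)) return(mask)
    d <- dim(mask)
    border <- unique(c(cc[1, , ], cc[d[1], , ], cc[, 1, ], cc[, d[2], ],
                       cc[, , 1], cc[, , d[3]]))
    mask | !(cc %in% setdiff(border, 0L) | cc == 0L)
}

largestComponent <- function(mask) {
    cc <- labelComponents3D(mask)
    if (!any(cc > 0L)) return(array(FALSE, dim(mask)))
    sizes <- tabulate(cc[cc > 0L])
    cc == which.max(sizes)
}

# physical voxel-centre coordinate arrays (mm) for a grid
coordArrays <- function(grid) {
    d <- grid@shape; sp <- grid@spacing; o <- grid@origin
    x <- o[1] + (seq_len(d[1]) - 1) * sp[1]
    y <- o[2] + (seq_len(d[2]) - 1) * sp[2]
    z <- o[3] + (seq_len(d[3]) - 1) * sp[3]
    list(
        X = array(rep.int(x, d[2] * d[3]), d),
        Y = array(rep.int(rep(y, each = d[1]), d[3]), d),
        Z = array(rep(z, each = d[1] * d[2]), d))
}
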