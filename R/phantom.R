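#' @include AllClasses.R
NULL

# fine-label inventory of the phantom (a ~12-structure proxy parcellation)
FINE_IDS <- c(
    cortex_L = 1L, cortex_R = 2L, white_L = 3L, white_R = 4L,
    lateral_ventricle_L = 5L, lateral_ventricle_R = 6L,
    third_ventricle = 7L, hippocampus_L = 8L, hippocampus_R = 9L,
    csf_shell = 10L, skull_base = 11L, skin = 12L)

#' Fine-to-coarse projection map of the phantom parcellation
#'
#' Named integer vector: names are fine ids (as characters), values the
#' coarse scheme ids. Hippocampus proxies project to gray matter; all three
#' ventricle proxies to the ventricle class.
#'
#' @return named integer vector.
#' @export
phantomFineToCoarse <- function() {
    m <- c(CS_GM, CS_GM, CS_WM, CS_WM, CS_VENT, CS_VENT, CS_VENT,
           CS_GM, CS_GM, CS_CSF, CS_SKULLBASE, CS_SKIN)
    names(m) <- as.character(FINE_IDS)
    m
}

fineTable <- function() {
    data.frame(id = unname(FINE_IDS), name = names(FINE_IDS),
               stringsAsFactors = FALSE)
}

#' Default intensity class means of the phantom (T1-like)
#'
#' CSF and ventricles dark, gray matter intermediate, white matter bright.
#' Skull-base and skin tissue are given low means so that the intensity
#' histogram separates head background from brain tissue cleanly, emulating
#' the subdued non-brain signal of partially stripped images.
#'
#' @return named numeric vector, names "0".."6" (coarse ids).
#' @export
defaultClassMeans <- function() {
    c("0" = 0, "1" = 50, "2" = 70, "3" = 110, "4" = 45, "5" = 10, "6" = 12)
}

#' Construct a PhantomSpec
#'
#' Defaults describe a 40 mm-scale head on a 40x40x40 1 mm grid: a 14 mm
#' brain with a 3 mm cortical shell, a 2 mm CSF shell, paired
#' lateral-ventricle ellipsoids with semiaxes (2.8, 2.2, 2.2) mm offset
#' (4.5, 0, 1.5) mm from centre, plus third-ventricle, hippocampus,
#' skull-base and skin proxies. Noise sd defaults to 2 (5% of the 40-unit
#' GM-WM gap) and the bias amplitude to 0.1.
#'
#' @param grid a [VolumeGrid-class].
#' @param brainRadius,cortexThickness,csfThickness mm, see
#'   [PhantomSpec-class].
#' @param ventricleSemiaxes,ventricleOffset mm, lateral-ventricle geometry.
#' @param skullBaseRadius,skinThickness mm (0 disables the structure).
#' @param classMeans named numeric ("0".."6"), per-coarse-class mean.
#' @param noiseSd,biasAmplitude intensity model parameters.
#' @param seed RNG seed for the noise field.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(grid = VolumeGrid(c(40, 40, 40)),
                        brainRadius = 14, cortexThickness = 3,
                        csfThickness = 2,
                        ventricleSemiaxes = c(2.8, 2.2, 2.2),
                        ventricleOffset = c(4.5, 0, 1.5),
                        skullBaseRadius = 1.5, skinThickness = 1.5,
                        classMeans = defaultClassMeans(),
                        noiseSd = 2, biasAmplitude = 0.1, seed = 1L) {
    new("PhantomSpec", grid = grid, brainRadius = brainRadius,
        cortexThickness = cortexThickness, csfThickness = csfThickness,
        ventricleSemiaxes = as.numeric(ventricleSemiaxes),
        ventricleOffset = as.numeric(ventricleOffset),
        skullBaseRadius = skullBaseRadius, skinThickness = skinThickness,
        classMeans = classMeans, noiseSd = noiseSd,
        biasAmplitude = biasAmplitude, seed = as.integer(seed))
}

# ellipsoid membership at voxel centres
inEllipsoid <- function(X, Y, Z, centre, semi) {
    ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
        ((Z - centre[3]) / semi[3])^2 <= 1
}

#' Generate one brain phantom
#'
#' Builds the fine parcellation geometrically (ellipsoids and spherical
#' shells, first-assigned-wins in a fixed order), projects it to the coarse
#' 7-label scheme, and synthesises intensity as
#' `classMean * (1 + biasAmplitude * q) + N(0, noiseSd)` where `q` is a
#' separable quadratic bias field normalised to `[-1, 1]`. Identical specs
#' (including seed) give bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @param id atlas id string.
#' @param meta metadata list.
#' @return an [Atlas-class].
#' @export
makePhantom <- function(spec, id = "phantom", meta = list()) {
    validObject(spec)
    grid <- spec@grid
    co <- coordArrays(grid)
    X <- co$X; Y <- co$Y; Z <- co$Z
    centre <- grid@origin + (grid@shape - 1) * grid@spacing / 2
    wmRadius <- spec@brainRadius - spec@cortexThickness

    # derived proxy structures scale with the main geometry
    off <- spec@ventricleOffset
    ventL <- centre + c(-abs(off[1]), off[2], off[3])
    ventR <- centre + c(abs(off[1]), off[2], off[3])
    thirdCentre <- centre + c(0, 0, -0.27 * wmRadius)
    thirdSemi <- spec@ventricleSemiaxes * 0.45
    hippoSemi <- 0.16 * wmRadius * c(1, 1, 0.85)
    hippoOff <- c(0.68 * wmRadius, 0, -0.45 * wmRadius)
    if (sqrt(sum(hippoOff^2)) + max(hippoSemi) >= wmRadius)
        stop("geometry violates invariants: hippocampus proxy outside white matter")
    if (sqrt(sum((thirdCentre - centre)^2)) + max(thirdSemi) >= wmRadius)
        stop("geometry violates invariants: third ventricle outside white matter")

    r2 <- (X - centre[1])^2 + (Y - centre[2])^2 + (Z - centre[3])^2
    fine <- array(0L, grid@shape)
    place <- function(mask, idName) {
        sel <- mask & fine == 0L
        fine[sel] <<- FINE_IDS[[idName]]
    }
    left <- X < centre[1]

    place(inEllipsoid(X, Y, Z, ventL, spec@ventricleSemiaxes),
          "lateral_ventricle_L")
    place(inEllipsoid(X, Y, Z, ventR, spec@ventricleSemiaxes),
          "lateral_ventricle_R")
    place(inEllipsoid(X, Y, Z, thirdCentre, thirdSemi), "third_ventricle")
    place(inEllipsoid(X, Y, Z, centre + c(-hippoOff[1], 0, hippoOff[3]),
                      hippoSemi), "hippocampus_L")
    place(inEllipsoid(X, Y, Z, centre + c(hippoOff[1], 0, hippoOff[3]),
                      hippoSemi), "hippocampus_R")
    wm <- r2 <= wmRadius^2
    place(wm & left, "white_L"); place(wm, "white_R")
    brain <- r2 <= spec@brainRadius^2
    place(brain & left, "cortex_L"); place(brain, "cortex_R")
    if (spec@skullBaseRadius > 0) {
        sbCentre <- centre +
            c(0, 0, -(spec@brainRadius + spec@csfThickness +
                      0.5 * spec@skullBaseRadius))
        sb2 <- (X - sbCentre[1])^2 + (Y - sbCentre[2])^2 +
            (Z - sbCentre[3])^2
        place(sb2 <= spec@skullBaseRadius^2, "skull_base")
    }
    csfOuter <- spec@brainRadius + spec@csfThickness
    place(r2 <= csfOuter^2, "csf_shell")
    if (spec@skinThickness > 0)
        place(r2 <= (csfOuter + spec@skinThickness)^2, "skin")

    fineVol <- LabelVolume(fine, grid = grid, table = fineTable())
    coarseVol <- projectFineToCoarse(fineVol, phantomFineToCoarse())

    # separable quadratic bias field normalised to [-1, 1]
    half <- (grid@shape - 1) * grid@spacing / 2
    q <- ((X - centre[1]) / half[1])^2 + ((Y - centre[2]) / half[2])^2 +
        ((Z - centre[3]) / half[3])^2
    q <- 2 * q / max(q) - 1
    means <- spec@classMeans[as.character(labelArray(coarseVol))]
    vals <- array(means * (1 + spec@biasAmplitude * q), grid@shape)
    if (spec@noiseSd > 0)
        vals <- vals + withr::with_seed(spec@seed,
            array(stats::rnorm(length(vals), 0, spec@noiseSd), grid@shape))
    Atlas(id = id,
          intensity = IntensityVolume(vals, grid = grid),
          coarse = coarseVol, fine = fineVol, meta = meta)
}

#' Construct a LibrarySpec
#'
#' @param nAtlases number of phantoms.
#' @param base base [PhantomSpec-class]; per-member geometry is derived from
#'   it.
#' @param ventricleScaleRange multiplier interval on the ventricle semiaxes;
#'   members take evenly spaced values across it.
#' @param cortexJitter half-width (mm) of the seeded uniform jitter on
#'   cortex thickness.
#' @param seed integer RNG seed.
#' @return a [LibrarySpec-class].
#' @export
librarySpec <- function(nAtlases = 20L, base = phantomSpec(),
                        ventricleScaleRange = c(0.7, 1.5),
                        cortexJitter = 0.8, seed = 1L) {
    new("LibrarySpec", nAtlases = as.integer(nAtlases), base = base,
        ventricleScaleRange = as.numeric(ventricleScaleRange),
        cortexJitter = cortexJitter, seed = as.integer(seed))
}

#' Generate a phantom library with controlled ventricle-volume spread
#'
#' Member `i` of `n` gets ventricle semiaxes scaled by the `i`-th of `n`
#' evenly spaced multipliers across `ventricleScaleRange` (a single member
#' sits at mid-range), and a cortex thickness jittered by seeded uniform
#' noise. Synthetic ages increase with ventricle scale (ventricular
#' enlargement with age), splitting members into "adult" and "geriatric"
#' groups at age 60.
#'
#' @param lspec a [LibrarySpec-class].
#' @return list with elements `library` (an [AtlasLibrary-class]) and
#'   `truth` (data.frame: id, ventricle_scale, cortex_thickness_mm,
#'   ventricle_voxels, ventricle_volume_mm3).
#' @export
makeLibrary <- function(lspec) {
    validObject(lspec)
    n <- lspec@nAtlases
    rng <- lspec@ventricleScaleRange
    scales <- if (n == 1L) mean(rng) else seq(rng[1], rng[2], length.out = n)
    jit <- withr::with_seed(lspec@seed,
        stats::runif(n, -lspec@cortexJitter, lspec@cortexJitter))
    base <- lspec@base
    members <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
        spec <- base
        spec@ventricleSemiaxes <- base@ventricleSemiaxes * scales[i]
        spec@cortexThickness <- base@cortexThickness + jit[i]
        spec@seed <- as.integer((lspec@seed + 7919L * i) %% .Machine$integer.max)
        validObject(spec)
        id <- sprintf("a%02d", i)
        age <- 20 + 60 * (scales[i] - rng[1]) / max(rng[2] - rng[1], 1e-12)
        meta <- list(age = age,
                     group = if (age >= 60) "geriatric" else "adult")
        members[[i]] <- makePhantom(spec, id = id, meta = meta)
        fl <- labelArray(atlasFine(members[[i]]))
        nVent <- sum(fl %in% c(FINE_IDS[["lateral_ventricle_L"]],
                               FINE_IDS[["lateral_ventricle_R"]],
                               FINE_IDS[["third_ventricle"]]))
        truth[[i]] <- data.frame(
            id = id, ventricle_scale = scales[i],
            cortex_thickness_mm = spec@cortexThickness,
            ventricle_voxels = nVent,
            ventricle_volume_mm3 = nVent * prod(base@grid@spacing),
            stringsAsFactors = FALSE)
    }
    list(library = AtlasLibrary(members), truth = do.call(rbind, truth))
}
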