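#' @import methods
NULL

#' VolumeGrid: the sampling geometry of a 3D volume
#'
#' A `VolumeGrid` records the voxel lattice shared by an intensity volume and
#' its label maps: the number of voxels per axis, the voxel spacing in mm,
#' and the position (mm) of the first voxel centre. Two grids are
#' *compatible* iff shape, spacing and origin agree exactly; no resampling
#' is ever performed, mixed grids are a hard error.
#'
#' @slot shape integer(3), voxels per axis (all >= 1).
#' @slot spacing numeric(3), mm per voxel (all > 0).
#' @slot origin numeric(3), mm position of voxel (1,1,1).
#' @export
setClass("VolumeGrid",
    representation(shape = "integer", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be three integers >= 1")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be three positive reals")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be three finite reals")
        if (length(msg)) msg else TRUE
    })

#' @describeIn VolumeGrid-class Constructor.
#' @param shape,spacing,origin see slots.
#' @export
VolumeGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("VolumeGrid", shape = as.integer(shape),
        spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' IntensityVolume: a 3D scalar image on a VolumeGrid
#'
#' Holds the voxel intensities of a structural MR image (or phantom) in
#' arbitrary units. All entries must be finite; non-finite values are
#' rejected at construction and at load time.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values 3D numeric array, dim equal to `shape(grid)`.
#' @export
setClass("IntensityVolume",
    representation(grid = "VolumeGrid", values = "array"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@values), as.integer(object@grid@shape)))
            msg <- c(msg, "values dim must equal grid shape")
        if (any(!is.finite(object@values)))
            msg <- c(msg, "non-finite intensity values")
        if (length(msg)) msg else TRUE
    })

#' @describeIn IntensityVolume-class Constructor; `grid` defaults to a unit
#'   1 mm grid matching `dim(values)`.
#' @param values,grid see slots.
#' @export
IntensityVolume <- function(values, grid = NULL) {
    values <- as.array(values)
    storage.mode(values) <- "double"
    if (is.null(grid)) grid <- VolumeGrid(dim(values))
    new("IntensityVolume", grid = grid, values = values)
}

#' LabelVolume: a 3D integer label map on a VolumeGrid
#'
#' Non-negative integer labels; id 0 is reserved for background ("remaining
#' space"). A label table maps every nonzero id present in the array to a
#' structure name.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot labels 3D integer array.
#' @slot table data.frame with columns `id` (integer) and `name` (character).
#' @export
setClass("LabelVolume",
    representation(grid = "VolumeGrid", labels = "array", table = "data.frame"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@labels), as.integer(object@grid@shape)))
            msg <- c(msg, "labels dim must equal grid shape")
        if (any(object@labels < 0L))
            msg <- c(msg, "labels must be non-negative")
        if (!all(c("id", "name") %in% names(object@table)))
            msg <- c(msg, "table must have columns id, name")
        ids <- setdiff(unique(as.integer(object@labels)), 0L)
        if (!all(ids %in% object@table$id))
            msg <- c(msg, sprintf("label id(s) missing from table: %s",
                paste(setdiff(ids, object@table$id), collapse = ", ")))
        if (anyDuplicated(object@table$id))
            msg <- c(msg, "duplicate ids in label table")
        if (length(msg)) msg else TRUE
    })

#' @describeIn LabelVolume-class Constructor. Values within 1e-6 of an
#'   integer are rounded; anything else errors.
#' @param labels,grid,table see slots; `table` may be omitted, in which case
#'   ids are named `label_<id>`.
#' @export
LabelVolume <- function(labels, grid = NULL, table = NULL) {
    labels <- as.array(labels)
    if (!is.integer(labels)) {
        rounded <- round(labels)
        if (any(abs(labels - rounded) > 1e-6, na.rm = TRUE) ||
            any(!is.finite(labels)))
            stop("non-integer label values")
        labels <- rounded
        storage.mode(labels) <- "integer"
    }
    if (is.null(grid)) grid <- VolumeGrid(dim(labels))
    if (is.null(table)) {
        ids <- setdiff(sort(unique(as.integer(labels))), 0L)
        table <- data.frame(id = as.integer(ids),
                            name = sprintf("label_%d", ids),
                            stringsAsFactors = FALSE)
    }
    new("LabelVolume", grid = grid, labels = labels, table = table)
}

#' Atlas: one library member (intensity + coarse + fine labels)
#'
#' @slot id character scalar, unique within a library.
#' @slot intensity an [IntensityVolume-class].
#' @slot coarse a [LabelVolume-class] using the 7-label coarse scheme.
#' @slot fine a [LabelVolume-class] with the fine parcellation.
#' @slot meta named list (e.g. `age`, `group`).
#' @export
setClass("Atlas",
    representation(id = "character", intensity = "IntensityVolume",
                   coarse = "LabelVolume", fine = "LabelVolume",
                   meta = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
            msg <- c(msg, "id must be a non-empty string")
        g <- object@intensity@grid
        if (!gridsCompatible(g, object@coarse@grid) ||
            !gridsCompatible(g, object@fine@grid))
            msg <- c(msg, "intensity, coarse and fine grids must be compatible")
        bad <- setdiff(unique(as.integer(object@coarse@labels)), 0:6)
        if (length(bad))
            msg <- c(msg, sprintf("coarse map uses non-scheme id(s): %s",
                                  paste(bad, collapse = ", ")))
        if (length(msg)) msg else TRUE
    })

#' @describeIn Atlas-class Constructor.
#' @param id,intensity,coarse,fine,meta see slots.
#' @export
Atlas <- function(id, intensity, coarse, fine, meta = list()) {
    new("Atlas", id = as.character(id), intensity = intensity,
        coarse = coarse, fine = fine, meta = meta)
}

#' AtlasLibrary: an ordered, grid-consistent collection of atlases
#'
#' @slot atlases list of [Atlas-class] with unique ids; order is meaningful
#'   (it is the manifest row order and the deterministic tie-break domain).
#' @slot grid the shared [VolumeGrid-class].
#' @export
setClass("AtlasLibrary",
    representation(atlases = "list", grid = "VolumeGrid"),
    validity = function(object) {
        msg <- character()
        if (!all(vapply(object@atlases, is, logical(1), "Atlas")))
            msg <- c(msg, "atlases must all be Atlas objects")
        else {
            ids <- vapply(object@atlases, function(a) a@id, character(1))
            if (anyDuplicated(ids))
                msg <- c(msg, sprintf("duplicate id: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
            ok <- vapply(object@atlases,
                function(a) gridsCompatible(a@intensity@grid, object@grid),
                logical(1))
            if (!all(ok))
                msg <- c(msg, sprintf("incompatible grid for atlas(es): %s",
                    paste(ids[!ok], collapse = ", ")))
        }
        if (length(msg)) msg else TRUE
    })

#' @describeIn AtlasLibrary-class Constructor; the grid is taken from the
#'   first member unless given.
#' @param atlases,grid see slots.
#' @export
AtlasLibrary <- function(atlases, grid = NULL) {
    if (is.null(grid)) {
        if (!length(atlases)) stop("empty atlas list and no grid given")
        grid <- atlases[[1]]@intensity@grid
    }
    new("AtlasLibrary", atlases = atlases, grid = grid)
}

#' Ranking: atlas ids ordered by similarity to a target
#'
#' @slot method one of "4L", "LV", "MI", "random".
#' @slot scores data.frame (atlas_id, value), empty for random rankings.
#' @slot order character, atlas ids best first.
#' @slot seed integer, the RNG seed (random method only, NA otherwise).
#' @export
setClass("Ranking",
    representation(method = "character", scores = "data.frame",
                   order = "character", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (!object@method %in% c("4L", "LV", "MI", "random"))
            msg <- c(msg, "unknown method")
        if (nrow(object@scores)) {
            if (!setequal(object@scores$atlas_id, object@order))
                msg <- c(msg, "order must be a permutation of scored ids")
            v <- object@scores$value[match(object@order,
                                           object@scores$atlas_id)]
            if (is.unsorted(rev(v), strictly = FALSE))
                msg <- c(msg, "scores must be non-increasing along order")
        }
        if (length(msg)) msg else TRUE
    })

#' CoarseSegResult: output of the fast 7-label tissue segmentation
#'
#' @slot coarse a [LabelVolume-class] on the coarse scheme.
#' @slot classMeans named numeric, per-class mean intensity found.
#' @slot brainMaskVoxels integer, voxels in the brain mask.
#' @export
setClass("CoarseSegResult",
    representation(coarse = "LabelVolume", classMeans = "numeric",
                   brainMaskVoxels = "integer"))

#' SweepReport: the method x subset-size evaluation harness output
#'
#' @slot records data.frame of per-structure Dice records
#'   (target_id, method, k, level, structure, dice).
#' @slot summaries data.frame of mean Dice per (method, k, level).
#' @slot poorRatio data.frame of poor-outcome ratios per (method, k).
#' @slot pairedStats data.frame of paired-t comparisons per method pair.
#' @slot params list echoing the sweep configuration (seed included).
#' @export
setClass("SweepReport",
    representation(records = "data.frame", summaries = "data.frame",
                   poorRatio = "data.frame", pairedStats = "data.frame",
                   params = "list"))

#' PhantomSpec: the geometry and intensity model of one brain phantom
#'
#' A phantom is a set of nested spherical shells (white matter core, cortical
#' gray shell, surrounding CSF shell, skin shell) plus paired lateral-ventricle
#' ellipsoids, a third-ventricle proxy, hippocampus proxies in each temporal
#' region, and a skull-base blob. Intensity = coarse class mean x a smooth
#' separable-quadratic bias field (1 + bias_amplitude * q, q in [-1, 1]) +
#' Gaussian noise.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot brainRadius outer radius of the cortical surface, mm.
#' @slot cortexThickness gray-matter shell thickness, mm.
#' @slot csfThickness surrounding-CSF shell thickness, mm.
#' @slot ventricleSemiaxes numeric(3), lateral-ventricle ellipsoid semiaxes, mm.
#' @slot ventricleOffset numeric(3), lateral-ventricle centre offset from the
#'   field-of-view centre, mm; x component is mirrored for the left/right pair.
#' @slot skullBaseRadius radius of the skull-base blob, mm (0 disables).
#' @slot skinThickness skin shell thickness, mm (0 disables).
#' @slot classMeans named numeric, intensity mean per coarse id "0".."6".
#' @slot noiseSd additive Gaussian noise sd.
#' @slot biasAmplitude multiplicative bias amplitude in [0, 1].
#' @slot seed integer RNG seed for noise.
#' @export
setClass("PhantomSpec",
    representation(grid = "VolumeGrid", brainRadius = "numeric",
        cortexThickness = "numeric", csfThickness = "numeric",
        ventricleSemiaxes = "numeric", ventricleOffset = "numeric",
        skullBaseRadius = "numeric", skinThickness = "numeric",
        classMeans = "numeric", noiseSd = "numeric",
        biasAmplitude = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- character()
        halfExtent <- min((object@grid@shape - 1) * object@grid@spacing) / 2
        outer <- object@brainRadius + object@csfThickness +
            object@skinThickness
        if (outer >= halfExtent)
            msg <- c(msg, sprintf(
                "nested shells (outer radius %.1f mm) must fit inside the field of view (half-extent %.1f mm)",
                outer, halfExtent))
        wmRadius <- object@brainRadius - object@cortexThickness
        if (wmRadius <= 0)
            msg <- c(msg, "cortex thicker than brain radius")
        reach <- sqrt(sum(object@ventricleOffset^2)) +
            max(object@ventricleSemiaxes)
        if (reach >= wmRadius)
            msg <- c(msg, sprintf(
                "ventricle ellipsoid (reach %.1f mm) must lie strictly inside the white matter (radius %.1f mm)",
                reach, wmRadius))
        if (any(object@ventricleSemiaxes <= 0) || object@brainRadius <= 0 ||
            object@cortexThickness <= 0 || object@csfThickness <= 0)
            msg <- c(msg, "radii and thicknesses must be positive")
        if (object@noiseSd < 0 || object@biasAmplitude < 0 ||
            object@biasAmplitude > 1)
            msg <- c(msg, "noiseSd must be >= 0 and biasAmplitude in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' LibrarySpec: a family of phantoms with controlled anatomical spread
#'
#' Ventricle size is the systematically varied trait: the ventricle semiaxes
#' of the `n` members are scaled by evenly spaced multipliers across
#' `ventricleScaleRange` (not sampled), so selection-recovery experiments
#' have a known unique answer. Cortex thickness is jittered with seeded
#' uniform noise.
#'
#' @slot nAtlases number of members.
#' @slot base the base [PhantomSpec-class].
#' @slot ventricleScaleRange numeric(2), multiplier interval (lower > 0).
#' @slot cortexJitter half-width of the uniform cortex-thickness jitter, mm.
#' @slot seed integer RNG seed for jitter and per-member noise.
#' @export
setClass("LibrarySpec",
    representation(nAtlases = "integer", base = "PhantomSpec",
        ventricleScaleRange = "numeric", cortexJitter = "numeric",
        seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@nAtlases < 1L)
            msg <- c(msg, "nAtlases must be >= 1")
        if (length(object@ventricleScaleRange) != 2L ||
            object@ventricleScaleRange[1] <= 0 ||
            diff(object@ventricleScaleRange) < 0)
            msg <- c(msg, "ventricleScaleRange must be an interval with positive lower bound")
        if (object@cortexJitter < 0)
            msg <- c(msg, "cortexJitter must be >= 0")
        if (length(msg)) msg else TRUE
    })
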