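#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into an [IntensityVolume-class] or, with
#' `asLabels = TRUE`, a [LabelVolume-class]. Spacing is taken from the
#' header pixdim and the origin from the sform translation (falling back to
#' qoffset). Volumes are used in stored array order; no reorientation is
#' applied. In label mode, values within 1e-6 of an integer are rounded and
#' anything else is an error; in intensity mode non-finite voxels are an
#' error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param asLabels read as an integer label map?
#' @param table optional label table (data.frame id, name) for label mode.
#' @return an [IntensityVolume-class] or [LabelVolume-class].
#' @export
readVolume <- function(path, asLabels = FALSE, table = NULL) {
    if (!file.exists(path)) stop(sprintf("missing file: %s", path))
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    vals <- array(as.numeric(img), dim = dim(img)[1:3])
    spacing <- hdr$pixdim[2:4]
    if (hdr$sform_code > 0)
        origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
    else
        origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    grid <- VolumeGrid(dim(vals), spacing, origin)
    if (asLabels) {
        if (any(!is.finite(vals)) ||
            any(abs(vals - round(vals)) > 1e-6))
            stop("non-integer label values in ", path)
        LabelVolume(vals, grid = grid, table = table)
    } else {
        if (any(!is.finite(vals)))
            stop("non-finite intensities in ", path)
        IntensityVolume(vals, grid = grid)
    }
}

#' Write a volume to NIfTI
#'
#' Label volumes are written as int32 (exact round-trip); intensity volumes
#' as float64. Spacing goes to pixdim and the origin into the sform
#' translation column (sform code 2).
#'
#' @param vol an [IntensityVolume-class] or [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
    if (!dir.exists(dirname(path)))
        stop(sprintf("unwritable path (no such directory): %s",
                     dirname(path)))
    grid <- volumeGrid(vol)
    labels <- is(vol, "LabelVolume")
    img <- RNifti::asNifti(if (labels) labelArray(vol) else
                           voxelValues(vol))
    RNifti::pixdim(img) <- grid@spacing
    m <- diag(c(grid@spacing, 1))
    m[1:3, 4] <- grid@origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path,
                       datatype = if (labels) "int32" else "double")
    invisible(path)
}

#' Load an atlas library from a CSV manifest
#'
#' The manifest must have columns `id`, `intensity_path`, `coarse_path`,
#' `fine_path`; optional `age` and `group` columns (and any further columns)
#' become atlas metadata. Relative paths are resolved against the manifest's
#' directory. Member order equals row order; duplicate ids and grid
#' mismatches are hard errors.
#'
#' @param manifest path to the CSV manifest.
#' @return an [AtlasLibrary-class].
#' @export
loadLibrary <- function(manifest) {
    if (!file.exists(manifest)) stop(sprintf("missing file: %s", manifest))
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("id", "intensity_path", "coarse_path", "fine_path")
    if (!all(need %in% names(tab)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$id))
        stop(sprintf("duplicate id: %s",
            paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
    root <- dirname(manifest)
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                  file.path(root, p))
    metaCols <- setdiff(names(tab), need)
    members <- lapply(seq_len(nrow(tab)), function(i) {
        meta <- as.list(tab[i, metaCols, drop = FALSE])
        Atlas(id = tab$id[i],
              intensity = readVolume(resolve(tab$intensity_path[i])),
              coarse = readVolume(resolve(tab$coarse_path[i]),
                                  asLabels = TRUE, table = coarseTable()),
              fine = readVolume(resolve(tab$fine_path[i]), asLabels = TRUE),
              meta = meta)
    })
    grid <- volumeGrid(members[[1]])
    for (a in members)
        if (!gridsCompatible(volumeGrid(a), grid))
            stop(sprintf("incompatible grid for atlas '%s'", atlasId(a)))
    AtlasLibrary(members, grid = grid)
}

#' Write an atlas library to disk
#'
#' Writes one intensity / coarse / fine NIfTI triple per atlas plus a CSV
#' manifest that [loadLibrary()] reads back.
#'
#' @param lib an [AtlasLibrary-class].
#' @param dir output directory (created if needed).
#' @param gz write gzipped NIfTI?
#' @return the manifest path, invisibly.
#' @export
writeLibrary <- function(lib, dir, gz = TRUE) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (gz) ".nii.gz" else ".nii"
    rows <- lapply(atlases(lib), function(a) {
        id <- atlasId(a)
        paths <- sprintf("%s_%s%s", id, c("t1", "coarse", "fine"), ext)
        writeVolume(atlasIntensity(a), file.path(dir, paths[1]))
        writeVolume(atlasCoarse(a), file.path(dir, paths[2]))
        writeVolume(atlasFine(a), file.path(dir, paths[3]))
        meta <- atlasMeta(a)
        data.frame(id = id, intensity_path = paths[1],
                   coarse_path = paths[2], fine_path = paths[3],
                   age = if (is.null(meta$age)) NA_real_
                         else as.numeric(meta$age),
                   group = if (is.null(meta$group)) NA_character_
                           else as.character(meta$group),
                   stringsAsFactors = FALSE)
    })
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
    invisible(manifest)
}
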