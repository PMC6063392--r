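#' Construct and validate a hierarchy table
#'
#' A hierarchy table maps fine label ids to named superstructures at three
#' nested granularity levels: Level A (hemispheric tissue), Level B (lobes
#' and major white-matter territories) and Level C (individual nuclei, gyri
#' and ventricular parts). `NA` means the fine structure has no
#' superstructure at that level and aggregates to background. The table
#' must be a tree: each named Level-C structure carries exactly one Level-B
#' value (possibly `NA`), and each named Level-B structure exactly one
#' Level-A value.
#'
#' The historical ROI-list spelling "Hippocampu_R" is normalised to
#' "Hippocampus_R" with a message; both are accepted on load.
#'
#' @param df data.frame with columns `fine_id`, `level_a`, `level_b`,
#'   `level_c` (an optional `fine_name` column is kept).
#' @return the validated data.frame with class `"HierarchyTable"` prepended.
#' @export
hierarchyTable <- function(df) {
    need <- c("fine_id", "level_a", "level_b", "level_c")
    if (!all(need %in% names(df)))
        stop("hierarchy table needs columns ", paste(need, collapse = ", "))
    df$fine_id <- as.integer(df$fine_id)
    for (col in c("level_a", "level_b", "level_c")) {
        v <- as.character(df[[col]])
        v[!is.na(v) & (v == "" | v == "none" | v == "NA")] <- NA_character_
        df[[col]] <- normalizeROIName(v)
    }
    if (anyDuplicated(df$fine_id))
        stop("duplicate fine_id in hierarchy table")
    checkTree <- function(child, parent, what) {
        sub <- df[!is.na(df[[child]]), c(child, parent)]
        if (!nrow(sub)) return(invisible(TRUE))
        nParents <- tapply(sub[[parent]], sub[[child]],
                           function(p) length(unique(p)))
        bad <- names(nParents)[nParents > 1]
        if (length(bad))
            stop(sprintf("hierarchy is not a tree: %s structure(s) with multiple parents: %s",
                         what, paste(bad, collapse = ", ")))
        invisible(TRUE)
    }
    checkTree("level_c", "level_b", "Level-C")
    checkTree("level_b", "level_a", "Level-B")
    class(df) <- c("HierarchyTable", class(df))
    df
}

# accepted alternative spellings of ROI names
normalizeROIName <- function(x) {
    fix <- !is.na(x) & x == "Hippocampu_R"
    if (any(fix)) {
        message("normalising ROI name 'Hippocampu_R' to 'Hippocampus_R'")
        x[fix] <- "Hippocampus_R"
    }
    x
}

#' Read a hierarchy table from TSV
#'
#' @param path TSV with columns `fine_id`, `level_a`, `level_b`, `level_c`
#'   (empty cells or "none" mean no superstructure at that level).
#' @return a validated hierarchy table (see [hierarchyTable()]).
#' @export
readHierarchy <- function(path) {
    if (!file.exists(path)) stop(sprintf("missing file: %s", path))
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA", "none"))
    hierarchyTable(df)
}

#' The packaged hierarchy table for the phantom parcellation
#'
#' Maps the phantom's proxy structures onto the packaged Level A/B/C ROI
#' names (cortex to CerebralCortex/Frontal, hippocampus proxies to
#' Limbic/Hippocampus, ventricle proxies to the lateral-ventricle-part and
#' third/fourth-ventricle Level-C names) so the evaluation code paths are
#' exercised level by level. Real atlas sets require a user-supplied table.
#'
#' @return a validated hierarchy table.
#' @export
phantomHierarchy <- function() {
    readHierarchy(system.file("extdata", "phantom_hierarchy.tsv",
                              package = "atlassel", mustWork = TRUE))
}

#' Aggregate a fine label volume to a granularity level
#'
#' Each voxel's fine id is replaced by an integer code for its level name;
#' codes are assigned by first appearance in table order, and fine ids with
#' no name at the level map to 0. Voxel counts are conserved: each
#' superstructure's count equals the sum of its member fine structures'
#' counts.
#'
#' @param fine a [LabelVolume-class].
#' @param table a hierarchy table ([hierarchyTable()]).
#' @param level "A", "B" or "C".
#' @return a [LabelVolume-class] whose table maps codes to level names.
#' @export
aggregateToLevel <- function(fine, table, level = c("A", "B", "C")) {
    level <- match.arg(level)
    col <- c(A = "level_a", B = "level_b", C = "level_c")[[level]]
    lab <- labelArray(fine)
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)
    missing <- setdiff(ids, table$fine_id)
    if (length(missing))
        stop(sprintf("fine id(s) missing from table: %s",
                     paste(missing, collapse = ", ")))
    names <- table[[col]]
    uniqueNames <- unique(names[!is.na(names)])   # first-appearance order
    codes <- match(names, uniqueNames)            # NA -> background
    codes[is.na(codes)] <- 0L
    lut <- integer(max(c(table$fine_id, ids)) + 1L)
    lut[table$fine_id + 1L] <- codes
    out <- array(lut[lab + 1L], dim(lab))
    outTable <- data.frame(id = seq_along(uniqueNames), name = uniqueNames,
                           stringsAsFactors = FALSE)
    LabelVolume(out, grid = volumeGrid(fine), table = outTable)
}

#' Load the Level A/B/C evaluation ROI sets
#'
#' Reads a TSV with columns `level` (A/B/C) and `name`. The packaged
#' default carries the standard 63-name evaluation list: 4 Level-A, 26
#' Level-B and 33 Level-C region names (lateral-ventricle parts listed per
#' horn and side, plus the combined third-and-fourth-ventricle entry).
#'
#' @param path TSV path; `NULL` loads the packaged default.
#' @return named list of character vectors `A`, `B`, `C` (ordered as in
#'   the file).
#' @export
loadROISets <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "roi_sets_level_abc.tsv",
                            package = "atlassel", mustWork = TRUE)
    if (!file.exists(path)) stop(sprintf("missing file: %s", path))
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("level", "name") %in% names(df)))
        stop("ROI set file needs columns level, name")
    bad <- setdiff(unique(df$level), c("A", "B", "C"))
    if (length(bad))
        stop(sprintf("unknown level token: %s", paste(bad, collapse = ", ")))
    df$name <- normalizeROIName(df$name)
    list(A = df$name[df$level == "A"],
         B = df$name[df$level == "B"],
         C = df$name[df$level == "C"])
}
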