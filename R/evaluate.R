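#' Per-structure Dice at one granularity level
#'
#' Aggregates both the estimated segmentation and the truth to the given
#' level via the hierarchy table, then computes Dice per named structure of
#' the ROI set. Structures empty in the truth are reported with `dice = NA`
#' (absent) and excluded from downstream means; a structure present in
#' truth but missing from the estimate scores 0.
#'
#' @param seg,truth fine [LabelVolume-class] maps on compatible grids.
#' @param table hierarchy table ([hierarchyTable()]).
#' @param level "A", "B" or "C".
#' @param roiSet character vector of structure names to score; default is
#'   the packaged ROI list for the level.
#' @return data.frame with columns `structure`, `dice` (`NA` = absent in
#'   truth).
#' @export
structureDice <- function(seg, truth, table, level = c("A", "B", "C"),
                          roiSet = NULL) {
    level <- match.arg(level)
    checkPairGrids(seg, truth)
    if (is.null(roiSet)) roiSet <- loadROISets()[[level]]
    aSeg <- aggregateToLevel(seg, table, level)
    aTruth <- aggregateToLevel(truth, table, level)
    segTab <- labelTable(aSeg); truthTab <- labelTable(aTruth)
    segArr <- labelArray(aSeg); truthArr <- labelArray(aTruth)
    dice <- vapply(roiSet, function(nm) {
        idT <- truthTab$id[truthTab$name == nm]
        maskT <- if (length(idT)) truthArr == idT[1]
                 else array(FALSE, dim(truthArr))
        if (!any(maskT)) return(NA_real_)       # absent in truth
        idS <- segTab$id[segTab$name == nm]
        maskS <- if (length(idS)) segArr == idS[1]
                 else array(FALSE, dim(segArr))
        diceCoefficient(maskS, maskT)
    }, numeric(1))
    data.frame(structure = roiSet, dice = unname(dice),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Poor-outcome ratio
#'
#' Fraction of Dice scores strictly below a threshold (default 0.7), a
#' tail-sensitive complement to mean Dice: occasional segmentation failures
#' move this ratio even when they barely move the mean.
#'
#' @param dices numeric vector of Dice values; `NA`s (absent structures)
#'   are dropped.
#' @param threshold the poor-outcome cut-off.
#' @return ratio in `[0, 1]`.
#' @export
poorOutcomeRatio <- function(dices, threshold = 0.7) {
    dices <- dices[!is.na(dices)]
    if (!length(dices)) stop("empty Dice list")
    mean(dices < threshold)
}

#' Paired comparison of two methods
#'
#' Classical paired t test on per-target differences, two-sided. Zero
#' variance with zero mean difference returns `t = 0, p = 1`; zero variance
#' with a nonzero mean is guarded to `t = +/-Inf, p = 0` with a warning.
#'
#' @param a,b numeric vectors of per-target scores, paired by position
#'   (equal lengths >= 2).
#' @return list with elements `t`, `p`, `df`, `meanDiff`.
#' @export
pairedCompare <- function(a, b) {
    if (length(a) != length(b)) stop("length mismatch")
    n <- length(a)
    if (n < 2L) stop("need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
        if (mean(d) == 0)
            return(list(t = 0, p = 1, df = n - 1L, meanDiff = 0))
        warning("zero variance with nonzero mean difference; t is infinite")
        return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                    meanDiff = mean(d)))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), meanDiff = unname(tt$estimate))
}

#' Run the full method-by-subset-size evaluation sweep
#'
#' For each target and each (method, k) cell: rank the candidate pool
#' (leave-one-out — the target never appears in its own pool), select the
#' subset, fuse the selected fine label maps, and score per-structure Dice
#' against the target's own fine truth at Levels A, B and C. With the
#' default 4 methods and 5 subset sizes every target is segmented by 20
#' atlas subsets. Deterministic given `seed`.
#'
#' @param lib an [AtlasLibrary-class] (candidate pool).
#' @param targets list of [Atlas-class] targets (typically library members,
#'   which are then excluded from their own pool by id).
#' @param methods subset of c("4L", "LV", "MI", "random").
#' @param ks subset sizes; values exceeding the candidate pool are clamped
#'   to it (the subset saturates).
#' @param mode fusion mode, "majority" or "weighted" (weighted uses the
#'   selection scores; random subsets fall back to equal weights).
#' @param seed master seed: target coarse estimation, random subsets and
#'   any other randomness all derive from it.
#' @param table hierarchy table; default [phantomHierarchy()].
#' @param roiSets named list of ROI name vectors per level; default
#'   [loadROISets()].
#' @param coarse "estimate" runs [quickCoarseSegment()] on each target's
#'   intensity (the pipeline path); "truth" uses the target atlas's own
#'   coarse map (the bypass path for precomputed maps).
#' @param threshold poor-outcome Dice threshold.
#' @param nBins histogram bins for MI.
#' @return a [SweepReport-class].
#' @export
runSweep <- function(lib, targets, methods = c("4L", "LV", "MI", "random"),
                     ks = c(5, 10, 15, 20, 25), mode = "majority",
                     seed = 1L, table = phantomHierarchy(),
                     roiSets = loadROISets(),
                     coarse = c("estimate", "truth"), threshold = 0.7,
                     nBins = 64L) {
    coarse <- match.arg(coarse)
    methods <- match.arg(methods, c("4L", "LV", "MI", "random"),
                         several.ok = TRUE)
    seed <- as.integer(seed)
    records <- withr::with_seed(seed, {
        recs <- list()
        for (target in targets) {
            tid <- atlasId(target)
            poolIds <- setdiff(atlasIds(lib), tid)
            if (!length(poolIds))
                stop("no candidate atlases for target ", tid)
            pool <- lib[poolIds]
            targetCoarse <- if (coarse == "estimate")
                coarseMap(quickCoarseSegment(atlasIntensity(target),
                    seed = sample.int(.Machine$integer.max, 1L)))
            else atlasCoarse(target)
            rankings <- list()
            for (m in setdiff(methods, "random"))
                rankings[[m]] <- rankAtlases(pool, method = m,
                    targetCoarse = targetCoarse,
                    targetImage = atlasIntensity(target), nBins = nBins)
            for (k in ks) {
                kEff <- min(k, length(poolIds))
                for (m in methods) {
                    if (m == "random") {
                        ids <- sample(poolIds, kEff)
                        w <- rep(1, kEff)
                    } else {
                        ids <- selectTopK(rankings[[m]], kEff)
                        sc <- rankingScores(rankings[[m]])
                        w <- sc$value[match(ids, sc$atlas_id)]
                    }
                    fines <- lapply(ids, function(i) atlasFine(lib[[i]]))
                    fused <- if (mode == "weighted" && any(w > 0))
                        fuseLabels(fines, mode = "weighted", weights = w)
                    else fuseLabels(fines, mode = "majority")
                    for (lv in c("A", "B", "C")) {
                        sd <- structureDice(fused, atlasFine(target),
                                            table, lv, roiSets[[lv]])
                        recs[[length(recs) + 1L]] <- data.frame(
                            target_id = tid, method = m, k = k,
                            level = lv, structure = sd$structure,
                            dice = sd$dice, stringsAsFactors = FALSE)
                    }
                }
            }
        }
        do.call(rbind, recs)
    })
    present <- records[!is.na(records$dice), ]
    summaries <- stats::aggregate(dice ~ method + k + level, present, mean)
    summaries <- summaries[order(summaries$method, summaries$k,
                                 summaries$level), ]
    names(summaries)[names(summaries) == "dice"] <- "mean_dice"
    poorRatio <- stats::aggregate(dice ~ method + k, present,
        function(d) mean(d < threshold))
    names(poorRatio)[names(poorRatio) == "dice"] <- "poor_ratio"
    poorRatio <- poorRatio[order(poorRatio$method, poorRatio$k), ]

    perTarget <- stats::aggregate(dice ~ method + target_id, present, mean)
    pairs <- utils::combn(sort(unique(present$method)), 2, simplify = FALSE)
    pairedStats <- do.call(rbind, lapply(pairs, function(pr) {
        a <- perTarget[perTarget$method == pr[1], ]
        b <- perTarget[perTarget$method == pr[2], ]
        ord <- intersect(a$target_id, b$target_id)
        if (length(ord) < 2) return(NULL)
        pc <- pairedCompare(a$dice[match(ord, a$target_id)],
                            b$dice[match(ord, b$target_id)])
        data.frame(method_a = pr[1], method_b = pr[2], t = pc$t, p = pc$p,
                   mean_diff = pc$meanDiff, n = length(ord),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(pairedStats))
        pairedStats <- data.frame(method_a = character(),
            method_b = character(), t = numeric(), p = numeric(),
            mean_diff = numeric(), n = integer())
    rownames(records) <- rownames(summaries) <- NULL
    rownames(poorRatio) <- rownames(pairedStats) <- NULL
    new("SweepReport", records = records, summaries = summaries,
        poorRatio = poorRatio, pairedStats = pairedStats,
        params = list(methods = methods, ks = ks, mode = mode, seed = seed,
                      coarse = coarse, threshold = threshold,
                      nBins = nBins))
}

#' Write a sweep report to a directory
#'
#' Emits `records.csv`, `summaries.csv`, `poor_ratio.csv`,
#' `paired_stats.csv` and a `run_metadata.json` echoing the configuration.
#'
#' @param report a [SweepReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSweepReport <- function(report, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(sweepRecords(report),
                     file.path(dir, "records.csv"), row.names = FALSE)
    utils::write.csv(sweepSummaries(report),
                     file.path(dir, "summaries.csv"), row.names = FALSE)
    utils::write.csv(sweepPoorRatio(report),
                     file.path(dir, "poor_ratio.csv"), row.names = FALSE)
    utils::write.csv(sweepPairedStats(report),
                     file.path(dir, "paired_stats.csv"), row.names = FALSE)
    meta <- c(report@params,
              list(timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   package_version =
                       as.character(utils::packageVersion("atlassel"))))
    jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
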