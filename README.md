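# atlassel

Atlas pre-selection for multi-atlas brain MRI segmentation.

Multi-atlas segmentation propagates expert label maps from a library of
reference brains (atlases) onto a target image and fuses them into a
consensus parcellation. Accuracy and cost both grow with the number of
atlases used, so for each target one wants the *subset* of atlases that
best matches its anatomy — ventricle shape above all, since ventricles
vary enormously across individuals and ages. `atlassel` implements and
compares four pre-selection strategies over an atlas library:

* **4L** — mean Dice overlap of four coarse tissue labels (CSF space,
  gray matter, white matter, ventricles) between the target's fast
  7-label segmentation and each atlas's coarse map:
  `Dice(W_i, W_j) = 2|W_i ∩ W_j| / (|W_i| + |W_j|)`.
* **LV** — Dice of the ventricle label alone.
* **MI** — normalized mutual information of the intensity images,
  `MI(I_A, I_B) = (H(I_A) + H(I_B)) / H(I_A, I_B)` with
  `H(I) = −Σ_i P(i) log₂ P(i)`, a whole-image similarity in `[1, 2]`.
* **random** — a seeded uniform baseline.

Around the ranking sits a desk-scale segmentation core and evaluation
harness: a fast k-means-based 7-label coarse tissue segmenter, top-k
subset selection with deterministic tie-breaking, registration-free
majority / similarity-weighted label voting on a common voxel grid,
hierarchical evaluation at three granularity levels (Level A: 4
hemispheric tissue ROIs, Level B: 26 lobar ROIs, Level C: 33 fine ROIs),
per-structure Dice, the poor-outcome ratio (fraction of Dice scores
below 0.7) and paired t comparisons between methods. A synthetic phantom
generator produces brain-like libraries with controlled ventricle-volume
spread so every stage is testable without clinical data.

The package is written for neuroimaging methods developers and
pipeline builders who need a reproducible, fully seeded pre-selection
stage (or a test-bed for one) in front of an existing registration +
fusion pipeline.

## Worked example

Generate a 9-phantom library whose ventricle volumes grow evenly from
member `a01` to `a09`, take the middle member as the target, estimate its
coarse tissue map, rank the remaining atlases by the LV criterion, fuse
the top 5 and score the result:

```r
library(atlassel)

lb  <- makeLibrary(librarySpec(nAtlases = 9, seed = 5))
lib <- lb$library
head(lb$truth, 3)
#>    id ventricle_scale cortex_thickness_mm ventricle_voxels ventricle_volume_mm3
#> 1 a01             0.7            2.520343               40                   40
#> 2 a02             0.8            3.296350               60                   60
#> 3 a03             0.9            3.667001              100                  100

target <- lib[["a05"]]
seg <- quickCoarseSegment(atlasIntensity(target), seed = 7)
seg
#> CoarseSegResult: 17252 brain-mask voxels, class means 0=1.3, 1=46.8, 2=65.0, 3=100.6, 4=46.8

r <- rankAtlases(lib, method = "LV", targetCoarse = seg, targetId = "a05")
r
#> Ranking (LV): a04 > a06 > a03 > a07 > a08 > a09 > a02 > a01
#>   best score 0.8571, worst 0.4000

subset <- selectTopK(r, 5)
fused  <- fuseLabels(lapply(subset, function(i) atlasFine(lib[[i]])))
sd <- structureDice(fused, atlasFine(target), phantomHierarchy(), "C")
na.omit(sd)
#>                   structure      dice
#> 3             Hippocampus_L 0.6666667
#> 4             Hippocampus_R 0.6666667
#> 24 Lateral Ventrical_body_L 0.8172043
#> 29 Lateral Ventrical_body_R 0.8172043
#> 33     III_and_IV_ventricle 1.0000000
poorOutcomeRatio(sd$dice)
#> [1] 0.4
```

The ranking recovers the anatomy: the target is excluded from its own
pool (leave-one-out) and the nearest ventricle volumes (`a04`, `a06`)
rank first. `structureDice` reports Level-C Dice for every ROI present
in the truth; `poorOutcomeRatio` is the fraction below 0.7.

The full experiment grid — every method crossed with subset sizes
{5, 10, 15, 20, 25} over many targets, with summaries, poor-outcome
ratios and paired t statistics — is one call:

```r
report <- runSweep(lib, targets = list(lib[["a03"]], lib[["a07"]]), seed = 1)
sweepSummaries(report)
```

A command-line wrapper covering the same stages
(`phantom-lib`, `coarse`, `rank`, `segment`, `sweep`) is installed at
`system.file("scripts", "atlassel", package = "atlassel")`.

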