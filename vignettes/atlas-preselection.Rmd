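---
title: "Atlas pre-selection for multi-atlas segmentation: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas pre-selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlassel)
```

## The problem

Multi-atlas segmentation labels a target brain MR image by propagating
the label maps of a library of reference brains (atlases) onto it and
fusing them into a consensus. Both accuracy and computational cost grow
with the number of atlases, and an atlas whose anatomy differs grossly
from the target — most visibly in ventricle size and shape — contributes
errors rather than information. Pre-selection ranks the library by
similarity to the target and keeps only the top *k* members.

`atlassel` implements the ranking criteria, a registration-free fusion
and evaluation core around them, and a phantom generator that produces
libraries with controlled anatomical spread, so that the entire pipeline
is testable end to end at desk scale.

## Similarity criteria

Let $W_i, W_j$ be binary region masks on a common voxel grid. The Dice
overlap is

$$\mathrm{Dice}(W_i, W_j) = \frac{2\,|W_i \cap W_j|}{|W_i| + |W_j|}.$$

* **4L** scores an atlas by the unweighted mean of the Dice over the
  four brain tissue classes of the coarse 7-label scheme — CSF space
  (id 1), gray matter (2), white matter (3), ventricles (4) — between
  the target's coarse map and the atlas's coarse map.
* **LV** uses the ventricle-class Dice alone.
* **MI** compares intensities directly. With $H(I) = -\sum_i P(i)
  \log_2 P(i)$ the entropy of the voxel-intensity histogram, the score
  is the normalized mutual information
  $\mathrm{MI}(I_A, I_B) = \bigl(H(I_A) + H(I_B)\bigr) / H(I_A, I_B)$,
  which lies in $[1, 2]$: 1 for independent images, 2 for identical
  ones. This quotient form (rather than the Shannon difference
  $H(A)+H(B)-H(A,B)$) is implemented deliberately; it is the standard
  overlap-normalised variant and is scale-bounded, which makes scores
  comparable across targets.
* **random** is a seeded uniform baseline.

Scores are sorted descending; exact ties break by ascending atlas id, so
rankings are reproducible regardless of library order. When the target
is itself a library member it is excluded from its own candidate pool
(leave-one-out), mirroring how such libraries are validated.

Decisions where the convention was genuinely open:

* *4L aggregation.* The mean of the four per-label Dices is unweighted.
  A volume-weighted mean would be dominated by white matter and nearly
  ignore the ventricles, defeating the purpose of including them.
* *Empty-empty Dice.* If a structure is absent from both maps the pair
  agrees, so the Dice is defined as 1.0 (with a warning); absent from
  exactly one, 0.0. At evaluation time, structures absent from the
  *truth* are instead dropped from means — scoring an absent structure
  is not meaningful.
* *MI domain.* Whole-grid by default, i.e. including background, which
  corresponds to ranking on whole-head images; a mask argument exists
  for skull-stripped use.
* *Histogram bins.* 64 equal-width bins per axis (marginals over each
  volume's own range; the joint histogram's margins are used as the
  marginals so the estimator is internally consistent and the $[1,2]$
  bounds hold exactly). Bin count is exposed because MI values depend
  on it.

## The fast coarse segmentation

The 4L/LV criteria need a 7-label coarse map of the target before any
atlas is touched. `quickCoarseSegment()` provides an atlas-free
estimate: Otsu threshold → largest 6-connected component →
morphological closing → interior-cavity filling gives the brain mask;
seeded 3-class k-means on in-mask intensities gives CSF/GM/WM by
ascending mean (T1-like contrast; a flag reverses the order for
T2-like images); CSF-class connected components that do not touch the
mask boundary are relabelled as ventricles. Every voxel receives
exactly one hard label; no partial-volume model is attempted. Skull-base
and skin classes are not estimated from raw intensities — they require
a head model the package does not have.

If a coarse map already exists (for instance from a production
pipeline's own 7-label step), pass it directly: the bypass is the
recommended path, and `runSweep(coarse = "truth")` exercises it.

## The phantom generator

`makePhantom()` builds a brain-like head as nested spherical shells —
white-matter core, cortical gray shell, surrounding CSF shell, skin
shell — plus paired lateral-ventricle ellipsoids, a third-ventricle
proxy, one hippocampus proxy per temporal region, and a skull-base
blob: twelve fine structures. The coarse map is a deterministic
projection of the fine map. Intensity is

$$I(x) = \mu_{c(x)} \bigl(1 + \alpha\, q(x)\bigr) + \varepsilon(x),$$

with $\mu_c$ the class mean, $q$ a separable quadratic bias field
normalised to $[-1, 1]$, $\alpha$ the bias amplitude and
$\varepsilon \sim N(0, \sigma^2)$ seeded noise. The quadratic bias is
the simplest smooth field that defeats a single global threshold, which
is why the segmenter clusters rather than thresholds tissue.

Defaults, with rationale:

| Parameter | Default | Why |
|---|---|---|
| grid | 40×40×40 voxels, 1 mm | smallest grid on which all twelve structures are several voxels across |
| brain radius / cortex / CSF shell | 14 / 3 / 2 mm | proportions of a head, miniaturised |
| ventricle semiaxes, offset | (2.8, 2.2, 2.2) mm at ±(4.5, 0, 1.5) | paired, strictly inside white matter at every library scale |
| class means (0–6) | 0, 50, 70, 110, 45, 10, 12 | T1-like ordering CSF < GM < WM; ventricle ≈ CSF (same fluid); skull-base/skin subdued, emulating partially stripped images so the intensity histogram separates head tissue from background cleanly |
| noise sd | 2 | 5 % of the 40-unit GM–WM gap, a benign but non-trivial noise level |
| bias amplitude | 0.1 | ±10 % smooth shading, typical of uncorrected field bias |
| ventricle scale range | 0.7–1.5 | a ~10× ventricle-volume spread across the library, the realistic range of an aging cohort and the trait pre-selection is supposed to key on |
| cortex jitter | ±0.8 mm uniform | inter-individual cortical-thickness variation; this is the generator's member-independent variability, and it must be large enough that even the best-matching atlas is imperfect — otherwise multi-atlas fusion would have nothing to average away |

`makeLibrary()` draws the ventricle scales *evenly spaced*, not
random, so selection-recovery experiments have a known unique answer;
synthetic ages increase with ventricle scale, splitting the library
into "adult" and "geriatric" groups at 60. Everything is bit-reproducible
from the spec seed.

What the phantoms do **not** emulate: cortical folding, lesions,
partial-volume voxels, multi-site intensity differences, and — most
importantly — registration error, since all phantoms share one voxel
grid. Tests passing on phantoms therefore validate the selection,
fusion and evaluation *machinery* and the ranking's ability to recover
known anatomical orderings; they do not predict absolute accuracy on
clinical data.

## Fusion and evaluation

`fuseLabels()` votes per voxel: majority, or weighted by the selection
scores. Ties go to the lowest label id, making the result independent
of atlas order. No deformable registration is performed; inputs must
share a grid exactly, and mixed grids are a hard error rather than a
silent resample.

Evaluation aggregates fine labels through a hierarchy table to Level A
(4 hemispheric tissue ROIs), Level B (26 lobar/white-matter ROIs) and
Level C (33 fine ROIs) — 63 names in total, packaged in
`inst/extdata/roi_sets_level_abc.tsv` (the legacy spelling
"Hippocampu_R" is normalised to "Hippocampus_R" on load, with a
message). The hierarchy must be a tree: each named Level-C structure
has exactly one Level-B parent value (possibly none — the ventricle
ROIs have no lobar parent), and each Level-B exactly one Level-A value.
Per-structure Dice, the poor-outcome ratio (fraction of Dice < 0.7,
configurable) and paired two-sided t tests on per-target means complete
the harness. `runSweep()` crosses methods with subset sizes
{5, 10, 15, 20, 25} — 20 subsets per target with the default four
methods — and is deterministic given its seed; subset sizes beyond the
candidate pool saturate to the full pool.

The test suite and the acceptance script run the harness at the sizes
above: 40³-voxel phantoms, 20-atlas libraries, five leave-one-out
targets, five replicate seeds. These sizes keep every experiment
reproducible on a laptop while leaving each structure large enough
(tens to thousands of voxels) for Dice to be meaningful.

## Known limitations

* **Accuracy does not rise with *k* here.** On phantom sweeps the
  selection methods' mean Level-C Dice *falls* as more atlases are
  fused (e.g. 4L ≈ 0.88 at k = 5 versus ≈ 0.78 at saturation in the
  default acceptance run), while the random baseline rises toward the
  same saturation point. This is a structural property of
  registration-free voting: over nested ventricle shapes the vote
  consensus is the subset's median anatomy, which drifts from the
  target toward the library median as *k* grows — precisely when the
  top-ranked subset was a good match. In production pipelines, where
  each atlas is deformably registered to the target before voting,
  adding atlases mainly averages away independent registration error,
  and accuracy grows with *k*. The package reproduces the
  selection-benefit finding (4L/LV beat random decisively at small
  *k*, with lower poor-outcome ratios); it cannot, by design, reproduce
  the fusion-scaling benefit.
* The coarse segmenter assumes a T1-like (or, flagged, T2-like)
  monotone tissue ordering and a head whose non-brain tissue is darker
  than brain tissue; bias-field estimation and histogram matching are
  out of scope.
* The packaged hierarchy covers the phantom's twelve proxy structures.
  Real atlas sets need a user-supplied fine-id → Level A/B/C table.
* `selectRandom()` errors when k exceeds the pool (the honest
  contract); only `runSweep()` clamps, because a sweep grid fixed at
  {5,…,25} must remain runnable on smaller libraries.
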