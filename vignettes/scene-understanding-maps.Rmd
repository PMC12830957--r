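---
title: "Scene Understanding Maps and task-dependent fixation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scene Understanding Maps and task-dependent fixation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesum)
```

## The problem

Where people look in a natural scene depends on what they are doing.
Classic saliency models predict fixations from low-level image
features; meaning maps predict them from crowd-rated local
informativeness. Neither distinguishes two photographs that are almost
pixel-identical but *mean* different things. gazesum implements an
analysis framework built around that contrast: **Winograd scene
pairs** — two nearly identical images whose small difference changes
the interpretation — and **Scene Understanding Maps (SUMs)**, which
score each object by how much its removal changes observers'
descriptions of the scene.

The framework covers four viewing tasks run as a between-subject
design: free viewing (FV), scene description (SD), object search (OS)
and counting objects (CO). The working hypothesis is that free-viewing
fixations resemble description-driven fixations (both guided by scene
understanding) and differ from search- or counting-driven fixations.

## The SUM model

For one scene with elements $o = 1..K$, raters judge the similarity
$r_{o,j} \in \{1..10\}$ (10 = highly similar) between the gold-standard
description of the intact scene and a description of the scene with
element $o$ removed. The per-element impact score is

$$\hat s_o = \frac{\mathrm{med}_j(11 - r_{o,j}) - \min_{o'} \mathrm{med}_j(11 - r_{o',j})}
                  {\max_{o'}\left[\mathrm{med}_j(11 - r_{o',j}) - \min_{o''} \mathrm{med}_j(11 - r_{o'',j})\right]}$$

i.e. scale-inverted ratings, the median across raters, shifted so the
lowest element sits at 0 and scaled so the highest sits at 1. The map
renders each $\hat s_o$ as a 2D Gaussian centred on the element's
bounding box with amplitude $\hat s_o$ and axis SDs equal to 0.29
(horizontal) and 0.34 (vertical) times the box dimensions, clamped to
0.5–1.5 degrees of visual angle (dva). A flat per-box variant
(`box_map`) assigns $\hat s_o$ uniformly inside the box.

Design choices where the procedure was genuinely open:

* **Inversion.** `11 - r` keeps the 1–10 range; any affine inversion
  yields identical normalized scores, so the choice is
  presentation-only. Inverting before the median equals inverting
  after it for the midpoint median convention used.
* **Overlapping Gaussians** combine by pixelwise *maximum* by default,
  which preserves the amplitude-equals-score reading at each element's
  centre; a `combine = "sum"` switch accumulates mass instead (the
  synthetic generative densities use the sum form, since a probability
  field should add mass).
* **The 0.5–1.5 dva SD range** is implemented as a clamp, configurable
  off (`sd_clamp = NULL`), since treating it as merely an observed
  range would make tiny or huge boxes degenerate.
* **Degenerate tables** (all elements rated identically) give all-zero
  scores and a flat map with a warning rather than an error.
* **Ties** for the top score resolve to the lowest element id, with a
  warning — deterministic reruns matter more than any particular
  tie-break.

Categories follow from the SUM: the **SU-relevant** object of a scene
is its score argmax; the **SU-irrelevant** object is the pair-mapped
partner of the *other* scene's SU-relevant object, so the same physical
objects swap categories across a Winograd pair and low-level properties
are controlled. Objects scoring low in both scenes belong to neither
category.

## Viewing geometry and heat maps

All sizes specified in dva are converted through a `viewing_geometry`
(default: a 26.6° × 21.8° screen at 1280 × 1024 px, 75 cm). Horizontal
and vertical pixels-per-degree are kept separate (48.12 vs 46.97
px/deg); where a single isotropic scale is required (the 0.5-dva
fixation kernel would still be per-axis, but the 2-dva circular patch
radius cannot be), the mean of the two axis scales is used.

Fixation heat maps deposit each fixation as an impulse at its nearest
pixel — weight 1 (`count`) or its duration (`duration`) — and convolve
with a Gaussian kernel of SD 0.5 dva per axis. The kernel is truncated
at the image border without renormalization, standard blur semantics,
so total mass equals total weight up to boundary loss. Pearson
correlation between maps is computed over pixels excluded by neither
mask; because Pearson is invariant to linear rescaling, whether maps
are normalized first is moot.

Two open points resolved here:

* **The trial-initial central fixation** is excluded by default
  (`exclude_initial_central = TRUE`): it is enforced by the procedure
  and carries no selection information. It is configurable because the
  choice is not dictated by the design; cumulative-fixation curves keep
  all indices, since "first fixation" is meaningful there.
* **Fixations outside the image region** are clipped to the nearest
  image pixel and flagged with a warning rather than dropped.

People in the scenes are handled both ways the analyses require:
dropping fixations that land on person boxes before counting
(frequency analyses) and masking person pixels out of correlation
supports (map analyses); both are explicit flags, and person-inclusive
reruns simply leave both off.

## Evaluation statistics

* **Across-condition correlations** pool random non-repeating
  subgroups of `n_sub` observers per condition (study value 12, 1000
  draws), correlate the two pooled maps per image, and average across
  images. The within-condition variant splits one condition's
  observers into two disjoint groups of 12 — the inter-observer
  ceiling. Per-image correlations are raw-averaged (a Fisher-z option
  was considered and left out of the default because the reported
  quantity is a mean of many moderate r values, where the difference
  is negligible relative to resampling noise).
* **Winograd-pair correlations** correlate the two images' maps within
  each pair; the control re-pairs images uniformly at random excluding
  true partners.
* **Shuffled AUC** scores a prediction map by how well its values
  separate an observer's fixations on an image from the same
  observer's fixations on *other* images, which discounts centre bias.
  The default implementation is the exact Mann–Whitney rank statistic
  $P(\mathrm{pred}_{pos} > \mathrm{pred}_{neg}) + \tfrac12 P(=)$; a
  threshold-sweep mode exists and is provably identical (the test
  suite checks agreement to 1e-9), so no discretization error enters.
* **Category fixation frequencies** count fixations (or sum durations)
  per trial inside each category's boxes; a category holding several
  objects reports the mean over its objects; a fixation inside
  overlapping boxes goes to the smallest box only. Counts are
  reported, not proportions (a proportion option exists via the raw
  table).
* **Cumulative difference curves** report, for fixation index
  $k = 1..K$, the mean cumulative count on the SU-relevant minus the
  SU-irrelevant category, $\Delta CF(k)$.
* **Prediction-map tops** are extracted by convolving the map with a
  uniform, normalized circular patch of 2 dva diameter and taking the
  argmax; a peak outside every box yields a synthetic box with the
  scene's mean box dimensions.

## Description scoring

Embeddings are opaque numeric vectors supplied as files; the package
never calls an embedding API. Scores are plain cosines. Correctness
classification marks an observer incorrect when their similarity to
the gold standard falls below `mean − k·SD` of that scene's scores
(sample SD; `k` defaults to 1, the explored range is 0–2.5). The
mean/SD are computed **per scene** — pooling across scenes would mix
scenes with different baseline describability — with a `pool_scenes`
flag for the pooled variant. The upper similarity bound is the mean
pairwise cosine among each scene's five gold descriptions; the lower
bound is the mean cosine between a scene's gold description and
candidates drawn from other scenes (1000 random draws).

## Inference

Uncertainty comes from hierarchical bootstrap resampling with
replacement over the declared units (images and/or participants;
study defaults 100,000 resamples for scalar statistics, 10,000 for map
correlations). The one-tailed p-value is the fraction of resamples on
the null side of zero, floored at $1/(B+1)$ so zero is never reported;
the tested direction is declared in the configuration, never inferred
from the data. CIs are percentile (68% by default, matching the error
bars the analyses use); BCa was considered and not implemented since
no reported quantity depends on the refinement. Cohen's d uses the
pooled-variance definition. FDR control is Benjamini–Hochberg, with
Benjamini–Yekutieli for the serially dependent cumulative-fixation
comparisons; both delegate to `stats::p.adjust` and are verified
against a brute-force step-up implementation in the test suite.

## The synthetic-data generator

Every analysis stage is exercised end to end on synthetic data whose
structure mirrors the study: 18 Winograd pairs (36 images) in two
stimulus sets, 5–10 objects plus one person region per scene, four
between-subject conditions with 25 observers per image, 2-s trials
emulated as 9 fixations (the per-trial fixation count is not a
reported quantity; 9 is an assumption exposed as a parameter), 18
raters per removed element, five gold descriptions and 15
forced-fixation observers per group per scene.

The generative model:

* **Impacts.** Each pair draws one high-impact object (0.80–0.92), its
  partner low (0.02–0.10), the rest mid-range (0.20–0.50), swapped
  across the pair; the person's impact is drawn at 0.95–1.00 so people
  are typically the most critical element, as scenes built around
  actors make plausible. The high/person separation is chosen so the
  ordering survives the integer rating channel (ratings near the scale
  floor compress differences).
* **Ratings.** `round(clip(10 − 9·impact + N(0, noise_sd), 1, 10))`
  with `noise_sd = 1` by default — enough noise that medians matter,
  little enough that 18 raters recover the ranking (Spearman > 0.9).
* **Densities.** FV and SD share a people-inclusive, impact-weighted
  Gaussian-mixture density with a 10% uniform exploration floor; OS is
  a 0.3-dva Gaussian on the search target; CO spreads equal mass
  across object boxes (equal *per box*, not per pixel, so box area
  does not systematically favour either SU category under the null).
  Trials start at the screen centre; later fixations are i.i.d. draws
  from the density plus a per-observer jitter of SD 0.3 dva, which
  keeps inter-observer correlations below 1 as real data show.
  Durations are LogNormal with median 250 ms.
* **Embeddings.** Each scene has a latent gold direction; a removal
  description's cosine to it is `1 − impact·spread` (spread 0.8) plus
  angular noise, so dissimilarity grows monotonically with impact.
  Forced-fixation candidates sit at cosine 0.80 (relevant) and 0.50
  (irrelevant).
* **Geometry.** The generator ties its `viewing_geometry` to the scene
  grid — the grid spans the 26.6° × 21.8° field — so dva-specified
  parameters scale with grid resolution and analyses are
  resolution-invariant. Tests and the acceptance script use a
  320 × 256 grid, which keeps a full 36-image, four-condition study
  to seconds; the default generator grid is 640 × 512.

What the generator deliberately does **not** emulate: photographic
content, saccade dynamics (main-sequence velocities, undershoot),
centre bias beyond the initial fixation, temporal dependence between
successive fixations, semantic structure in descriptions, or rater
individual differences. Passing tests therefore show that the
*analysis machinery* recovers known structure under the study's
design, not that the scientific claims hold for real scenes.

## Problem sizes used by the tests

Unit tests run on 1–3 pairs at 160 × 128 or 200 × 160 grids. The
end-to-end checks run 20 replicates of the full design (18 pairs,
25 observers per image, 320 × 256) and require each qualitative
ordering — FV–SD > FV–CO > FV–OS map correlations; Winograd
correlations below a pair-shared surrogate; SU-relevant > SU-irrelevant
frequency for FV/SD with one-tailed bootstrap p < .05 and no such
difference under CO; ΔCF(k) increasing; forced-fixation-relevant
descriptions outscoring irrelevant ones — to hold in at least 95% of
replicates. Bootstrap calibration is checked by 500 null simulations
at B = 1000, with the one-tailed rejection rate at p < .05 required to
lie in [0.03, 0.07].

## Known limitations

* SUM construction assumes rectangular, mostly non-overlapping object
  annotations; heavily nested boxes make the smallest-box fixation
  assignment rule load-bearing.
* The rank-based sAUC treats prediction values at fixation pixels
  only; maps with large flat plateaus get credit 0.5 on ties, which is
  correct but can hide a coarse map's weakness.
* The bootstrap treats observers and images as exchangeable units;
  observer-by-image interactions are resampled only implicitly.
* Percentile CIs can undercover for strongly skewed statistics at
  small n; the 68% default matches the error-bar convention, not a
  coverage guarantee.
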