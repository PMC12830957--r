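# gazesum

Analysis tools for task-dependent eye movements and **Scene
Understanding Maps (SUMs)** — for researchers in visual cognition who
want to ask not just *where* people look in a scene, but whether they
look at the objects that carry the scene's meaning.

## The idea

A SUM scores every annotated object in a scene by how much deleting it
changes observers' descriptions of the scene. Raters judge the
similarity (1–10, 10 = highly similar) between the gold-standard
description of the intact scene and descriptions of the scene with one
object removed. Per object *o* with ratings *r*<sub>*o,j*</sub>:

    s_o = [ med_j(11 − r_oj) − min_o' med_j(11 − r_o'j) ] / max_o'[ ... ]

— scale-inverted, median across raters, shifted so the least impactful
object is 0 and scaled so the most impactful is 1. Scores are rendered
as 2D Gaussians centred on each object's bounding box (amplitude =
score; SD = 0.29/0.34 of the box width/height, clamped to 0.5–1.5
degrees of visual angle).

Around that core the package provides:

- **Winograd scene pairs** — nearly identical images with swapped
  SU-relevant/irrelevant objects — as a first-class data structure;
- smoothed **fixation heat maps** (0.5-dva Gaussian kernel, count- or
  duration-weighted, with people-region exclusion at the fixation or
  the pixel level);
- across-condition, within-condition (inter-observer) and
  Winograd-pair **map correlations**;
- **shuffled AUC** evaluation of any prediction map (exact rank
  statistic, with an equivalent threshold-sweep mode);
- per-category **fixation frequencies** and cumulative
  **ΔCF(k)** curves;
- embedding-based **description scoring** (cosine similarity, gold
  standards, correctness classification, upper/lower similarity
  bounds);
- hierarchical **bootstrap** inference with one-tailed p-values,
  Cohen's d, and **BH/BY** false-discovery-rate control;
- a **synthetic-data generator** reproducing the study design
  (18 Winograd pairs × 2 sets, 4 between-subject viewing conditions ×
  25 observers per image, ~9 fixations per 2-s trial, 18 raters per
  removed object) so the full pipeline is testable without any
  collected data.

## Worked example

```r
library(gazesum)

# a synthetic two-pair study: scenes, fixations (4 conditions),
# rating tables and description embeddings
d <- simulate_study(n_pairs = 2, n_observers = 25, grid = c(320L, 256L),
                    seed = 42)

# SUM for one scene from its rating table
sc  <- d$scenes[["pair01_img1"]]
tab <- d$ratings[d$ratings$scene_id == "pair01_img1", ]
scores <- aggregate_ratings(tab, sc, include_people = FALSE)
round(scores, 3)
#> pair01_img1_e01 pair01_img1_e02 pair01_img1_e03 pair01_img1_e04 pair01_img1_e05
#>           1.000           0.286           0.286           0.000           0.571
#> pair01_img1_e06
#>           0.429
s <- build_sum(sc, scores, geometry = d$geometry)
s
#> <sum_map> pair01_img1: 6 scored elements (max pair01_img1_e01)
```

Object `e01` scored 1: removing it changed descriptions the most, so
it is this scene's SU-relevant object. Categories swap across the
Winograd pair, and fixation analyses follow:

```r
fv <- d$trials[d$trials$condition == "FV" &
                 d$trials$image_id == "pair01_img1", ]
hm <- build_heatmap(fv, sc, d$geometry)   # 0.5-dva kernel, 25 observers
sd_tr <- d$trials[d$trials$condition == "SD" &
                    d$trials$image_id == "pair01_img1", ]
heatmap_correlation(hm, build_heatmap(sd_tr, sc, d$geometry))
#> [1] 0.8161883            # free viewing resembles scene description
heatmap_correlation(hm, s$heat_map)
#> [1] 0.6110574            # ...and the SUM predicts free viewing
```

The free-viewing map correlates strongly with the scene-description
map and with the SUM itself; per-category counts show the SU-relevant
object drawing far more fixations (1.64 vs 0.00 mean fixations per
trial in this scene). `bootstrap_statistic()` attaches one-tailed
resampling p-values and `fdr_adjust()` corrects families of such
comparisons. `run_pipeline()` chains every stage and writes tidy CSV
results plus a manifest with config and result hashes.

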