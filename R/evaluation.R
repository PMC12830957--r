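# Comparison statistics: heat-map correlations (across conditions,
# across Winograd pairs, inter-observer split-half), shuffled AUC,
# category fixation frequencies, and cumulative-difference curves.

#' Pearson correlation between two heat maps
#'
#' Computed over the pixels excluded by neither map's mask. Pearson is
#' the field's convention for fixation-map similarity and is invariant
#' to any linear rescaling of either map, so prior normalization is
#' irrelevant.
#'
#' @param h1,h2 [heat_map()] objects on the same grid.
#' @return Scalar correlation in \[-1, 1\].
#' @export
heatmap_correlation <- function(h1, h2) {
  if (!identical(dim(h1$values), dim(h2$values))) {
    stopf("heat maps are on different grids")
  }
  keep <- rep(TRUE, length(h1$values))
  if (!is.null(h1$mask)) keep <- keep & !as.vector(h1$mask)
  if (!is.null(h2$mask)) keep <- keep & !as.vector(h2$mask)
  a <- as.vector(h1$values)[keep]
  b <- as.vector(h2$values)[keep]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("correlation undefined: fewer than 2 unmasked pixels or zero variance")
  }
  stats::cor(a, b)
}

#' Across- and within-condition heat-map correlations
#'
#' For each of `n_combos` draws, pools a random `n_sub`-observer subset
#' per condition (non-repeating observers within a draw), builds the
#' two pooled heat maps per image, correlates them, and averages across
#' images. The within-condition variant (`conditions` of length 1)
#' splits one condition's observers into two disjoint groups of
#' `n_sub`, giving the inter-observer ceiling.
#'
#' @param trials Fixation data.frame covering both conditions.
#' @param scenes Named list of [scene_spec()] objects.
#' @param conditions One condition label (within) or two (across).
#' @param geometry,config Passed to [build_heatmap()].
#' @param n_sub Observers per subgroup (study default 12).
#' @param n_combos Number of random subgroup draws (study default 1000).
#' @param seed Integer seed.
#' @return List with `mean_r`, `combo_r` (one mean-over-images r per
#'   draw) and `per_image_r` (images x combos matrix).
#' @export
condition_pair_correlation <- function(trials, scenes, conditions,
                                       geometry = viewing_geometry(),
                                       config = heatmap_config(),
                                       n_sub = 12L, n_combos = 100L,
                                       seed = 1L) {
  within <- length(conditions) == 1L
  if (!within && length(conditions) != 2L) {
    stopf("conditions must name one (within) or two (across) conditions")
  }
  obs_by_img_cond <- function(img, cond) {
    unique(trials$observer_id[trials$image_id == img & trials$condition == cond])
  }
  imgs <- names(scenes)
  per_image <- matrix(NA_real_, length(imgs), n_combos,
                      dimnames = list(imgs, NULL))
  with_seed(seed, {
    for (k in seq_len(n_combos)) {
      for (i in seq_along(imgs)) {
        img <- imgs[i]
        tr <- trials[trials$image_id == img, , drop = FALSE]
        if (within) {
          obs <- obs_by_img_cond(img, conditions[1L])
          if (length(obs) < 2L * n_sub) {
            stopf("within-condition split needs >= %d observers on '%s'",
                  2L * n_sub, img)
          }
          pick <- sample(obs, 2L * n_sub)
          g1 <- pick[seq_len(n_sub)]
          g2 <- pick[n_sub + seq_len(n_sub)]
          h1 <- pooled_heatmap(tr[tr$condition == conditions[1L], ], g1,
                               scenes[[img]], geometry, config)
          h2 <- pooled_heatmap(tr[tr$condition == conditions[1L], ], g2,
                               scenes[[img]], geometry, config)
        } else {
          maps <- lapply(conditions, function(cond) {
            obs <- obs_by_img_cond(img, cond)
            if (length(obs) < n_sub) {
              stopf("condition '%s' has fewer than %d observers on '%s'",
                    cond, n_sub, img)
            }
            pick <- sample(obs, n_sub)
            pooled_heatmap(tr[tr$condition == cond, ], pick,
                           scenes[[img]], geometry, config)
          })
          h1 <- maps[[1L]]; h2 <- maps[[2L]]
        }
        per_image[i, k] <- heatmap_correlation(h1, h2)
      }
    }
  })
  combo_r <- colMeans(per_image)
  list(mean_r = mean(combo_r), combo_r = combo_r, per_image_r = per_image,
       conditions = conditions, n_sub = n_sub)
}

#' Heat-map correlation across Winograd pairs
#'
#' Correlates the two images' maps within each pair. With
#' `random_control = TRUE` the pairing is instead drawn uniformly at
#' random among images (excluding true pairs), giving the chance-level
#' control distribution.
#'
#' @param pairs List of [winograd_pair()].
#' @param maps Named list (by image_id) of [heat_map()] objects.
#' @param random_control Re-pair images at random?
#' @param n_random Number of random pairings when `random_control`.
#' @param seed Seed for the random control.
#' @return List with `mean_r` and `pair_r` (named per pair, or one
#'   entry per random pairing).
#' @export
winograd_correlation <- function(pairs, maps, random_control = FALSE,
                                 n_random = 100L, seed = 1L) {
  for (pr in pairs) {
    da <- dim(maps[[pr$scene_a$image_id]]$values)
    db <- dim(maps[[pr$scene_b$image_id]]$values)
    if (!identical(da, db)) stopf("grid mismatch within pair '%s'", pr$pair_id)
  }
  if (!random_control) {
    pair_r <- vapply(pairs, function(pr) {
      heatmap_correlation(maps[[pr$scene_a$image_id]],
                          maps[[pr$scene_b$image_id]])
    }, numeric(1L))
    names(pair_r) <- vapply(pairs, function(pr) pr$pair_id, character(1L))
  } else {
    partner <- unlist(lapply(pairs, function(pr) {
      stats::setNames(c(pr$scene_b$image_id, pr$scene_a$image_id),
                      c(pr$scene_a$image_id, pr$scene_b$image_id))
    }))
    imgs <- names(partner)
    same_dim <- function(a, b) identical(dim(maps[[a]]$values), dim(maps[[b]]$values))
    pair_r <- with_seed(seed, vapply(seq_len(n_random), function(k) {
      a <- sample(imgs, 1L)
      pool <- setdiff(imgs, c(a, partner[[a]]))
      pool <- pool[vapply(pool, same_dim, logical(1L), a = a)]
      if (!length(pool)) stopf("no compatible image to re-pair with '%s'", a)
      b <- if (length(pool) == 1L) pool else sample(pool, 1L)
      heatmap_correlation(maps[[a]], maps[[b]])
    }, numeric(1L)))
  }
  list(mean_r = mean(pair_r), pair_r = pair_r, random_control = random_control)
}

#' Shuffled AUC of a prediction map
#'
#' Discrimination of an observer's fixations (positives) from the same
#' observer's fixations on other images (negatives) by the prediction
#' map's values. The default `"rank"` mode uses the exact Mann-Whitney
#' rank formulation `P(pred(pos) > pred(neg)) + 0.5 P(equal)`;
#' `"sweep"` traces the TP-vs-FP curve over thresholds at every
#' distinct map value and integrates by trapezoid — the two are
#' provably identical.
#'
#' @param prediction A [heat_map()].
#' @param positives,negatives Data.frames with `x_px`, `y_px` columns;
#'   the sets must have equal size.
#' @param mode `"rank"` or `"sweep"`.
#' @return Scalar sAUC in \[0, 1\].
#' @export
sauc <- function(prediction, positives, negatives, mode = c("rank", "sweep")) {
  mode <- match.arg(mode)
  if (nrow(positives) == 0L) stopf("positive set is empty")
  if (nrow(negatives) != nrow(positives)) {
    stopf("negative set must have the same size as the positive set")
  }
  val_at <- function(df) {
    h <- nrow(prediction$values); w <- ncol(prediction$values)
    xi <- floor(df$x_px); yi <- floor(df$y_px)
    if (any(xi < 0 | xi >= w | yi < 0 | yi >= h)) {
      stopf("fixation outside the prediction grid")
    }
    prediction$values[yi + 1L + xi * h]
  }
  p <- val_at(positives); n <- val_at(negatives)
  if (mode == "rank") {
    cmp <- outer(p, n, ">") + 0.5 * outer(p, n, "==")
    mean(cmp)
  } else {
    thr <- sort(unique(c(p, n)), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(t) mean(p >= t), numeric(1L)))
    fpr <- c(0, vapply(thr, function(t) mean(n >= t), numeric(1L)))
    sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  }
}

#' Sample an observer's negative fixation set
#'
#' Negatives are the observer's own fixations on *other* images, which
#' preserves that observer's spatial biases (centre bias) under the
#' shuffled-AUC logic. Samples with replacement (with a warning) if
#' more are requested than exist.
#'
#' @param trials Full fixation data.frame.
#' @param observer,image The observer/image whose positives are tested.
#' @param n Number of negatives (must equal the positive count).
#' @param seed Integer seed.
#' @return A data.frame of `n` fixations.
#' @export
build_negative_sets <- function(trials, observer, image, n, seed = 1L) {
  pool <- trials[trials$observer_id == observer & trials$image_id != image, ,
                 drop = FALSE]
  if (nrow(pool) == 0L) {
    stopf("observer '%s' has no fixations on other images", observer)
  }
  with_seed(seed, {
    if (n > nrow(pool)) {
      warnf("requested %d negatives but only %d available; sampling with replacement",
            n, nrow(pool))
      pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
    } else {
      pool[sample.int(nrow(pool), n), , drop = FALSE]
    }
  })
}

# Assign each fixation to the element whose box contains it; when boxes
# overlap the smallest-area box wins (specific beats general). Returns
# element_id or NA.
assign_fixations_to_elements <- function(fx, scene, include_people = TRUE) {
  els <- if (include_people) scene$elements else scene_objects(scene)
  out <- rep(NA_character_, nrow(fx))
  if (!length(els) || nrow(fx) == 0L) return(out)
  areas <- vapply(els, box_area, numeric(1L))
  best <- rep(Inf, nrow(fx))
  n_overlap <- 0L
  for (eid in names(els)) {
    inside <- point_in_box(fx$x_px, fx$y_px, els[[eid]])
    n_overlap <- n_overlap + sum(inside & !is.na(out))
    take <- inside & areas[[eid]] < best
    out[take] <- eid
    best[take] <- areas[[eid]]
  }
  if (n_overlap > 0L) {
    warnf("%d fixations fell in overlapping boxes; assigned to the smallest box",
          n_overlap)
  }
  out
}

#' Per-observer fixation frequency by object category
#'
#' Counts fixations (or sums their durations) landing inside each
#' category's boxes, per trial. A category holding several objects
#' reports the mean over its objects. Fixations in overlapping boxes go
#' to the smallest box only, never double-counted.
#'
#' @param trials Fixation data.frame for one scene.
#' @param scene The [scene_spec()].
#' @param assignment One scene's entry from [assign_categories()], or
#'   any named list of category -> element_id vector.
#' @param weight_mode `"count"` or `"duration"`.
#' @param exclude_people Drop fixations on person-class boxes before
#'   counting (rather than reporting them under a `people` category)?
#' @param exclude_initial_central Drop each trial's first fixation?
#' @return Data.frame: `observer_id`, `category`, `value`.
#' @export
category_fixation_frequency <- function(trials, scene, assignment,
                                        weight_mode = c("count", "duration"),
                                        exclude_people = FALSE,
                                        exclude_initial_central = TRUE) {
  weight_mode <- match.arg(weight_mode)
  cats <- assignment_categories(assignment)
  fx <- trials
  if (exclude_initial_central && nrow(fx)) fx <- fx[fx$fix_index > 1L, , drop = FALSE]
  eid <- assign_fixations_to_elements(fx, scene, include_people = TRUE)
  person_ids <- names(scene_people(scene))
  if (exclude_people) {
    keep <- is.na(eid) | !eid %in% person_ids
    fx <- fx[keep, , drop = FALSE]
    eid <- eid[keep]
    cats <- cats[names(cats) != "people"]
  }
  wgt <- if (weight_mode == "duration") fx$duration_ms else rep(1, nrow(fx))
  observers <- unique(trials$observer_id)
  rows <- list()
  for (ob in observers) {
    sel <- fx$observer_id == ob
    for (cat in names(cats)) {
      members <- cats[[cat]]
      per_obj <- vapply(members, function(m) sum(wgt[sel & !is.na(eid) & eid == m]),
                        numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        observer_id = ob, category = cat,
        value = if (length(per_obj)) mean(per_obj) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Normalize an assignment into category -> character vector of elements.
assignment_categories <- function(assignment) {
  keep <- c("su_relevant", "su_irrelevant", "grasp_gaze", "search_target",
            "people", "most_critical")
  cats <- assignment[intersect(names(assignment), keep)]
  extra <- assignment[setdiff(names(assignment),
                              c(keep, "scene_id", "model_top"))]
  if (!is.null(assignment$model_top)) cats <- c(cats, assignment$model_top)
  cats <- c(cats, extra)
  cats <- Filter(function(x) !is.null(x) && length(x) > 0, cats)
  lapply(cats, as.character)
}

#' Cumulative fixation-difference curve
#'
#' For each fixation index k, the mean over trials of the number of
#' fixations 1..k landing on a category (CF), and the difference
#' between the SU-relevant and SU-irrelevant categories,
#' `delta_cf(k) = CF_rel(k) - CF_irr(k)`.
#'
#' @param trials Fixation data.frame for one scene (or several scenes
#'   if `scene` is a named list and trials carry matching `image_id`s).
#' @param scene A [scene_spec()] or named list of them.
#' @param assignments Named list (by image_id) from [assign_categories()].
#' @param K Maximum fixation index (default 10).
#' @param weight_mode `"count"` or `"duration"`.
#' @param categories Two category names to difference (default
#'   SU-relevant minus SU-irrelevant).
#' @return Data.frame with columns `k`, `cf_rel`, `cf_irr`, `delta_cf`.
#' @export
cumulative_difference_curve <- function(trials, scene, assignments, K = 10L,
                                        weight_mode = c("count", "duration"),
                                        categories = c("su_relevant",
                                                       "su_irrelevant")) {
  weight_mode <- match.arg(weight_mode)
  if (length(categories) != 2L) stopf("categories must name exactly two categories")
  scenes <- if (inherits(scene, "scene_spec")) {
    stats::setNames(list(scene), scene$image_id)
  } else scene
  if (inherits(assignments, "scene_spec") ||
      (!is.null(assignments$su_relevant))) {
    assignments <- stats::setNames(list(assignments), names(scenes)[1L])
  }
  # per-trial cumulative hits, padded with the final value past the
  # trial's last fixation
  per_trial <- function(fx, sc, asg) {
    eid <- assign_fixations_to_elements(fx, sc, include_people = TRUE)
    wgt <- if (weight_mode == "duration") fx$duration_ms else rep(1, nrow(fx))
    cats <- assignment_categories(asg)
    sapply(categories, function(cat) {
      members <- cats[[cat]] %||% character(0)
      cum <- numeric(K)
      for (k in seq_len(K)) {
        upto <- fx$fix_index <= k
        per_obj <- vapply(members, function(m) {
          sum(wgt[upto & !is.na(eid) & eid == m])
        }, numeric(1L))
        cum[k] <- if (length(per_obj)) mean(per_obj) else 0
      }
      cum
    })
  }
  acc <- array(0, c(K, 2L)); n_tr <- 0L
  for (img in unique(trials$image_id)) {
    sc <- scenes[[img]]
    if (is.null(sc)) stopf("no scene for image '%s'", img)
    asg <- assignments[[img]]
    if (is.null(asg)) stopf("no category assignment for image '%s'", img)
    tr <- trials[trials$image_id == img, , drop = FALSE]
    for (ob in unique(tr$observer_id)) {
      fx <- tr[tr$observer_id == ob, , drop = FALSE]
      acc <- acc + per_trial(fx, sc, asg)
      n_tr <- n_tr + 1L
    }
  }
  cf <- acc / max(n_tr, 1L)
  data.frame(k = seq_len(K), cf_rel = cf[, 1L], cf_irr = cf[, 2L],
             delta_cf = cf[, 1L] - cf[, 2L])
}
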