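# Scene Understanding Maps.
#
# A SUM scores each scene element by the impact of its removal on
# observers' scene descriptions, estimated from 1-10 similarity ratings
# between descriptions of the intact and element-removed scene. Scores
# are rendered as box-anchored 2D Gaussians.

#' SUM construction parameters
#'
#' @param fraction_x,fraction_y Box-size-to-Gaussian-SD fractions along
#'   x and y (defaults 0.29 and 0.34).
#' @param sd_clamp Two-element range in dva the per-element SDs are
#'   clamped to (default 0.5-1.5 dva); `NULL` disables clamping.
#' @param combine How overlapping element Gaussians are merged:
#'   `"max"` preserves amplitude = score at each element's centre;
#'   `"sum"` accumulates mass.
#' @param include_people Whether person-class elements enter the map.
#' @return A `sum_config` list.
#' @export
sum_config <- function(fraction_x = 0.29, fraction_y = 0.34,
                       sd_clamp = c(0.5, 1.5),
                       combine = c("max", "sum"),
                       include_people = FALSE) {
  if (fraction_x <= 0 || fraction_x >= 1 || fraction_y <= 0 || fraction_y >= 1) {
    stopf("fractions must lie in (0, 1)")
  }
  if (!is.null(sd_clamp)) {
    if (length(sd_clamp) != 2L || sd_clamp[1L] >= sd_clamp[2L] || sd_clamp[1L] <= 0) {
      stopf("sd_clamp must be c(low, high) with 0 < low < high")
    }
  }
  list(fraction_x = fraction_x, fraction_y = fraction_y,
       sd_clamp = sd_clamp, combine = match.arg(combine),
       include_people = include_people)
}

#' Aggregate removal-impact ratings into normalized scores
#'
#' Each rating is scale-inverted (`11 - r`, so dissimilar descriptions
#' score high), the per-element median is taken across raters, the
#' lowest element median is subtracted, and the result is divided by
#' the maximum shifted value. Output lies in \[0, 1\] with a maximum of
#' 1; if all elements tie, all scores are 0 (flat SUM) with a warning.
#'
#' @param table Data.frame with columns `rater_id`, `element_id`,
#'   `rating` (integers 1-10) for a single scene.
#' @param scene Optional [scene_spec()] used to identify person-class
#'   elements when `include_people = FALSE`.
#' @param include_people Keep person-class entries (requires `scene`)?
#' @return Named numeric vector of normalized impact scores.
#' @export
aggregate_ratings <- function(table, scene = NULL, include_people = TRUE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stopf("rating table is empty")
  }
  need <- c("rater_id", "element_id", "rating")
  if (!all(need %in% names(table))) {
    stopf("rating table must have columns %s", paste(need, collapse = ", "))
  }
  r <- table$rating
  if (any(!is.finite(r)) || any(r < 1 | r > 10) || any(r != floor(r))) {
    stopf("ratings must be integers in 1..10")
  }
  if (!include_people) {
    if (is.null(scene)) stopf("include_people = FALSE requires a scene")
    drop <- names(scene_people(scene))
    table <- table[!table$element_id %in% drop, , drop = FALSE]
    if (nrow(table) == 0L) stopf("no object-class ratings left after dropping people")
  }
  inv <- 11 - table$rating
  med <- tapply(inv, table$element_id, stats::median)
  shifted <- med - min(med)
  denom <- max(shifted)
  if (denom == 0) {
    warnf("all elements rated identically; returning a flat (all-zero) SUM")
    scores <- shifted * 0
  } else {
    scores <- shifted / denom
  }
  stats::setNames(as.numeric(scores), names(med))
}

# Shared Gaussian-mixture renderer: one 2D Gaussian per scored element,
# amplitude = score, SDs = clamp(fraction * box size). Used by both
# build_sum() and the synthetic generative densities.
gaussian_mixture_map <- function(scene, scores, config, geometry,
                                 combine = config$combine) {
  w <- scene$width_px; h <- scene$height_px
  vals <- matrix(0, h, w)
  # pixel j holds coordinate j-1, so integer box centres land on a sample
  xg <- seq_len(w) - 1
  yg <- seq_len(h) - 1
  for (eid in names(scores)) {
    s <- scores[[eid]]
    if (s <= 0) next
    e <- scene$elements[[eid]]
    if (is.null(e)) stopf("score refers to unknown element '%s'", eid)
    sd_px <- element_sd_px(e, config, geometry)
    ctr <- box_center(e)
    gx <- exp(-(xg - ctr[1L])^2 / (2 * sd_px[1L]^2))
    gy <- exp(-(yg - ctr[2L])^2 / (2 * sd_px[2L]^2))
    g <- s * outer(gy, gx)
    vals <- if (combine == "max") pmax(vals, g) else vals + g
  }
  vals
}

# Per-element Gaussian SDs in pixels; the dva clamp is converted
# per-axis before applying.
element_sd_px <- function(e, config, geometry) {
  sx <- config$fraction_x * box_width(e)
  sy <- config$fraction_y * box_height(e)
  if (!is.null(config$sd_clamp)) {
    lo_x <- deg_to_px(geometry, config$sd_clamp[1L], "horizontal")
    hi_x <- deg_to_px(geometry, config$sd_clamp[2L], "horizontal")
    lo_y <- deg_to_px(geometry, config$sd_clamp[1L], "vertical")
    hi_y <- deg_to_px(geometry, config$sd_clamp[2L], "vertical")
    sx <- min(max(sx, lo_x), hi_x)
    sy <- min(max(sy, lo_y), hi_y)
  }
  c(sx, sy)
}

#' Build a Scene Understanding Map
#'
#' Renders normalized impact scores as 2D Gaussians centred on each
#' element's bounding box (amplitude = score; SD = fraction of the box
#' size, clamped in dva), plus a flat per-box variant in which the
#' median-derived score fills the whole bounding box.
#'
#' @param scene A [scene_spec()].
#' @param scores Named numeric vector from [aggregate_ratings()].
#' @param config A [sum_config()].
#' @param geometry A [viewing_geometry()].
#' @return An object of class `sum_map`: `scene_id`, `element_scores`,
#'   `heat_map` and `box_map` (both [heat_map()] objects).
#' @export
build_sum <- function(scene, scores, config = sum_config(),
                      geometry = viewing_geometry()) {
  unknown <- setdiff(names(scores), names(scene$elements))
  if (length(unknown)) {
    stopf("scores refer to unknown elements: %s", paste(unknown, collapse = ", "))
  }
  if (!config$include_people) {
    scores <- scores[setdiff(names(scores), names(scene_people(scene)))]
  }
  vals <- gaussian_mixture_map(scene, scores, config, geometry)
  bvals <- matrix(0, scene$height_px, scene$width_px)
  for (eid in names(scores)) {
    e <- scene$elements[[eid]]
    xs <- seq.int(floor(e$box[1L]) + 1L, ceiling(e$box[3L]))
    ys <- seq.int(floor(e$box[2L]) + 1L, ceiling(e$box[4L]))
    bvals[ys, xs] <- pmax(bvals[ys, xs], scores[[eid]])
  }
  meta <- list(kind = "sum", include_people = config$include_people)
  structure(
    list(scene_id = scene$image_id,
         element_scores = scores,
         heat_map = heat_map(vals, meta = meta),
         box_map = heat_map(bvals, meta = c(meta, variant = "box"))),
    class = "sum_map")
}

#' @export
print.sum_map <- function(x, ...) {
  cat(sprintf("<sum_map> %s: %d scored elements (max %s)\n", x$scene_id,
              length(x$element_scores),
              if (length(x$element_scores)) names(which.max(x$element_scores)) else "none"))
  invisible(x)
}

#' Assign SU-relevance categories across a Winograd pair
#'
#' The SU-relevant object of a scene is its highest-scoring object; the
#' SU-irrelevant object is the pair-mapped partner of the *other*
#' scene's SU-relevant object, so the same physical objects swap
#' categories across the pair. Objects with low scores in both scenes
#' belong to neither category. Also records the perceived grasp/gaze
#' object (vote argmax), the search target, person-class elements, and
#' — when person-inclusive scores are supplied — the overall most
#' critical element.
#'
#' @param pair A [winograd_pair()].
#' @param sum_a,sum_b [build_sum()] results for the two scenes, scored
#'   with `include_people = FALSE`.
#' @param people_scores Optional list of two person-inclusive score
#'   vectors (scene_a, scene_b) used to fill `most_critical`.
#' @return Named list (by image_id) of `category_assignment` lists with
#'   fields `su_relevant`, `su_irrelevant`, `grasp_gaze`,
#'   `search_target`, `people`, `most_critical`.
#' @export
assign_categories <- function(pair, sum_a, sum_b, people_scores = NULL) {
  pick_max <- function(scores, what, scene_id) {
    if (!length(scores)) stopf("no scores for scene '%s'", scene_id)
    mx <- max(scores)
    hits <- sort(names(scores)[scores >= mx - 1e-12])
    if (length(hits) > 1L) {
      warnf("tie for %s in scene '%s'; taking lowest element_id", what, scene_id)
    }
    hits[1L]
  }
  sc_a <- pair$scene_a; sc_b <- pair$scene_b
  obj_a <- sum_a$element_scores[intersect(names(sum_a$element_scores),
                                          names(scene_objects(sc_a)))]
  obj_b <- sum_b$element_scores[intersect(names(sum_b$element_scores),
                                          names(scene_objects(sc_b)))]
  rel_a <- pick_max(obj_a, "SU-relevant", sc_a$image_id)
  rel_b <- pick_max(obj_b, "SU-relevant", sc_b$image_id)

  fmap <- pair$shared_object_map             # a -> b
  rmap <- stats::setNames(names(fmap), fmap) # b -> a
  irr_a <- rmap[[rel_b]] %||% stopf(
    "no pair correspondence for SU-relevant object '%s'", rel_b)
  irr_b <- fmap[[rel_a]] %||% stopf(
    "no pair correspondence for SU-relevant object '%s'", rel_a)

  one <- function(scene, rel, irr, scores_people) {
    gg <- NULL
    if (!is.null(scene$grasp_gaze_votes)) {
      v <- scene$grasp_gaze_votes
      gg <- pick_max(v, "grasp/gaze votes", scene$image_id)
    }
    mc <- NULL
    if (!is.null(scores_people)) {
      mc <- pick_max(scores_people, "most critical element", scene$image_id)
    }
    list(scene_id = scene$image_id, su_relevant = rel, su_irrelevant = irr,
         grasp_gaze = gg, search_target = scene$search_target_id,
         people = names(scene_people(scene)), most_critical = mc)
  }
  ps_a <- if (is.null(people_scores)) NULL else people_scores[[1L]]
  ps_b <- if (is.null(people_scores)) NULL else people_scores[[2L]]
  out <- list(one(sc_a, rel_a, irr_a, ps_a),
              one(sc_b, rel_b, irr_b, ps_b))
  stats::setNames(out, c(sc_a$image_id, sc_b$image_id))
}
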