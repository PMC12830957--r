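# Fixation heat maps.
#
# Fixations are deposited as impulses on the scene grid (weight 1 or
# their duration) and convolved with a Gaussian kernel whose SD is
# specified in dva. People regions can be excluded either by dropping
# the fixations that land on them or by masking the pixels out of
# later correlation supports.

#' Nonnegative 2D field on a scene grid
#'
#' The shared container for fixation heat maps, SUMs and externally
#' supplied prediction maps. `mask` marks excluded pixels (TRUE =
#' excluded), e.g. people regions.
#'
#' @param values Nonnegative numeric matrix (rows = y, cols = x).
#' @param mask Optional logical matrix of the same shape.
#' @param meta Optional list of provenance fields (kernel SD, source
#'   condition, n_observers, ...).
#' @return An object of class `heat_map`.
#' @export
heat_map <- function(values, mask = NULL, meta = list()) {
  if (!is.matrix(values) || any(values < 0) || any(!is.finite(values))) {
    stopf("heat map values must be a nonnegative finite matrix")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
      stopf("mask must be a logical matrix matching the values grid")
    }
  }
  structure(list(values = values, mask = mask, meta = meta),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> %d x %d px, mass %.4g%s\n", ncol(x$values),
              nrow(x$values), sum(x$values),
              if (is.null(x$mask)) "" else sprintf(", %d px masked", sum(x$mask))))
  invisible(x)
}

#' Heat-map construction parameters
#'
#' @param kernel_sd_deg Gaussian kernel SD in dva (default 0.5).
#' @param exclude_initial_central Drop each trial's first fixation (the
#'   enforced trial-start fixation carries no selection information)?
#' @param weight_mode `"count"` (each fixation weighs 1) or
#'   `"duration"` (weighs its duration in ms).
#' @param exclude_people_fixations Drop fixations landing on
#'   person-class boxes before counting?
#' @param mask_people Attach the people raster as the exclusion mask
#'   (removes those pixels from correlation supports)?
#' @return A `heatmap_config` list.
#' @export
heatmap_config <- function(kernel_sd_deg = 0.5,
                           exclude_initial_central = TRUE,
                           weight_mode = c("count", "duration"),
                           exclude_people_fixations = FALSE,
                           mask_people = FALSE) {
  if (kernel_sd_deg <= 0) stopf("kernel_sd_deg must be > 0")
  list(kernel_sd_deg = kernel_sd_deg,
       exclude_initial_central = exclude_initial_central,
       weight_mode = match.arg(weight_mode),
       exclude_people_fixations = exclude_people_fixations,
       mask_people = mask_people)
}

#' Build a smoothed fixation heat map
#'
#' Deposits each fixation as an impulse at its nearest pixel and
#' convolves with a per-axis Gaussian kernel (SD converted from dva).
#' The kernel is truncated at the image border without renormalization,
#' so total mass equals total fixation weight up to boundary loss.
#'
#' @param trials Fixation data.frame (`observer_id`, `condition`,
#'   `image_id`, `fix_index`, `x_px`, `y_px`, `duration_ms`), all rows
#'   belonging to `scene`.
#' @param scene A [scene_spec()].
#' @param geometry A [viewing_geometry()].
#' @param config A [heatmap_config()].
#' @return A [heat_map()] whose `meta` records the kernel SD, source
#'   condition and number of observers.
#' @export
build_heatmap <- function(trials, scene, geometry = viewing_geometry(),
                          config = heatmap_config()) {
  w <- scene$width_px; h <- scene$height_px
  if (nrow(trials) > 0 && any(trials$image_id != scene$image_id)) {
    stopf("trials contain fixations for a different scene than '%s'",
          scene$image_id)
  }
  fx <- trials
  if (config$exclude_initial_central && nrow(fx) > 0) {
    fx <- fx[fx$fix_index > 1L, , drop = FALSE]
  }
  if (config$exclude_people_fixations && nrow(fx) > 0) {
    ppl <- scene_people(scene)
    if (length(ppl)) {
      inside <- Reduce(`|`, lapply(ppl, function(e) point_in_box(fx$x_px, fx$y_px, e)))
      fx <- fx[!inside, , drop = FALSE]
    }
  }
  vals <- matrix(0, h, w)
  if (nrow(fx) == 0L) {
    warnf("no fixations for scene '%s'; returning a zero map", scene$image_id)
  } else {
    out_of_bounds <- fx$x_px < 0 | fx$x_px >= w | fx$y_px < 0 | fx$y_px >= h
    if (any(out_of_bounds)) {
      warnf("%d fixations outside the image region were clipped", sum(out_of_bounds))
    }
    # clip to the image, then snap to the nearest pixel centre
    xi <- pmin(pmax(floor(fx$x_px), 0), w - 1L) + 1L
    yi <- pmin(pmax(floor(fx$y_px), 0), h - 1L) + 1L
    wgt <- if (config$weight_mode == "duration") fx$duration_ms else rep(1, nrow(fx))
    cell <- (xi - 1L) * h + yi # column-major linear index
    acc <- rowsum(wgt, group = cell)
    vals[as.integer(rownames(acc))] <- acc[, 1L]
    sd_x <- deg_to_px(geometry, config$kernel_sd_deg, "horizontal")
    sd_y <- deg_to_px(geometry, config$kernel_sd_deg, "vertical")
    vals <- blur_gaussian(vals, sd_x, sd_y)
  }
  mask <- if (config$mask_people) people_mask(scene) else NULL
  heat_map(pmax(vals, 0), mask = mask,
           meta = list(kernel_sd_deg = config$kernel_sd_deg,
                       condition = if (nrow(trials)) trials$condition[1L] else NA,
                       n_observers = length(unique(trials$observer_id)),
                       weight_mode = config$weight_mode))
}

#' Pool an observer subset into one heat map
#'
#' Builds a single heat map from the union of the subset's fixations;
#' by linearity the result equals the elementwise sum of the singleton
#' maps.
#'
#' @param trials Fixation data.frame for one scene.
#' @param observers Character vector of observer ids to pool.
#' @inheritParams build_heatmap
#' @return A [heat_map()] with `meta$n_observers = length(observers)`.
#' @export
pooled_heatmap <- function(trials, observers, scene,
                           geometry = viewing_geometry(),
                           config = heatmap_config()) {
  if (length(observers) == 0L) stopf("observer subset is empty")
  sub <- trials[trials$observer_id %in% observers, , drop = FALSE]
  hm <- build_heatmap(sub, scene, geometry, config)
  hm$meta$n_observers <- length(unique(observers))
  hm
}

#' Extract a prediction map's top element
#'
#' Convolves the map with a uniform, normalized circular patch of 2 dva
#' diameter and takes the argmax. If the peak lies inside an element's
#' bounding box that box represents the prediction (smallest box wins
#' when boxes overlap); otherwise a synthetic box with the scene's mean
#' box dimensions is centred on the peak.
#'
#' @param map A [heat_map()] on the scene grid.
#' @param scene A [scene_spec()].
#' @param geometry A [viewing_geometry()].
#' @param patch_diameter_deg Patch diameter in dva (default 2).
#' @param include_people May the prediction land on person-class boxes?
#' @return List with `peak` (`c(x, y)`, 0-based pixels), `element_id`
#'   (`NA` for a synthetic box), `box` and `synthetic` flag.
#' @export
extract_top_prediction <- function(map, scene, geometry = viewing_geometry(),
                                   patch_diameter_deg = 2,
                                   include_people = FALSE) {
  v <- map$values
  if (!identical(dim(v), c(scene$height_px, scene$width_px))) {
    stopf("map grid does not match scene '%s'", scene$image_id)
  }
  if (max(v) <= 0) stopf("cannot extract a prediction from an all-zero map")
  if (!is.null(map$mask)) v[map$mask] <- 0
  r <- deg_to_px(geometry, patch_diameter_deg / 2, "horizontal")
  r <- (r + deg_to_px(geometry, patch_diameter_deg / 2, "vertical")) / 2
  r <- max(1L, round(r))
  d <- 2L * r + 1L
  patch <- outer(seq_len(d) - r - 1L, seq_len(d) - r - 1L,
                 function(dy, dx) as.numeric(dy^2 + dx^2 <= r^2))
  patch <- patch / sum(patch)
  smoothed <- conv2_same(v, patch)
  peak <- argmax_xy(smoothed, sprintf("prediction map for '%s'", scene$image_id))

  cand <- if (include_people) scene$elements else scene_objects(scene)
  hits <- Filter(function(e) point_in_box(peak[["x"]] + 0.5, peak[["y"]] + 0.5, e),
                 cand)
  if (length(hits)) {
    areas <- vapply(hits, box_area, numeric(1L))
    e <- hits[[which.min(areas)]]
    return(list(peak = peak, element_id = e$element_id, box = e$box,
                synthetic = FALSE))
  }
  dims <- vapply(cand, function(e) c(box_width(e), box_height(e)), numeric(2L))
  mw <- mean(dims[1L, ]); mh <- mean(dims[2L, ])
  box <- c(peak[["x"]] + 0.5 - mw / 2, peak[["y"]] + 0.5 - mh / 2,
           peak[["x"]] + 0.5 + mw / 2, peak[["y"]] + 0.5 + mh / 2)
  list(peak = peak, element_id = NA_character_, box = box, synthetic = TRUE)
}
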