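#' Viewing geometry of the eye-tracking display
#'
#' Describes the screen as seen by the observer: its extent in degrees
#' of visual angle (dva) and in pixels. Horizontal and vertical
#' pixels-per-degree are kept separate because displays are rarely
#' exactly isotropic (e.g. 1280/26.6 != 1024/21.8).
#'
#' @param distance_cm Viewing distance in centimetres.
#' @param screen_width_deg,screen_height_deg Screen extent in dva.
#' @param screen_width_px,screen_height_px Screen extent in pixels.
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry(75, 26.6, 21.8, 1280, 1024)
#' deg_to_px(geom, 0.5, "horizontal")
#' @export
viewing_geometry <- function(distance_cm = 75,
                             screen_width_deg = 26.6,
                             screen_height_deg = 21.8,
                             screen_width_px = 1280L,
                             screen_height_px = 1024L) {
  vals <- c(distance_cm, screen_width_deg, screen_height_deg,
            screen_width_px, screen_height_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("invalid geometry: all fields must be positive and finite")
  }
  structure(
    list(distance_cm = distance_cm,
         screen_width_deg = screen_width_deg,
         screen_height_deg = screen_height_deg,
         screen_width_px = as.integer(screen_width_px),
         screen_height_px = as.integer(screen_height_px)),
    class = "viewing_geometry")
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf("<viewing_geometry> %g x %g dva at %d x %d px (%.2f / %.2f px/deg)\n",
              x$screen_width_deg, x$screen_height_deg,
              x$screen_width_px, x$screen_height_px,
              px_per_deg(x, "horizontal"), px_per_deg(x, "vertical")))
  invisible(x)
}

px_per_deg <- function(geometry, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") {
    geometry$screen_width_px / geometry$screen_width_deg
  } else {
    geometry$screen_height_px / geometry$screen_height_deg
  }
}

# Isotropic scale where a single value is needed (kernel SDs, patch
# radii specified in dva only): mean of the two axis scales.
px_per_deg_iso <- function(geometry) {
  (px_per_deg(geometry, "horizontal") + px_per_deg(geometry, "vertical")) / 2
}

#' Convert between degrees of visual angle and pixels
#'
#' Each axis uses its own scale; the round trip is the identity.
#'
#' @param geometry A [viewing_geometry()].
#' @param value Nonnegative scalar or vector to convert.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return The converted value(s).
#' @export
deg_to_px <- function(geometry, value, axis = c("horizontal", "vertical")) {
  check_geometry(geometry)
  value * px_per_deg(geometry, match.arg(axis))
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(geometry, value, axis = c("horizontal", "vertical")) {
  check_geometry(geometry)
  value / px_per_deg(geometry, match.arg(axis))
}

check_geometry <- function(geometry) {
  if (!inherits(geometry, "viewing_geometry")) {
    stopf("invalid geometry: expected a viewing_geometry object")
  }
  invisible(geometry)
}

#' Rectangular element annotation
#'
#' Boxes are 0-based and half-open: a fixation at (x, y) is inside iff
#' `x_min <= x < x_max` and `y_min <= y < y_max`.
#'
#' @param element_id Identifier, unique within a scene.
#' @param label Free-text label; shared labels define the correspondence
#'   across a Winograd pair.
#' @param box Numeric `c(x_min, y_min, x_max, y_max)` in pixels.
#' @param element_class `"object"`, `"person"` or `"person_hands"`.
#' @return An object of class `object_box`.
#' @export
object_box <- function(element_id, label, box,
                       element_class = c("object", "person", "person_hands")) {
  element_class <- match.arg(element_class)
  box <- as.numeric(box)
  if (length(box) != 4L || any(!is.finite(box))) {
    stopf("box must be numeric c(x_min, y_min, x_max, y_max)")
  }
  if (box[1L] >= box[3L] || box[2L] >= box[4L]) {
    stopf("degenerate box for element '%s': require x_min < x_max and y_min < y_max",
          element_id)
  }
  structure(
    list(element_id = as.character(element_id), label = as.character(label),
         box = box, element_class = element_class),
    class = "object_box")
}

box_width <- function(b) b$box[3L] - b$box[1L]
box_height <- function(b) b$box[4L] - b$box[2L]
box_center <- function(b) c((b$box[1L] + b$box[3L]) / 2, (b$box[2L] + b$box[4L]) / 2)
box_area <- function(b) box_width(b) * box_height(b)

point_in_box <- function(x, y, b) {
  x >= b$box[1L] & x < b$box[3L] & y >= b$box[2L] & y < b$box[4L]
}

#' Scene specification
#'
#' One image's geometry: the pixel grid, its annotated elements, and
#' optional task metadata (search target, grasp/gaze votes). All heat
#' maps for a scene live on its `width_px x height_px` grid.
#'
#' @param image_id,pair_id Identifiers; exactly two scenes share a
#'   `pair_id` (a Winograd pair).
#' @param set_id Which of the two stimulus sets the image belongs to (1 or 2).
#' @param width_px,height_px Scene grid size in pixels.
#' @param elements List of [object_box()] annotations.
#' @param search_target_id Optional element_id of the search target.
#' @param grasp_gaze_votes Optional named integer vector of
#'   perceived-grasp/gaze votes per element.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_id, pair_id, set_id, width_px, height_px,
                       elements, search_target_id = NULL,
                       grasp_gaze_votes = NULL) {
  if (!is_count(width_px) || !is_count(height_px)) {
    stopf("scene dimensions must be positive integers")
  }
  ids <- vapply(elements, function(e) e$element_id, character(1L))
  if (anyDuplicated(ids)) stopf("duplicate element_id in scene '%s'", image_id)
  for (e in elements) {
    if (!inherits(e, "object_box")) stopf("elements must be object_box objects")
    if (e$box[3L] > width_px || e$box[4L] > height_px ||
        e$box[1L] < 0 || e$box[2L] < 0) {
      stopf("element '%s' box outside the %dx%d grid", e$element_id,
            width_px, height_px)
    }
  }
  n_obj <- sum(vapply(elements, function(e) e$element_class == "object", logical(1L)))
  if (n_obj < 1L) stopf("scene '%s' has no object-class elements", image_id)
  if (!is.null(search_target_id) && !search_target_id %in% ids) {
    stopf("search_target_id '%s' is not an element of scene '%s'",
          search_target_id, image_id)
  }
  structure(
    list(image_id = as.character(image_id), pair_id = as.character(pair_id),
         set_id = as.integer(set_id), width_px = as.integer(width_px),
         height_px = as.integer(height_px), elements = stats::setNames(elements, ids),
         search_target_id = search_target_id,
         grasp_gaze_votes = grasp_gaze_votes),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %s (pair %s, set %d): %d x %d px, %d elements\n",
              x$image_id, x$pair_id, x$set_id, x$width_px, x$height_px,
              length(x$elements)))
  invisible(x)
}

scene_objects <- function(scene) {
  Filter(function(e) e$element_class == "object", scene$elements)
}

scene_people <- function(scene) {
  Filter(function(e) e$element_class != "object", scene$elements)
}

# Binary people raster: TRUE inside any person-class box.
people_mask <- function(scene) {
  m <- matrix(FALSE, scene$height_px, scene$width_px)
  for (e in scene_people(scene)) {
    xs <- seq.int(floor(e$box[1L]) + 1L, ceiling(e$box[3L]))
    ys <- seq.int(floor(e$box[2L]) + 1L, ceiling(e$box[4L]))
    m[ys, xs] <- TRUE
  }
  m
}

#' Winograd pair
#'
#' Two nearly identical scenes plus the correspondence between their
#' shared objects. Corresponding elements must carry the same label and
#' the map must be a bijection on its domain.
#'
#' @param scene_a,scene_b [scene_spec()] objects sharing a `pair_id`.
#' @param shared_object_map Named character vector: element_id in
#'   `scene_a` -> element_id in `scene_b`. Defaults to matching by label.
#' @return An object of class `winograd_pair`.
#' @export
winograd_pair <- function(scene_a, scene_b, shared_object_map = NULL) {
  if (scene_a$pair_id != scene_b$pair_id) {
    stopf("scenes '%s' and '%s' have different pair_ids",
          scene_a$image_id, scene_b$image_id)
  }
  if (is.null(shared_object_map)) {
    la <- vapply(scene_objects(scene_a), function(e) e$label, character(1L))
    lb <- vapply(scene_objects(scene_b), function(e) e$label, character(1L))
    shared <- intersect(la, lb)
    shared_object_map <- stats::setNames(
      names(lb)[match(shared, lb)], names(la)[match(shared, la)])
  }
  if (anyDuplicated(shared_object_map) || anyDuplicated(names(shared_object_map))) {
    stopf("shared_object_map must be a bijection")
  }
  for (i in seq_along(shared_object_map)) {
    a <- scene_a$elements[[names(shared_object_map)[i]]]
    b <- scene_b$elements[[shared_object_map[[i]]]]
    if (is.null(a) || is.null(b)) stopf("shared_object_map references unknown elements")
    if (a$label != b$label) {
      stopf("mapped elements '%s'/'%s' have different labels",
            a$element_id, b$element_id)
    }
  }
  structure(
    list(pair_id = scene_a$pair_id, scene_a = scene_a, scene_b = scene_b,
         shared_object_map = shared_object_map),
    class = "winograd_pair")
}
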