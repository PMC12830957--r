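# Shared fixtures, built in code.

study_geometry <- function() viewing_geometry(75, 26.6, 21.8, 1280, 1024)

# A tiny two-object + one-person scene on a 200x160 grid.
tiny_scene <- function(image_id = "img1", pair_id = "p1", set_id = 1L) {
  scene_spec(
    image_id, pair_id, set_id, 200L, 160L,
    elements = list(
      object_box(paste0(image_id, "_A"), "lamp", c(20, 20, 70, 60)),
      object_box(paste0(image_id, "_B"), "mug", c(120, 90, 170, 130)),
      object_box(paste0(image_id, "_P"), "person", c(80, 30, 110, 120),
                 element_class = "person")),
    search_target_id = paste0(image_id, "_B"))
}

# A matched Winograd pair of tiny scenes.
tiny_pair <- function() {
  winograd_pair(tiny_scene("imgA", "p1", 1L), tiny_scene("imgB", "p1", 2L))
}

# Fixation data.frame from bare coordinates.
make_trials <- function(x, y, image_id = "img1", observer_id = "o1",
                        condition = "FV", duration = 250,
                        fix_index = seq_along(x)) {
  data.frame(observer_id = observer_id, condition = condition,
             image_id = image_id, fix_index = fix_index,
             x_px = x, y_px = y, duration_ms = duration,
             stringsAsFactors = FALSE)
}

# Rating table from a named list: element_id -> vector of ratings.
make_rating_table <- function(ratings, scene_id = "img1") {
  rows <- lapply(names(ratings), function(eid) {
    data.frame(scene_id = scene_id,
               rater_id = sprintf("r%02d", seq_along(ratings[[eid]])),
               element_id = eid, rating = ratings[[eid]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brute-force step-up FDR oracle, independent of stats::p.adjust.
brute_force_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(cm * m / (i:m) * ps[i:m]))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Mann-Whitney rank oracle for the shuffled AUC.
rank_auc_oracle <- function(pos_vals, neg_vals) {
  s <- 0
  for (p in pos_vals) for (n in neg_vals) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos_vals) * length(neg_vals))
}

# Geometry whose full field is the tiny 200x160 grid (small kernels).
tiny_geometry <- function() viewing_geometry(75, 26.6, 21.8, 200, 160)
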