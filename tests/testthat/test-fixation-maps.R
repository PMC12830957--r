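test_that("a single fixation produces a unique peak at its location", {
  sc <- tiny_scene()
  g <- study_geometry()
  tr <- make_trials(130, 100, fix_index = 2L)
  hm <- build_heatmap(tr, sc, g)
  peak <- which(hm$values == max(hm$values), arr.ind = TRUE)
  expect_identical(nrow(peak), 1L)
  expect_identical(unname(peak[1, ]), c(101L, 131L)) # row = y+1, col = x+1
})

test_that("heat map mass equals total fixation weight for interior points", {
  sc <- tiny_scene()
  g <- tiny_geometry()
  set.seed(1)
  n <- 50
  tr <- make_trials(runif(n, 60, 140), runif(n, 60, 100),
                    fix_index = seq_len(n) + 1L)
  hm <- build_heatmap(tr, sc, g)
  expect_lt(abs(sum(hm$values) - n) / n, 0.005)
  # duration weighting: mass = total duration
  tr$duration_ms <- runif(n, 100, 400)
  hmd <- build_heatmap(tr, sc, g, heatmap_config(weight_mode = "duration"))
  expect_lt(abs(sum(hmd$values) - sum(tr$duration_ms)) / sum(tr$duration_ms),
            0.005)
})

test_that("maps are deterministic, linear and translation-equivariant", {
  sc <- scene_spec("img1", "p", 1L, 300L, 300L,
                   list(object_box("e", "x", c(10, 10, 50, 50))))
  g <- study_geometry()
  t1 <- make_trials(c(100, 120), c(100, 140), observer_id = "o1",
                    fix_index = 2:3)
  t2 <- make_trials(c(180, 200), c(150, 120), observer_id = "o2",
                    fix_index = 2:3)
  both <- rbind(t1, t2)
  expect_identical(build_heatmap(both, sc, g), build_heatmap(both, sc, g))

  # pooled map of disjoint subsets = sum of singleton maps
  pooled <- pooled_heatmap(both, c("o1", "o2"), sc, g)
  h1 <- build_heatmap(t1, sc, g)
  h2 <- build_heatmap(t2, sc, g)
  expect_equal(pooled$values, h1$values + h2$values, tolerance = 1e-12)
  expect_identical(pooled$meta$n_observers, 2L)
  # observer order is irrelevant
  expect_equal(pooled_heatmap(both, c("o2", "o1"), sc, g)$values,
               pooled$values)

  # translation equivariance for interior fixations
  shift <- build_heatmap(make_trials(c(100, 120) + 7, c(100, 140) + 5,
                                     observer_id = "o1", fix_index = 2:3),
                         sc, g)
  expect_equal(shift$values[(1 + 5):300, (1 + 7):300],
               h1$values[1:(300 - 5), 1:(300 - 7)], tolerance = 1e-12)
})

test_that("trial filters and guards behave as configured", {
  sc <- tiny_scene()
  g <- tiny_geometry()
  tr <- make_trials(c(100, 130), c(80, 100), fix_index = 1:2)
  hm <- build_heatmap(tr, sc, g) # drops the initial central fixation
  expect_lt(abs(sum(hm$values) - 1), 0.01)
  hm2 <- build_heatmap(tr, sc, g, heatmap_config(exclude_initial_central = FALSE))
  expect_lt(abs(sum(hm2$values) - 2), 0.02)

  expect_error(build_heatmap(make_trials(1, 1, image_id = "other"), sc, g),
               "different scene")
  expect_warning(z <- build_heatmap(tr[0, ], sc, g), "zero map")
  expect_identical(sum(z$values), 0)
  expect_warning(build_heatmap(make_trials(500, 50, fix_index = 2L), sc, g),
                 "clipped")
})

test_that("people exclusion drops fixations or masks pixels, never both values", {
  sc <- tiny_scene() # person box c(80, 30, 110, 120)
  g <- tiny_geometry()
  tr <- make_trials(c(95, 30), c(70, 30), fix_index = 2:3)
  drop <- build_heatmap(tr, sc, g,
                        heatmap_config(exclude_people_fixations = TRUE))
  expect_lt(abs(sum(drop$values) - 1), 0.01) # person-box fixation dropped

  masked <- build_heatmap(tr, sc, g, heatmap_config(mask_people = TRUE))
  expect_lt(abs(sum(masked$values) - 2), 0.02) # values untouched
  expect_true(all(masked$mask[31:120, 81:110]))
  unmasked <- build_heatmap(tr, sc, g)
  expect_equal(masked$values, unmasked$values, tolerance = 1e-12)
})

test_that("empirical maps converge to the generative density", {
  ss <- generate_scene_set(1, 5, grid = c(320L, 256L), seed = 2)
  sc <- ss$scenes[[1]]
  gt <- ss$ground_truth
  d <- condition_density(sc, gt, "FV")
  set.seed(3)
  n <- 20000
  idx <- sample.int(length(d), n, TRUE, prob = as.vector(d))
  h <- nrow(d)
  tr <- make_trials(((idx - 1) %/% h) + runif(n) - 0.5,
                    ((idx - 1) %% h) + runif(n) - 0.5,
                    image_id = sc$image_id, fix_index = seq_len(n) + 1L)
  tr$x_px <- pmin(pmax(tr$x_px, 0), sc$width_px - 1e-6)
  tr$y_px <- pmin(pmax(tr$y_px, 0), sc$height_px - 1e-6)
  hm <- build_heatmap(tr, sc, gt$geometry)
  expected <- gazesum:::blur_gaussian(
    d, deg_to_px(gt$geometry, 0.5, "horizontal"),
    deg_to_px(gt$geometry, 0.5, "vertical"))
  expect_gt(cor(as.vector(hm$values), as.vector(expected)), 0.98)
})

test_that("top prediction lands on the containing box or a synthetic one", {
  g <- study_geometry()
  sc <- scene_spec("s", "p", 1L, 300L, 240L,
                   list(object_box("B", "b", c(40, 40, 120, 100)),
                        object_box("C", "c", c(200, 150, 280, 210))))
  # Gaussian bump centred inside B
  v <- outer(stats::dnorm(1:240, 70, 15), stats::dnorm(1:300, 80, 15))
  top <- extract_top_prediction(heat_map(v / max(v)), sc, g)
  expect_identical(top$element_id, "B")
  expect_false(top$synthetic)

  # peak in the background: synthetic box with the mean dimensions (80x60)
  v2 <- outer(stats::dnorm(1:240, 220, 10), stats::dnorm(1:300, 20, 10))
  top2 <- extract_top_prediction(heat_map(v2 / max(v2)), sc, g)
  expect_true(top2$synthetic)
  expect_equal(top2$box[3] - top2$box[1], 80, tolerance = 1e-9)
  expect_equal(top2$box[4] - top2$box[2], 60, tolerance = 1e-9)

  expect_error(extract_top_prediction(heat_map(matrix(0, 240, 300)), sc, g),
               "all-zero")
})

test_that("tied maxima resolve deterministically to the lowest (y, x)", {
  m <- matrix(0, 10, 10)
  m[3, 7] <- 1
  m[8, 2] <- 1
  expect_warning(peak <- gazesum:::argmax_xy(m), "tied")
  expect_identical(unname(peak), c(6L, 2L)) # 0-based (x, y) of the lower-y hit

  # two identical impulses through the full extractor: the warning fires
  # and the reported peak stays inside the containing box
  g <- tiny_geometry()
  sc <- scene_spec("s", "p", 1L, 200L, 160L,
                   list(object_box("B", "b", c(10, 10, 80, 80)),
                        object_box("C", "c", c(110, 90, 190, 150))))
  v <- matrix(0, 160, 200)
  v[40, 40] <- 1
  v[120, 150] <- 1
  expect_warning(top <- extract_top_prediction(heat_map(v), sc, g), "tied")
  expect_identical(top$element_id, "B")
})
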