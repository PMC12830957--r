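test_that("rating aggregation matches the hand-computed worked example", {
  tab <- make_rating_table(list(A = c(2, 3, 2), B = c(9, 10, 10)))
  sc <- aggregate_ratings(tab)
  # inverted medians: A -> 9, B -> 1; shift by min then divide by max
  expect_identical(sc[["A"]], 1.0)
  expect_identical(sc[["B"]], 0.0)
})

test_that("degenerate rating tables give flat all-zero scores", {
  tab <- make_rating_table(list(A = c(5, 5, 5), B = c(5, 5, 5)))
  expect_warning(sc <- aggregate_ratings(tab), "flat")
  expect_identical(unname(sc), c(0, 0))
  expect_warning(one <- aggregate_ratings(make_rating_table(list(A = c(3, 4)))),
                 "flat")
  expect_identical(unname(one), 0)
})

test_that("aggregation validates its inputs", {
  expect_error(aggregate_ratings(data.frame()), "empty")
  bad <- make_rating_table(list(A = c(2, 11)))
  expect_error(aggregate_ratings(bad), "1..10")
  tab <- make_rating_table(list(img1_A = c(2, 2), img1_P = c(9, 9)))
  expect_error(aggregate_ratings(tab, include_people = FALSE), "requires a scene")
})

test_that("aggregation is invariant to rater order and duplication", {
  tab <- make_rating_table(list(A = c(2, 7, 4), B = c(9, 3, 5), C = c(1, 1, 8)))
  base <- aggregate_ratings(tab)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(aggregate_ratings(shuf), base)
  doubled <- rbind(tab, transform(tab, rater_id = paste0(rater_id, "_dup")))
  expect_equal(aggregate_ratings(doubled), base)
})

test_that("dropping people before aggregation renormalizes over objects", {
  sc <- tiny_scene()
  tab <- make_rating_table(list(img1_A = c(4, 4, 4), img1_B = c(8, 8, 8),
                                img1_P = c(1, 1, 1)))
  with_people <- aggregate_ratings(tab, sc, include_people = TRUE)
  expect_identical(with_people[["img1_P"]], 1.0)
  objects_only <- aggregate_ratings(tab, sc, include_people = FALSE)
  expect_identical(objects_only[["img1_A"]], 1.0)
  expect_identical(objects_only[["img1_B"]], 0.0)
  expect_false("img1_P" %in% names(objects_only))
})

test_that("SUM Gaussians have amplitude = score and clamped SDs", {
  g <- study_geometry()
  sc <- scene_spec("s", "p", 1L, 400L, 300L,
                   list(object_box("e1", "x", c(100, 100, 200, 180))))
  # 100-px box: SD_x = 0.29*100 = 29 px, inside the clamp [24.06, 72.18];
  # 80-px height: SD_y = 0.34*80 = 27.2 px, above the 0.5-dva floor (23.49)
  sd_px <- gazesum:::element_sd_px(sc$elements[["e1"]], sum_config(), g)
  expect_equal(sd_px[1], 29, tolerance = 1e-9)
  expect_equal(sd_px[2], 0.34 * 80, tolerance = 1e-9)

  s <- build_sum(sc, c(e1 = 1), geometry = g)
  ctr <- gazesum:::box_center(sc$elements[["e1"]]) # (150, 140)
  peak <- s$heat_map$values[ctr[2] + 1, ctr[1] + 1] # pixel j = coordinate j-1
  expect_equal(peak, 1, tolerance = 1e-6)
  expect_equal(max(s$heat_map$values), peak, tolerance = 1e-12)

  # box map: the score fills the box uniformly
  expect_identical(s$box_map$values[140, 150], 1)
  expect_identical(s$box_map$values[50, 50], 0)
})

test_that("the SD clamp binds at both dva boundaries", {
  g <- study_geometry()
  tiny <- object_box("t", "x", c(0, 0, 20, 20))
  sd_t <- gazesum:::element_sd_px(tiny, sum_config(), g)
  expect_equal(sd_t[1], deg_to_px(g, 0.5, "horizontal"), tolerance = 1e-9)
  expect_equal(sd_t[1], 24.06, tolerance = 1e-2)
  huge <- object_box("h", "x", c(0, 0, 600, 500))
  sd_h <- gazesum:::element_sd_px(huge, sum_config(), g)
  expect_equal(sd_h[1], deg_to_px(g, 1.5, "horizontal"), tolerance = 1e-9)
  expect_equal(sd_h[2], deg_to_px(g, 1.5, "vertical"), tolerance = 1e-9)
  # clamp off: raw fraction of the box size
  sd_raw <- gazesum:::element_sd_px(tiny, sum_config(sd_clamp = NULL), g)
  expect_equal(sd_raw[1], 0.29 * 20, tolerance = 1e-9)
})

test_that("zero-score elements contribute nothing and unknown elements error", {
  sc <- scene_spec("s", "p", 1L, 200L, 200L,
                   list(object_box("e1", "x", c(10, 10, 60, 60)),
                        object_box("e2", "y", c(100, 100, 150, 150))))
  with_e2 <- build_sum(sc, c(e1 = 1, e2 = 0), geometry = study_geometry())
  without <- build_sum(sc, c(e1 = 1), geometry = study_geometry())
  expect_identical(with_e2$heat_map$values, without$heat_map$values)
  expect_identical(with_e2$box_map$values[125, 125], 0)
  expect_error(build_sum(sc, c(zz = 1), geometry = study_geometry()),
               "unknown element")
})

test_that("category assignment swaps SU-relevance across the pair", {
  pr <- tiny_pair()
  g <- study_geometry()
  # projector-like object is relevant in A, its partner (same label) in B
  sum_a <- build_sum(pr$scene_a, c(imgA_A = 1, imgA_B = 0.1), geometry = g)
  sum_b <- build_sum(pr$scene_b, c(imgB_A = 0.1, imgB_B = 1), geometry = g)
  asg <- assign_categories(pr, sum_a, sum_b)
  expect_identical(asg[["imgA"]]$su_relevant, "imgA_A")
  expect_identical(asg[["imgA"]]$su_irrelevant, "imgA_B")
  expect_identical(asg[["imgB"]]$su_relevant, "imgB_B")
  expect_identical(asg[["imgB"]]$su_irrelevant, "imgB_A")
  # the mapped SU-relevant set of one scene is the other's SU-irrelevant set
  expect_identical(unname(pr$shared_object_map[[asg[["imgA"]]$su_relevant]]),
                   asg[["imgB"]]$su_irrelevant)
})

test_that("grasp/gaze votes resolve by argmax with deterministic ties", {
  pr <- tiny_pair()
  pr$scene_a$grasp_gaze_votes <- c(imgA_A = 20, imgA_B = 5)
  pr$scene_b$grasp_gaze_votes <- c(imgB_A = 7, imgB_B = 7)
  g <- study_geometry()
  sum_a <- build_sum(pr$scene_a, c(imgA_A = 1, imgA_B = 0.2), geometry = g)
  sum_b <- build_sum(pr$scene_b, c(imgB_A = 0.2, imgB_B = 1), geometry = g)
  expect_warning(asg <- assign_categories(pr, sum_a, sum_b), "tie")
  expect_identical(asg[["imgA"]]$grasp_gaze, "imgA_A")
  expect_identical(asg[["imgB"]]$grasp_gaze, "imgB_A") # lowest id on tie
})

test_that("person-inclusive scores name people as most critical", {
  pr <- tiny_pair()
  g <- study_geometry()
  sum_a <- build_sum(pr$scene_a, c(imgA_A = 1, imgA_B = 0.2), geometry = g)
  sum_b <- build_sum(pr$scene_b, c(imgB_A = 0.2, imgB_B = 1), geometry = g)
  asg <- assign_categories(pr, sum_a, sum_b,
                           people_scores = list(
                             c(imgA_A = 0.8, imgA_B = 0.1, imgA_P = 1),
                             c(imgB_A = 0.1, imgB_B = 0.8, imgB_P = 1)))
  expect_identical(asg[["imgA"]]$most_critical, "imgA_P")
  expect_identical(asg[["imgB"]]$most_critical, "imgB_P")
})

test_that("synthetic people are most critical in most scenes", {
  # person impact is drawn near the top of the scale, so person-inclusive
  # aggregation should rank people first in the large majority of scenes
  ss <- generate_scene_set(9, 6, grid = c(320L, 256L), seed = 21)
  rt <- generate_ratings(ss$pairs, ss$ground_truth, seed = 22)
  top_is_person <- vapply(names(ss$scenes), function(img) {
    sc <- aggregate_ratings(rt[rt$scene_id == img, ], ss$scenes[[img]],
                            include_people = TRUE)
    names(which.max(sc)) %in% names(gazesum:::scene_people(ss$scenes[[img]]))
  }, logical(1))
  expect_gt(mean(top_is_person), 0.5)
})
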