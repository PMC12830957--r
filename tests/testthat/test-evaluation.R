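test_that("heat-map correlation is Pearson over unmasked pixels", {
  h <- heat_map(matrix(c(1, 3, 2, 4), 2))
  expect_identical(heatmap_correlation(h, h), 1)
  h2 <- heat_map(matrix(c(4, 2, 3, 1), 2))
  expect_equal(heatmap_correlation(h, h2), -1, tolerance = 1e-12)

  # correlation restricted by a mask equals cor() of the kept vectors
  set.seed(5)
  a <- matrix(runif(100), 10)
  b <- matrix(runif(100), 10)
  mask <- matrix(runif(100) < 0.3, 10)
  hm_a <- heat_map(a, mask = mask)
  hm_b <- heat_map(b)
  expect_equal(heatmap_correlation(hm_a, hm_b),
               cor(as.vector(a)[!mask], as.vector(b)[!mask]),
               tolerance = 1e-12)

  flat <- heat_map(matrix(1, 2, 2))
  expect_error(heatmap_correlation(h, flat), "zero variance")
  expect_error(heatmap_correlation(h, heat_map(matrix(1, 3, 3))),
               "different grids")
})

test_that("shuffled AUC matches the rank oracle and complements to 1", {
  set.seed(7)
  for (i in 1:100) {
    w <- sample(5:20, 1)
    h <- sample(5:20, 1)
    pred <- heat_map(matrix(sample(0:5, w * h, TRUE) * 0.5, h, w))
    np <- sample(1:50, 1)
    pos <- make_trials(runif(np, 0, w - 1e-9), runif(np, 0, h - 1e-9))
    neg <- make_trials(runif(np, 0, w - 1e-9), runif(np, 0, h - 1e-9))
    s_rank <- sauc(pred, pos, neg, mode = "rank")
    s_sweep <- sauc(pred, pos, neg, mode = "sweep")
    expect_lt(abs(s_rank - s_sweep), 1e-9)
    hmat <- nrow(pred$values)
    oracle <- rank_auc_oracle(
      pred$values[floor(pos$y_px) + 1 + floor(pos$x_px) * hmat],
      pred$values[floor(neg$y_px) + 1 + floor(neg$x_px) * hmat])
    expect_lt(abs(s_rank - oracle), 1e-9)
    expect_lt(abs(s_rank + sauc(pred, neg, pos) - 1), 1e-9)
  }
})

test_that("sAUC hits its analytic extremes", {
  pred <- heat_map(matrix(rep(c(0, 1), each = 8), 4)) # left half 0, right 1
  hi <- make_trials(c(2.5, 3.5), c(1, 2))
  lo <- make_trials(c(0.5, 1.5), c(1, 2))
  expect_identical(sauc(pred, hi, lo), 1)
  expect_identical(sauc(pred, lo, hi), 0)
  flat <- heat_map(matrix(1, 4, 4))
  expect_identical(sauc(flat, hi, lo), 0.5)
  expect_error(sauc(pred, hi[0, ], lo[0, ]), "empty")
  expect_error(sauc(pred, hi, lo[1, ]), "same size")
})

test_that("negative sets come from the observer's other images only", {
  tr <- rbind(make_trials(1:5, 1:5, image_id = "imgX", observer_id = "o1"),
              make_trials(6:9, 6:9, image_id = "imgY", observer_id = "o1"))
  neg <- build_negative_sets(tr, "o1", "imgX", 3, seed = 1)
  expect_true(all(neg$image_id == "imgY"))
  expect_identical(build_negative_sets(tr, "o1", "imgX", 3, seed = 1), neg)
  expect_warning(big <- build_negative_sets(tr, "o1", "imgX", 10, seed = 2),
                 "replacement")
  expect_identical(nrow(big), 10L)
  expect_error(build_negative_sets(tr, "o1", "imgY", 2, seed = 1), NA)
  only <- make_trials(1, 1, image_id = "imgX", observer_id = "o2")
  expect_error(build_negative_sets(only, "o2", "imgX", 1), "no fixations")
})

test_that("category frequencies count per trial with the averaging rule", {
  sc <- scene_spec("img1", "p", 1L, 200L, 160L,
                   list(object_box("A", "a", c(0, 0, 50, 50)),
                        object_box("B", "b", c(100, 0, 150, 50)),
                        object_box("B2", "b2", c(100, 100, 150, 150))))
  asg <- list(su_relevant = "A", su_irrelevant = "B")
  # sequence A, B, A, background (after the central start fixation)
  tr <- make_trials(c(100, 25, 125, 25, 75), c(80, 25, 25, 25, 75),
                    fix_index = 1:5)
  fr <- category_fixation_frequency(tr, sc, asg)
  expect_identical(fr$value[fr$category == "su_relevant"], 2)
  expect_identical(fr$value[fr$category == "su_irrelevant"], 1)

  # a two-object category averages over its objects: hits 2 and 0 -> 1
  asg2 <- list(su_relevant = c("B", "B2"), su_irrelevant = "A")
  tr2 <- make_trials(c(100, 110, 120), c(80, 25, 25), fix_index = 1:3)
  fr2 <- category_fixation_frequency(tr2, sc, asg2)
  expect_identical(fr2$value[fr2$category == "su_relevant"], 1)

  # empty trial: all zeros
  fr0 <- category_fixation_frequency(tr[1, ], sc, asg)
  expect_true(all(fr0$value == 0))

  # duration weighting sums durations instead of counts
  frd <- category_fixation_frequency(tr, sc, asg, weight_mode = "duration")
  expect_identical(frd$value[frd$category == "su_relevant"], 500)
})

test_that("overlapping boxes assign to the smallest, never double-counting", {
  sc <- scene_spec("img1", "p", 1L, 200L, 160L,
                   list(object_box("big", "x", c(0, 0, 100, 100)),
                        object_box("small", "y", c(20, 20, 40, 40))))
  tr <- make_trials(c(30, 60), c(30, 60), fix_index = 2:3)
  expect_warning(
    fr <- category_fixation_frequency(tr, sc,
                                      list(su_relevant = "small",
                                           su_irrelevant = "big"),
                                      exclude_initial_central = FALSE),
    "overlapping")
  expect_identical(fr$value[fr$category == "su_relevant"], 1)
  expect_identical(fr$value[fr$category == "su_irrelevant"], 1)
  # totals never exceed the trial's fixation count
  expect_lte(sum(fr$value), nrow(tr))
})

test_that("people hits are reported or dropped per the exclusion flag", {
  sc <- tiny_scene() # person box c(80, 30, 110, 120)
  asg <- list(su_relevant = "img1_A", su_irrelevant = "img1_B",
              people = "img1_P")
  tr <- make_trials(c(100, 95, 25), c(80, 70, 25), fix_index = 1:3)
  fr <- category_fixation_frequency(tr, sc, asg)
  expect_identical(fr$value[fr$category == "people"], 1)
  fr_ex <- category_fixation_frequency(tr, sc, asg, exclude_people = TRUE)
  expect_false("people" %in% fr_ex$category)
  expect_identical(fr_ex$value[fr_ex$category == "su_relevant"], 1)
})

test_that("cumulative difference curves track the worked example", {
  sc <- scene_spec("img1", "p", 1L, 200L, 160L,
                   list(object_box("R", "r", c(0, 0, 50, 50)),
                        object_box("I", "i", c(100, 0, 150, 50))))
  asg <- list(su_relevant = "R", su_irrelevant = "I")
  # single trial: rel, irr, rel
  tr <- make_trials(c(25, 125, 30), c(25, 25, 30), fix_index = 1:3)
  cv <- cumulative_difference_curve(tr, sc, asg, K = 3)
  expect_identical(cv$cf_rel, c(1, 1, 2))
  expect_identical(cv$cf_irr, c(0, 1, 1))
  expect_identical(cv$delta_cf, c(1, 0, 1))
  expect_identical(cv$delta_cf, cv$cf_rel - cv$cf_irr)

  # all fixations on rel: delta_cf(k) = k
  tr_all <- make_trials(c(10, 20, 30), c(10, 20, 30), fix_index = 1:3)
  cv_all <- cumulative_difference_curve(tr_all, sc, asg, K = 3)
  expect_identical(cv_all$delta_cf, c(1, 2, 3))

  # swapping categories negates the curve
  cv_sw <- cumulative_difference_curve(
    tr, sc, asg, K = 3, categories = c("su_irrelevant", "su_relevant"))
  expect_identical(cv_sw$delta_cf, -cv$delta_cf)

  # CF is nondecreasing in k
  expect_true(all(diff(cv$cf_rel) >= 0))
  expect_true(all(diff(cv$cf_irr) >= 0))
})

test_that("condition correlations approach the within-condition bound when
           densities are shared", {
  d <- simulate_study(n_pairs = 2, n_observers = 26, grid = c(160L, 128L),
                      seed = 13)
  across <- condition_pair_correlation(d$trials, d$scenes, c("FV", "SD"),
                                       d$geometry, n_sub = 12, n_combos = 4,
                                       seed = 1)
  within <- condition_pair_correlation(d$trials, d$scenes, "FV",
                                       d$geometry, n_sub = 12, n_combos = 4,
                                       seed = 2)
  expect_true(all(across$per_image_r > -1 & across$per_image_r < 1))
  # FV and SD share a generative density: across-condition r is close to
  # the inter-observer bound
  expect_lt(abs(across$mean_r - within$mean_r), 0.15)
  # determinism
  rerun <- condition_pair_correlation(d$trials, d$scenes, c("FV", "SD"),
                                      d$geometry, n_sub = 12, n_combos = 4,
                                      seed = 1)
  expect_identical(rerun$combo_r, across$combo_r)
  expect_error(
    condition_pair_correlation(d$trials, d$scenes, c("FV", "SD"), d$geometry,
                               n_sub = 40), "fewer than")
})

test_that("winograd correlations separate shared from swapped maps", {
  d <- simulate_study(n_pairs = 3, n_observers = 12, grid = c(160L, 128L),
                      seed = 17)
  cfg <- heatmap_config()
  maps_fv <- lapply(d$scenes, function(sc) {
    build_heatmap(d$trials[d$trials$condition == "FV" &
                             d$trials$image_id == sc$image_id, ],
                  sc, d$geometry, cfg)
  })
  # a surrogate map identical across the pair (equal weight on every
  # shared object box) correlates perfectly within each pair
  surrogate <- lapply(d$scenes, function(sc) {
    objs <- names(gazesum:::scene_objects(sc))
    build_sum(sc, setNames(rep(1, length(objs)), objs),
              geometry = d$geometry)$heat_map
  })
  w_fv <- winograd_correlation(d$pairs, maps_fv)
  w_sur <- winograd_correlation(d$pairs, surrogate)
  expect_equal(unname(w_sur$pair_r), rep(1, 3), tolerance = 1e-9)
  expect_lt(w_fv$mean_r, w_sur$mean_r)

  ctrl <- winograd_correlation(d$pairs, maps_fv, random_control = TRUE,
                               n_random = 10, seed = 3)
  expect_length(ctrl$pair_r, 10L)
  expect_identical(
    winograd_correlation(d$pairs, maps_fv, random_control = TRUE,
                         n_random = 10, seed = 3)$pair_r, ctrl$pair_r)
})
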