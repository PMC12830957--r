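# Synthetic study generator.
#
# Emulates the structure of the four-condition eye-tracking study:
# Winograd scene pairs with 5-10 annotated objects plus one person,
# removal-impact rating tables (1-10 scale), description embeddings,
# and condition-specific fixation datasets (free viewing FV, scene
# description SD, object search OS, counting objects CO). Everything is
# a pure function of (arguments, seed).

CONDITIONS <- c("FV", "SD", "OS", "CO")

#' Generate a synthetic set of Winograd scene pairs
#'
#' Builds `n_pairs` pairs of scenes on a blank pixel grid. The two
#' scenes of a pair share object labels and positions; their true
#' removal-impact weights are swapped so that the highest-impact
#' ("SU-relevant") object of one scene is the lowest-impact object of
#' the other. Each scene also contains one person-class element whose
#' impact is typically the largest, mirroring scenes built around human
#' actors.
#'
#' @param n_pairs Number of Winograd pairs.
#' @param objects_per_scene Objects per scene (5-10).
#' @param grid `c(width_px, height_px)` of the scene grid.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list with `pairs` (list of [winograd_pair()]), `scenes`
#'   (named list of all scenes) and `ground_truth` (true impact weights
#'   and the generative parameters used downstream).
#' @export
generate_scene_set <- function(n_pairs, objects_per_scene = 6,
                               grid = c(640L, 512L), seed = 1L) {
  if (!is_count(n_pairs)) stopf("n_pairs must be a positive integer")
  if (objects_per_scene < 5 || objects_per_scene > 10) {
    stopf("objects_per_scene must be between 5 and 10")
  }
  w <- as.integer(grid[1L]); h <- as.integer(grid[2L])
  geometry <- viewing_geometry(75, 26.6, 21.8, w, h)
  with_seed(seed, {
    pairs <- vector("list", n_pairs)
    impacts <- list()
    scenes <- list()
    for (p in seq_len(n_pairs)) {
      pid <- sprintf("pair%02d", p)
      layout <- place_boxes(objects_per_scene, w, h)
      labels <- sprintf("%s_obj%02d", pid, seq_len(objects_per_scene))

      make_scene <- function(set_id, target_label) {
        iid <- sprintf("%s_img%d", pid, set_id)
        els <- vector("list", objects_per_scene + 1L)
        for (i in seq_len(objects_per_scene)) {
          els[[i]] <- object_box(sprintf("%s_e%02d", iid, i), labels[i],
                                 layout$boxes[[i]], "object")
        }
        els[[objects_per_scene + 1L]] <- object_box(
          sprintf("%s_person", iid), sprintf("%s_person", pid),
          layout$person, "person")
        scene_spec(iid, pid, set_id, w, h, els,
                   search_target_id = sprintf("%s_e%02d", iid,
                                              match(target_label, labels)))
      }

      # True impacts: one high (SU-relevant), its pair partner low,
      # the rest mid-range; swapped across the pair. Person highest.
      i_rel <- sample.int(objects_per_scene, 2L)
      base_mid <- stats::runif(objects_per_scene, 0.20, 0.50)
      imp_a <- base_mid; imp_b <- base_mid
      imp_a[i_rel[1L]] <- stats::runif(1, 0.80, 0.92)
      imp_a[i_rel[2L]] <- stats::runif(1, 0.02, 0.10)
      imp_b[i_rel[2L]] <- stats::runif(1, 0.80, 0.92)
      imp_b[i_rel[1L]] <- stats::runif(1, 0.02, 0.10)
      person_imp <- stats::runif(1, 0.95, 1.00)

      target_label <- labels[sample.int(objects_per_scene, 1L)]
      sa <- make_scene(1L, target_label)
      sb <- make_scene(2L, target_label)

      # Perceived grasp/gaze votes: concentrated on one object.
      gaze_i <- sample.int(objects_per_scene, 1L)
      vote_scene <- function(sc) {
        obj_ids <- names(scene_objects(sc))
        prob <- rep(1, objects_per_scene); prob[gaze_i] <- 12
        v <- as.integer(stats::rmultinom(1L, 25L, prob))
        stats::setNames(v, obj_ids)
      }
      sa$grasp_gaze_votes <- vote_scene(sa)
      sb$grasp_gaze_votes <- vote_scene(sb)

      obj_ids_a <- names(scene_objects(sa)); obj_ids_b <- names(scene_objects(sb))
      impacts[[sa$image_id]] <- c(stats::setNames(imp_a, obj_ids_a),
                                  stats::setNames(person_imp, names(scene_people(sa))))
      impacts[[sb$image_id]] <- c(stats::setNames(imp_b, obj_ids_b),
                                  stats::setNames(person_imp, names(scene_people(sb))))
      pairs[[p]] <- winograd_pair(sa, sb)
      scenes[[sa$image_id]] <- sa
      scenes[[sb$image_id]] <- sb
    }
    ground_truth <- list(
      impacts = impacts,
      geometry = geometry,
      jitter_sd_deg = 0.3,     # per-observer spatial offset SD
      os_sigma_deg = 0.3,      # search-condition density SD on the target
      floor_frac = 0.10,       # uniform exploration floor in FV/SD density
      embed_spread = 0.8,      # cosine drop per unit impact
      duration_median_ms = 250,
      duration_sdlog = 0.35,
      seed = seed)
    list(pairs = pairs, scenes = scenes, ground_truth = ground_truth)
  })
}

# Rejection-sample non-overlapping boxes (objects + one person region).
place_boxes <- function(n_obj, w, h, max_tries = 4000L) {
  boxes <- list()
  # person region: a taller box, placed first
  pw <- round(stats::runif(1, 0.14, 0.20) * w)
  ph <- round(stats::runif(1, 0.35, 0.50) * h)
  px <- round(stats::runif(1, 0, w - pw))
  py <- round(stats::runif(1, 0.1 * h, h - ph))
  person <- c(px, py, px + pw, py + ph)
  placed <- list(person)
  for (i in seq_len(n_obj)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      bw <- round(stats::runif(1, 0.09, 0.16) * w)
      bh <- round(stats::runif(1, 0.11, 0.19) * h)
      bx <- round(stats::runif(1, 0, w - bw))
      by <- round(stats::runif(1, 0, h - bh))
      cand <- c(bx, by, bx + bw, by + bh)
      overlap <- any(vapply(placed, function(q) {
        cand[1L] < q[3L] && q[1L] < cand[3L] && cand[2L] < q[4L] && q[2L] < cand[4L]
      }, logical(1L)))
      if (!overlap) { ok <- TRUE; break }
    }
    if (!ok) stopf("grid %dx%d too small to place %d non-overlapping boxes", w, h, n_obj)
    placed <- c(placed, list(cand))
    boxes[[i]] <- cand
  }
  list(boxes = boxes, person = person)
}

#' Condition-specific generative fixation density
#'
#' The probability field each condition's fixations are drawn from:
#' FV and SD share a people-inclusive, impact-proportional Gaussian
#' mixture with a uniform exploration floor; OS is a Gaussian on the
#' search target; CO spreads mass equally across object boxes (uniform
#' within each box). Sums to 1 over the scene grid.
#'
#' @param scene A [scene_spec()].
#' @param ground_truth The `ground_truth` component of [generate_scene_set()].
#' @param condition One of `"FV"`, `"SD"`, `"OS"`, `"CO"`.
#' @return A `height_px x width_px` matrix summing to 1.
#' @export
condition_density <- function(scene, ground_truth, condition) {
  if (!condition %in% CONDITIONS) {
    stopf("unknown condition '%s' (expected FV, SD, OS or CO)", condition)
  }
  geometry <- ground_truth$geometry
  w <- scene$width_px; h <- scene$height_px
  if (condition %in% c("FV", "SD")) {
    impacts <- ground_truth$impacts[[scene$image_id]]
    g <- gaussian_mixture_map(scene, impacts, sum_config(), geometry,
                              combine = "sum")
    if (sum(g) <= 0) stopf("degenerate impact weights for scene '%s'", scene$image_id)
    fl <- ground_truth$floor_frac
    d <- (1 - fl) * g / sum(g) + fl / (w * h)
  } else if (condition == "OS") {
    tgt <- scene$elements[[scene$search_target_id]]
    if (is.null(tgt)) stopf("scene '%s' has no search target", scene$image_id)
    ctr <- box_center(tgt)
    sx <- deg_to_px(geometry, ground_truth$os_sigma_deg, "horizontal")
    sy <- deg_to_px(geometry, ground_truth$os_sigma_deg, "vertical")
    gx <- stats::dnorm(seq_len(w) - 1, ctr[1L], sx)
    gy <- stats::dnorm(seq_len(h) - 1, ctr[2L], sy)
    d <- outer(gy, gx)
    d <- d / sum(d)
  } else { # CO: equal total mass per object box
    d <- matrix(0, h, w)
    objs <- scene_objects(scene)
    for (e in objs) {
      xs <- seq.int(floor(e$box[1L]) + 1L, ceiling(e$box[3L]))
      ys <- seq.int(floor(e$box[2L]) + 1L, ceiling(e$box[4L]))
      d[ys, xs] <- d[ys, xs] + 1 / (length(xs) * length(ys) * length(objs))
    }
    d <- d / sum(d)
  }
  d
}

#' Generate removal-impact rating tables
#'
#' Emulates raters judging the similarity (1-10, 10 = highly similar)
#' between the gold-standard description and the description of the
#' scene with one element removed. The generative model is
#' `round(clip(10 - 9 * impact + Normal(0, noise_sd), 1, 10))`, so
#' high-impact elements receive low similarity ratings.
#'
#' @param pairs List of [winograd_pair()] from [generate_scene_set()].
#' @param ground_truth Matching ground truth.
#' @param n_raters Raters per removed element (study default 18).
#' @param noise_sd Rater noise SD in rating units.
#' @param seed Integer seed.
#' @return A data.frame with columns `scene_id`, `rater_id`,
#'   `element_id`, `rating`.
#' @export
generate_ratings <- function(pairs, ground_truth, n_raters = 18L,
                             noise_sd = 1, seed = 1L) {
  if (!is_count(n_raters)) stopf("n_raters must be a positive integer")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  with_seed(seed, {
    out <- list()
    for (pr in pairs) {
      for (scene in list(pr$scene_a, pr$scene_b)) {
        impacts <- ground_truth$impacts[[scene$image_id]]
        eids <- names(impacts)
        n <- length(eids) * n_raters
        raw <- 10 - 9 * rep(impacts, each = n_raters) +
          stats::rnorm(n, 0, noise_sd)
        rating <- as.integer(round(pmin(pmax(raw, 1), 10)))
        out[[scene$image_id]] <- data.frame(
          scene_id = scene$image_id,
          rater_id = sprintf("r%02d", rep(seq_len(n_raters), times = length(eids))),
          element_id = rep(eids, each = n_raters),
          rating = rating,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Generate a condition's fixation dataset
#'
#' Each observer views every scene of one stimulus set for one trial.
#' A trial starts with a central fixation, followed by i.i.d. draws
#' from the condition's generative density ([condition_density()]),
#' offset by a per-observer spatial jitter. Durations are LogNormal.
#'
#' @param pairs,ground_truth Output of [generate_scene_set()].
#' @param condition `"FV"`, `"SD"`, `"OS"` or `"CO"`.
#' @param n_observers Observers per image (study default 25).
#' @param fixations_per_trial Fixations per 2-s trial (default 9).
#' @param seed Integer seed.
#' @return A tidy data.frame: `observer_id`, `condition`, `image_id`,
#'   `fix_index`, `x_px`, `y_px`, `duration_ms`.
#' @export
generate_fixation_dataset <- function(pairs, ground_truth, condition,
                                      n_observers = 25L,
                                      fixations_per_trial = 9L, seed = 1L) {
  if (!condition %in% CONDITIONS) {
    stopf("unknown condition '%s' (expected FV, SD, OS or CO)", condition)
  }
  if (!is_count(n_observers)) stopf("n_observers must be a positive integer")
  if (!is_count(fixations_per_trial)) {
    stopf("fixations_per_trial must be a positive integer")
  }
  geometry <- ground_truth$geometry
  jx <- deg_to_px(geometry, ground_truth$jitter_sd_deg, "horizontal")
  jy <- deg_to_px(geometry, ground_truth$jitter_sd_deg, "vertical")
  with_seed(seed, {
    # one observer panel per stimulus set
    obs_ids <- lapply(1:2, function(s) {
      sprintf("%s_s%d_o%02d", condition, s, seq_len(n_observers))
    })
    jitter <- lapply(1:2, function(s) {
      cbind(stats::rnorm(n_observers, 0, jx), stats::rnorm(n_observers, 0, jy))
    })
    out <- list()
    for (pr in pairs) {
      for (scene in list(pr$scene_a, pr$scene_b)) {
        s <- scene$set_id
        w <- scene$width_px; h <- scene$height_px
        dens <- condition_density(scene, ground_truth, condition)
        nf <- fixations_per_trial - 1L
        n_draw <- n_observers * nf
        if (n_draw > 0) {
          idx <- sample.int(w * h, n_draw, replace = TRUE, prob = as.vector(dens))
          # matrix is column-major: row = y, col = x
          y <- ((idx - 1L) %% h) + stats::runif(n_draw) - 1
          x <- ((idx - 1L) %/% h) + stats::runif(n_draw) - 1
          x <- x + rep(jitter[[s]][, 1L], each = nf)
          y <- y + rep(jitter[[s]][, 2L], each = nf)
        } else {
          x <- numeric(0); y <- numeric(0)
        }
        n_total <- n_observers * fixations_per_trial
        xs <- numeric(n_total); ys <- numeric(n_total)
        pos <- rep(seq_len(fixations_per_trial), times = n_observers)
        xs[pos == 1L] <- w / 2; ys[pos == 1L] <- h / 2
        xs[pos != 1L] <- x; ys[pos != 1L] <- y
        out[[scene$image_id]] <- data.frame(
          observer_id = rep(obs_ids[[s]], each = fixations_per_trial),
          condition = condition,
          image_id = scene$image_id,
          fix_index = pos,
          x_px = pmin(pmax(xs, 0), w - 1e-6),
          y_px = pmin(pmax(ys, 0), h - 1e-6),
          duration_ms = stats::rlnorm(n_total,
                                      log(ground_truth$duration_median_ms),
                                      ground_truth$duration_sdlog),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Generate synthetic description embeddings
#'
#' Builds an embedding store mirroring the description-similarity
#' pipeline: five gold-standard vectors per scene, one removal vector
#' per element whose cosine to the gold direction decreases linearly
#' with true impact (`cos = 1 - impact * spread`), and forced-fixation
#' candidate vectors ("relevant" fixators close to the gold direction,
#' "irrelevant" fixators further away).
#'
#' @param pairs,ground_truth Output of [generate_scene_set()].
#' @param dim Embedding dimension (>= 2).
#' @param noise Angular noise added to every constructed vector.
#' @param n_forced Observers per forced-fixation group (study used 15).
#' @param seed Integer seed.
#' @return An `embedding_set`: list with `vectors` (matrix, one row per
#'   description) and `index` (data.frame `scene_id`, `role`,
#'   `observer_id`, `row`). Roles are `gold`, `removal:<element_id>`,
#'   `forced_fix:relevant`, `forced_fix:irrelevant`.
#' @export
generate_description_embeddings <- function(pairs, ground_truth, dim = 64L,
                                            noise = 0.05, n_forced = 15L,
                                            seed = 1L) {
  if (dim < 2) stopf("dim must be >= 2")
  spread <- ground_truth$embed_spread
  with_seed(seed, {
    vecs <- list(); idx <- list(); row <- 0L
    add <- function(scene_id, role, observer_id, v) {
      row <<- row + 1L
      vecs[[row]] <<- v
      idx[[row]] <<- data.frame(scene_id = scene_id, role = role,
                                observer_id = observer_id, row = row,
                                stringsAsFactors = FALSE)
    }
    for (pr in pairs) {
      for (scene in list(pr$scene_a, pr$scene_b)) {
        g <- unit_vector(stats::rnorm(dim))
        for (k in seq_len(5L)) {
          add(scene$image_id, "gold", sprintf("gold%02d", k),
              noisy_at_cosine(g, 0.97, noise))
        }
        impacts <- ground_truth$impacts[[scene$image_id]]
        for (eid in names(impacts)) {
          target <- max(min(1 - impacts[[eid]] * spread, 1), -1)
          add(scene$image_id, paste0("removal:", eid), NA_character_,
              noisy_at_cosine(g, target, noise))
        }
        for (k in seq_len(n_forced)) {
          add(scene$image_id, "forced_fix:relevant", sprintf("ffr%02d", k),
              noisy_at_cosine(g, 0.80, noise))
          add(scene$image_id, "forced_fix:irrelevant", sprintf("ffi%02d", k),
              noisy_at_cosine(g, 0.50, noise))
        }
      }
    }
    structure(list(vectors = do.call(rbind, vecs),
                   index = do.call(rbind, c(idx, list(make.row.names = FALSE)))),
              class = "embedding_set")
  })
}

unit_vector <- function(v) v / sqrt(sum(v^2))

# Unit vector at the given cosine from g, plus isotropic noise.
# noise = 0 hits the target cosine exactly.
noisy_at_cosine <- function(g, target_cos, noise) {
  u <- stats::rnorm(length(g))
  u <- u - sum(u * g) * g
  u <- unit_vector(u)
  v <- target_cos * g + sqrt(max(0, 1 - target_cos^2)) * u
  if (noise > 0) v <- v + stats::rnorm(length(g), 0, noise)
  unit_vector(v)
}

#' Simulate a complete four-condition study
#'
#' Convenience wrapper chaining the generators: scene set, all four
#' conditions' fixation datasets, rating tables and description
#' embeddings, with stage seeds derived deterministically from `seed`.
#'
#' @param n_pairs Winograd pairs (study used 18).
#' @param n_observers Observers per image per condition (study used 25).
#' @param objects_per_scene Objects per scene (5-10).
#' @param grid Scene grid `c(width_px, height_px)`.
#' @param fixations_per_trial Fixations per 2-s trial.
#' @param n_raters Raters per removed element.
#' @param rating_noise_sd Rater noise SD.
#' @param seed Global seed.
#' @return A dataset bundle consumable by [run_pipeline()]: `scenes`,
#'   `pairs`, `trials` (all conditions), `ratings`, `embeddings`,
#'   `ground_truth`, `geometry`.
#' @export
simulate_study <- function(n_pairs = 18L, n_observers = 25L,
                           objects_per_scene = 6L, grid = c(320L, 256L),
                           fixations_per_trial = 9L, n_raters = 18L,
                           rating_noise_sd = 1, seed = 1L) {
  ss <- generate_scene_set(n_pairs, objects_per_scene, grid,
                           seed = derive_seed(seed, 1L))
  gt <- ss$ground_truth
  trials <- do.call(rbind, lapply(seq_along(CONDITIONS), function(i) {
    generate_fixation_dataset(ss$pairs, gt, CONDITIONS[i], n_observers,
                              fixations_per_trial,
                              seed = derive_seed(seed, 1L + i))
  }))
  ratings <- generate_ratings(ss$pairs, gt, n_raters, rating_noise_sd,
                              seed = derive_seed(seed, 6L))
  embeddings <- generate_description_embeddings(ss$pairs, gt,
                                                seed = derive_seed(seed, 7L))
  list(scenes = ss$scenes, pairs = ss$pairs, trials = trials,
       ratings = ratings, embeddings = embeddings, ground_truth = gt,
       geometry = gt$geometry)
}
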