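# File formats and the pipeline that chains all stages. All formats are
# plain text: JSON for scene annotations, CSV for fixations / ratings /
# embeddings / results, YAML for the run manifest.

#' Write and read scene annotations (JSON)
#'
#' One record per scene: image/pair/set ids, grid size, elements with
#' class and box, and optional search target and grasp/gaze votes.
#'
#' @param scenes Named list of [scene_spec()] objects.
#' @param path Output JSON path.
#' @return `read_scenes()` returns the named list of scenes.
#' @export
write_scenes <- function(scenes, path) {
  recs <- lapply(unname(scenes), function(s) {
    list(image_id = s$image_id, pair_id = s$pair_id, set_id = s$set_id,
         width_px = s$width_px, height_px = s$height_px,
         elements = lapply(unname(s$elements), function(e) {
           list(element_id = e$element_id, label = e$label,
                element_class = e$element_class, box = e$box)
         }),
         search_target_id = s$search_target_id,
         grasp_gaze_votes = as.list(s$grasp_gaze_votes))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scenes
#' @export
read_scenes <- function(path) {
  recs <- jsonlite::read_json(path)
  scenes <- lapply(recs, function(r) {
    els <- lapply(r$elements, function(e) {
      object_box(e$element_id, e$label, unlist(e$box), e$element_class)
    })
    votes <- if (length(r$grasp_gaze_votes)) {
      unlist(r$grasp_gaze_votes)
    } else NULL
    scene_spec(r$image_id, r$pair_id, r$set_id, r$width_px, r$height_px, els,
               search_target_id = r$search_target_id, grasp_gaze_votes = votes)
  })
  stats::setNames(scenes, vapply(scenes, function(s) s$image_id, character(1L)))
}

# Rebuild Winograd pairs from a scene list (two scenes per pair_id).
pairs_from_scenes <- function(scenes) {
  by_pair <- split(scenes, vapply(scenes, function(s) s$pair_id, character(1L)))
  lapply(by_pair, function(two) {
    if (length(two) != 2L) {
      stopf("pair '%s' has %d scenes; exactly two required",
            two[[1L]]$pair_id, length(two))
    }
    ord <- order(vapply(two, function(s) s$set_id, integer(1L)))
    winograd_pair(two[[ord[1L]]], two[[ord[2L]]])
  })
}

#' Write and read fixation records (CSV)
#'
#' Columns: `observer_id`, `condition`, `image_id`, `fix_index`,
#' `x_px`, `y_px`, `duration_ms`.
#'
#' @param trials Fixation data.frame.
#' @param path CSV path.
#' @param scenes Optional scene list for cross-reference validation.
#' @export
write_fixations <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixations
#' @export
read_fixations <- function(path, scenes = NULL) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "condition", "image_id", "fix_index", "x_px",
            "y_px", "duration_ms")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stopf("fixation CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(tr$duration_ms <= 0)) {
    stopf("fixation CSV row %d: nonpositive duration",
          which(tr$duration_ms <= 0)[1L])
  }
  if (!is.null(scenes)) {
    bad <- which(!tr$image_id %in% names(scenes))
    if (length(bad)) {
      stopf("fixation CSV row %d references unknown image_id '%s'",
            bad[1L], tr$image_id[bad[1L]])
    }
  }
  tr
}

#' Write and read rating tables (CSV)
#'
#' Columns: `scene_id`, `rater_id`, `element_id`, `rating` (1-10).
#'
#' @param ratings Rating data.frame.
#' @param path CSV path.
#' @param scenes Optional scene list for cross-reference validation.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path, scenes = NULL) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scene_id", "rater_id", "element_id", "rating")
  miss <- setdiff(need, names(rt))
  if (length(miss)) stopf("rating CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  bad <- which(rt$rating < 1 | rt$rating > 10 | rt$rating != floor(rt$rating))
  if (length(bad)) {
    stopf("rating CSV row %d: rating %s outside 1..10", bad[1L],
          rt$rating[bad[1L]])
  }
  if (!is.null(scenes)) {
    for (i in seq_len(nrow(rt))) {
      sc <- scenes[[rt$scene_id[i]]]
      if (is.null(sc)) {
        stopf("rating CSV row %d references unknown scene_id '%s'", i,
              rt$scene_id[i])
      }
      if (!rt$element_id[i] %in% names(sc$elements)) {
        stopf("rating CSV row %d references unknown element '%s'", i,
              rt$element_id[i])
      }
    }
  }
  rt
}

#' Write and read an embedding store (CSV pair)
#'
#' The vectors go to `<path>` (one row per description, plain numeric
#' CSV); the index (`scene_id`, `role`, `observer_id`, `row`) goes to
#' `<path>` with suffix `_index.csv`.
#'
#' @param emb An `embedding_set`.
#' @param path Path for the vector CSV.
#' @export
write_embeddings <- function(emb, path) {
  utils::write.csv(as.data.frame(emb$vectors), path, row.names = FALSE)
  utils::write.csv(emb$index, index_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  vectors <- as.matrix(utils::read.csv(path))
  index <- utils::read.csv(index_path(path), stringsAsFactors = FALSE)
  need <- c("scene_id", "role", "observer_id", "row")
  miss <- setdiff(need, names(index))
  if (length(miss)) stopf("embedding index missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(index$row < 1 | index$row > nrow(vectors))) {
    stopf("embedding index references rows outside the vector matrix")
  }
  dimnames(vectors) <- NULL
  structure(list(vectors = vectors, index = index), class = "embedding_set")
}

index_path <- function(path) sub("\\.csv$", "_index.csv", path)

#' Write and read a heat map (CSV + JSON sidecar)
#'
#' @param map A [heat_map()].
#' @param path Matrix CSV path; mask (if any) and meta go to sidecars.
#' @export
write_heatmap <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- sub("\\.csv$", "_meta.json", path)
  meta <- map$meta
  if (!is.null(map$mask)) {
    utils::write.table(map$mask * 1L, sub("\\.csv$", "_mask.csv", path),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    meta$has_mask <- TRUE
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  side <- sub("\\.csv$", "_meta.json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  mask <- NULL
  mask_path <- sub("\\.csv$", "_mask.csv", path)
  if (isTRUE(meta$has_mask) && file.exists(mask_path)) {
    mask <- as.matrix(utils::read.table(mask_path, sep = ",")) == 1
    dimnames(mask) <- NULL
  }
  heat_map(vals, mask = mask, meta = meta)
}

#' Load a cross-referenced dataset bundle
#'
#' Reads scene JSON, fixation CSV, rating CSV and (optionally) an
#' embedding store, validating every cross-reference (trial -> scene,
#' rating -> element).
#'
#' @param scene_path,fixation_path,rating_path,embedding_path File paths;
#'   the last two may be `NULL`.
#' @return List with `scenes`, `pairs`, `trials`, `ratings`, `embeddings`.
#' @export
load_dataset <- function(scene_path, fixation_path, rating_path = NULL,
                         embedding_path = NULL) {
  scenes <- read_scenes(scene_path)
  pairs <- pairs_from_scenes(scenes)
  trials <- read_fixations(fixation_path, scenes)
  ratings <- if (!is.null(rating_path)) read_ratings(rating_path, scenes) else NULL
  embeddings <- if (!is.null(embedding_path)) read_embeddings(embedding_path) else NULL
  list(scenes = scenes, pairs = pairs, trials = trials, ratings = ratings,
       embeddings = embeddings)
}

#' Write a full synthetic bundle to disk
#'
#' Serializes everything [generate_scene_set()] and friends produced,
#' plus a YAML manifest recording the generator parameters and seeds.
#'
#' @param dir Output directory (created if needed).
#' @param scenes,trials,ratings,embeddings Dataset components
#'   (`ratings`/`embeddings` may be `NULL`).
#' @param params List of generator parameters recorded in the manifest.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dir, scenes, trials, ratings = NULL,
                          embeddings = NULL, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scenes(scenes, file.path(dir, "scenes.json"))
  write_fixations(trials, file.path(dir, "fixations.csv"))
  if (!is.null(ratings)) write_ratings(ratings, file.path(dir, "ratings.csv"))
  if (!is.null(embeddings)) {
    write_embeddings(embeddings, file.path(dir, "embeddings.csv"))
  }
  manifest <- list(created = "gazesum synthetic bundle", params = params)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration plus the global seed from which
#' all stage seeds are derived deterministically.
#'
#' @param heatmap,sum,bootstrap,fdr,classifier Stage configurations.
#' @param n_sub,n_combos Observer-subset size and draw count for the
#'   correlation analyses.
#' @param K Maximum fixation index for cumulative curves.
#' @param exclude_people Run the people-excluded primary analyses?
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(heatmap = heatmap_config(),
                            sum = sum_config(),
                            bootstrap = bootstrap_config(n_resamples = 1000L),
                            fdr = fdr_config(),
                            classifier = classifier_config(),
                            n_sub = 12L, n_combos = 20L, K = 9L,
                            exclude_people = TRUE, seed = 1L) {
  list(heatmap = heatmap, sum = sum, bootstrap = bootstrap, fdr = fdr,
       classifier = classifier, n_sub = n_sub, n_combos = n_combos, K = K,
       exclude_people = exclude_people, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Chains every stage on a loaded dataset: SUM construction from the
#' rating tables, category assignment across Winograd pairs, pooled
#' heat maps per condition, across-condition and Winograd-pair
#' correlations, category fixation frequencies with bootstrap
#' inference, cumulative-difference curves, shuffled-AUC evaluation of
#' the SUM as a prediction map, description scoring (when embeddings
#' are supplied), and an FDR-adjusted inference report. Results are
#' written as tidy CSVs plus a YAML manifest; a rerun with the same
#' config and inputs is identical.
#'
#' @param dataset A [load_dataset()] bundle (or the in-memory
#'   equivalent from the generators).
#' @param geometry A [viewing_geometry()] for the scene grids.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of result tables (invisibly written to `out_dir`).
#' @export
run_pipeline <- function(dataset, geometry, config = pipeline_config(),
                         out_dir = NULL) {
  scenes <- dataset$scenes
  pairs <- dataset$pairs
  trials <- dataset$trials
  if (is.null(dataset$ratings)) stopf("pipeline requires rating tables")
  conds <- intersect(CONDITIONS, unique(trials$condition))
  seed <- config$seed

  # SUMs and categories
  sums <- list(); sums_people <- list()
  for (img in names(scenes)) {
    tab <- dataset$ratings[dataset$ratings$scene_id == img, , drop = FALSE]
    sc <- scenes[[img]]
    sums[[img]] <- build_sum(
      sc, aggregate_ratings(tab, sc, include_people = FALSE),
      config$sum, geometry)
    cfg_p <- config$sum; cfg_p$include_people <- TRUE
    sums_people[[img]] <- build_sum(
      sc, aggregate_ratings(tab, sc, include_people = TRUE), cfg_p, geometry)
  }
  assignments <- list()
  for (pr in pairs) {
    a <- pr$scene_a$image_id; b <- pr$scene_b$image_id
    asg <- assign_categories(pr, sums[[a]], sums[[b]],
                             people_scores = list(
                               sums_people[[a]]$element_scores,
                               sums_people[[b]]$element_scores))
    assignments[c(a, b)] <- asg
  }

  # Pooled heat maps per condition
  maps <- list()
  for (cond in conds) {
    maps[[cond]] <- lapply(scenes, function(sc) {
      build_heatmap(trials[trials$condition == cond &
                             trials$image_id == sc$image_id, , drop = FALSE],
                    sc, geometry, config$heatmap)
    })
  }

  # Across-condition correlations vs free viewing
  corr_rows <- list()
  if ("FV" %in% conds) {
    for (cond in setdiff(conds, "FV")) {
      res <- condition_pair_correlation(
        trials, scenes, c("FV", cond), geometry, config$heatmap,
        n_sub = config$n_sub, n_combos = config$n_combos,
        seed = derive_seed(seed, match(cond, CONDITIONS)))
      corr_rows[[cond]] <- data.frame(analysis = "condition_correlation",
                                      group = paste0("FV-", cond),
                                      statistic = "mean_r", value = res$mean_r)
    }
    within <- condition_pair_correlation(
      trials, scenes, "FV", geometry, config$heatmap, n_sub = config$n_sub,
      n_combos = config$n_combos, seed = derive_seed(seed, 9L))
    corr_rows[["FV-FV"]] <- data.frame(analysis = "condition_correlation",
                                       group = "FV-FV", statistic = "mean_r",
                                       value = within$mean_r)
  }

  # Winograd-pair correlations per condition + SUM prediction maps
  wino_rows <- list()
  for (cond in conds) {
    res <- winograd_correlation(pairs, maps[[cond]])
    wino_rows[[cond]] <- data.frame(analysis = "winograd_correlation",
                                    group = cond, statistic = "mean_r",
                                    value = res$mean_r)
  }
  sum_maps_hm <- lapply(sums, function(s) s$heat_map)
  wino_rows[["SUM"]] <- data.frame(
    analysis = "winograd_correlation", group = "SUM", statistic = "mean_r",
    value = winograd_correlation(pairs, sum_maps_hm)$mean_r)

  # Category fixation frequencies + bootstrap inference
  freq_tables <- list(); infer_rows <- list()
  for (cond in conds) {
    per_scene <- lapply(names(scenes), function(img) {
      fr <- category_fixation_frequency(
        trials[trials$condition == cond & trials$image_id == img, , drop = FALSE],
        scenes[[img]], assignments[[img]],
        weight_mode = config$heatmap$weight_mode,
        exclude_people = config$exclude_people)
      fr$image_id <- img
      fr
    })
    freq <- do.call(rbind, per_scene)
    freq$condition <- cond
    freq_tables[[cond]] <- freq
    wide <- freq[freq$category %in% c("su_relevant", "su_irrelevant"), ]
    diff_stat <- function(d) {
      mean(d$value[d$category == "su_relevant"]) -
        mean(d$value[d$category == "su_irrelevant"])
    }
    bcfg <- config$bootstrap
    bcfg$seed <- derive_seed(seed, 20L + match(cond, CONDITIONS))
    bt <- bootstrap_statistic(wide, diff_stat, bcfg)
    obs_mean <- tapply(wide$value, list(wide$observer_id, wide$category), mean)
    infer_rows[[cond]] <- data.frame(
      comparison_id = paste0(cond, ":su_relevant_vs_su_irrelevant"),
      statistic = "mean_frequency_difference",
      estimate = bt$estimate, ci68_low = bt$ci[1L], ci68_high = bt$ci[2L],
      p_one_tailed = bt$p,
      cohens_d = tryCatch(cohens_d(obs_mean[, "su_relevant"],
                                   obs_mean[, "su_irrelevant"]),
                          error = function(e) NA_real_),
      n_resamples = bt$n_resamples)
  }
  inference <- do.call(rbind, c(infer_rows, list(make.row.names = FALSE)))
  inference <- cbind(inference,
                     fdr_adjust(inference$p_one_tailed, config$fdr)["q"])

  # Cumulative difference curves
  curves <- list()
  for (cond in conds) {
    cv <- cumulative_difference_curve(
      trials[trials$condition == cond, , drop = FALSE], scenes, assignments,
      K = config$K, weight_mode = config$heatmap$weight_mode)
    cv$condition <- cond
    curves[[cond]] <- cv
  }

  # Shuffled AUC of the SUM prediction per condition (subsampled
  # observers keep this stage cheap; seed-derived, deterministic)
  sauc_rows <- list()
  for (cond in conds) {
    vals <- sauc_over_dataset(trials[trials$condition == cond, , drop = FALSE],
                              scenes, sum_maps_hm,
                              seed = derive_seed(seed, 40L + match(cond, CONDITIONS)))
    sauc_rows[[cond]] <- data.frame(analysis = "sauc", group = cond,
                                    statistic = "mean_sauc", value = mean(vals))
  }

  # Description scoring
  desc <- NULL
  if (!is.null(dataset$embeddings)) {
    emb <- dataset$embeddings
    rel <- score_against_gold(emb, "^forced_fix:relevant$")
    irr <- score_against_gold(emb, "^forced_fix:irrelevant$")
    bounds <- similarity_bounds(emb, seed = derive_seed(seed, 60L))
    desc <- list(relevant = rel, irrelevant = irr, bounds = bounds,
                 correctness = classify_correctness(
                   rbind(rel, irr)[, c("scene_id", "observer_id", "score")],
                   config$classifier))
  }

  results <- list(
    correlations = do.call(rbind, c(corr_rows, wino_rows, sauc_rows,
                                    list(make.row.names = FALSE))),
    frequencies = do.call(rbind, c(freq_tables, list(make.row.names = FALSE))),
    curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
    inference = inference,
    description = desc,
    sums = sums)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(results$frequencies,
                     file.path(out_dir, "frequencies.csv"), row.names = FALSE)
    utils::write.csv(results$curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(results$inference, file.path(out_dir, "inference.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("gazesum")),
      seed = seed,
      config_hash = rlang::hash(config),
      result_hash = rlang::hash(results[c("correlations", "frequencies",
                                          "curves", "inference")]))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(results)
}

# Mean sAUC of per-scene prediction maps over (observer, image) pairs.
sauc_over_dataset <- function(trials, scenes, prediction_maps, seed = 1L,
                              max_observers = 5L) {
  vals <- c()
  k <- 0L
  for (img in names(scenes)) {
    tr <- trials[trials$image_id == img, , drop = FALSE]
    obs <- utils::head(sort(unique(tr$observer_id)), max_observers)
    for (ob in obs) {
      pos <- tr[tr$observer_id == ob, , drop = FALSE]
      if (nrow(pos) == 0L) next
      k <- k + 1L
      neg <- build_negative_sets(trials, ob, img, nrow(pos),
                                 seed = derive_seed(seed, k))
      vals <- c(vals, sauc(prediction_maps[[img]], pos, neg))
    }
  }
  vals
}
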