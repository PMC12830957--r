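# Embedding-space scoring of scene descriptions. Embeddings are opaque
# numeric vectors supplied as data; no model or network calls.

#' Cosine similarity
#'
#' @param u,v Nonzero numeric vectors of equal dimension.
#' @return `u . v / (|u| |v|)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors have different dimensions")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Pick the gold-standard description by majority vote
#'
#' @param votes Named numeric vector: description id -> vote count.
#' @return The argmax id; ties go to the lowest id with a warning.
#' @export
select_gold_standard <- function(votes) {
  if (length(votes) == 0L) stopf("votes are empty")
  if (all(votes == 0)) stopf("all-zero votes: no gold standard can be selected")
  mx <- max(votes)
  hits <- sort(names(votes)[votes == mx])
  if (length(hits) > 1L) {
    warnf("tied votes for gold standard; taking lowest id '%s'", hits[1L])
  }
  hits[1L]
}

#' Configuration for correctness classification
#'
#' @param k_sd Multiplier on the per-scene SD below the mean that marks
#'   a description incorrect (study explored 0-2.5; default 1).
#' @param pool_scenes Compute one mean/SD pooled over all scenes rather
#'   than per scene?
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(k_sd = 1, pool_scenes = FALSE) {
  if (k_sd < 0) stopf("k_sd must be >= 0")
  list(k_sd = k_sd, pool_scenes = pool_scenes)
}

#' Classify described scenes as correct or incorrect
#'
#' An observer's description is incorrect iff its similarity score to
#' the gold standard falls strictly below `mean - k_sd * SD` (sample
#' SD) of that scene's scores.
#'
#' @param scores Data.frame with columns `scene_id`, `observer_id`,
#'   `score` (a human 1-10 rating or an embedding cosine — the
#'   classifier is agnostic to which).
#' @param config A [classifier_config()].
#' @return The input with a logical `correct` column appended.
#' @export
classify_correctness <- function(scores, config = classifier_config()) {
  need <- c("scene_id", "observer_id", "score")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    stopf("scores must have columns %s", paste(need, collapse = ", "))
  }
  grp <- if (config$pool_scenes) rep("all", nrow(scores)) else scores$scene_id
  counts <- table(grp)
  if (any(counts < 2L)) {
    stopf("need >= 2 scores per scene to compute a sample SD")
  }
  mu <- tapply(scores$score, grp, mean)
  sdv <- tapply(scores$score, grp, stats::sd)
  thr <- as.numeric(mu[grp]) - config$k_sd * as.numeric(sdv[grp])
  scores$correct <- !(scores$score < thr)
  scores
}

# Internal accessors for an embedding_set.
embedding_rows <- function(emb, scene_id = NULL, role = NULL) {
  ix <- emb$index
  sel <- rep(TRUE, nrow(ix))
  if (!is.null(scene_id)) sel <- sel & ix$scene_id == scene_id
  if (!is.null(role)) sel <- sel & grepl(role, ix$role)
  emb$vectors[ix$row[sel], , drop = FALSE]
}

#' Upper and lower similarity bounds
#'
#' Upper bound: the mean over scenes of the mean pairwise cosine among
#' each scene's gold-standard embeddings (inter-observer agreement with
#' unrestricted viewing). Lower bound: the mean cosine between a
#' scene's gold embedding and candidate descriptions drawn from *other*
#' scenes, over `n_permutations` random draws.
#'
#' @param emb An `embedding_set` (see
#'   [generate_description_embeddings()] or [read_embeddings()]).
#' @param candidate_role Regex for the candidate role used in the lower
#'   bound (default: forced-fixation descriptions).
#' @param n_permutations Random cross-scene draws (study used 1000).
#' @param seed Integer seed.
#' @return `list(upper =, lower =)`.
#' @export
similarity_bounds <- function(emb, candidate_role = "^forced_fix",
                              n_permutations = 1000L, seed = 1L) {
  scenes <- unique(emb$index$scene_id)
  if (length(scenes) < 2L) stopf("lower bound needs >= 2 scenes")
  upper_per_scene <- vapply(scenes, function(s) {
    g <- embedding_rows(emb, s, "^gold$")
    if (nrow(g) < 2L) stopf("scene '%s' has fewer than 2 gold embeddings", s)
    prs <- utils::combn(nrow(g), 2L)
    mean(apply(prs, 2L, function(ij) cosine_similarity(g[ij[1L], ], g[ij[2L], ])))
  }, numeric(1L))
  lower <- with_seed(seed, {
    draws <- vapply(seq_len(n_permutations), function(k) {
      s <- sample(scenes, 1L)
      g <- embedding_rows(emb, s, "^gold$")
      gold <- g[sample.int(nrow(g), 1L), ]
      other <- sample(setdiff(scenes, s), 1L)
      cand <- embedding_rows(emb, other, candidate_role)
      if (nrow(cand) == 0L) stopf("scene '%s' has no '%s' candidates", other,
                                  candidate_role)
      cosine_similarity(gold, cand[sample.int(nrow(cand), 1L), ])
    }, numeric(1L))
    mean(draws)
  })
  list(upper = mean(upper_per_scene), lower = lower)
}

#' Score candidate descriptions against each scene's gold standard
#'
#' @param emb An `embedding_set`.
#' @param role Regex selecting the candidate rows (e.g.
#'   `"^forced_fix:relevant$"` or `"^removal:"`).
#' @return Data.frame `scene_id`, `role`, `observer_id`, `score` — the
#'   mean cosine of each candidate against the scene's gold embeddings.
#' @export
score_against_gold <- function(emb, role) {
  ix <- emb$index
  sel <- which(grepl(role, ix$role))
  if (!length(sel)) stopf("no embeddings match role '%s'", role)
  gold_by_scene <- lapply(stats::setNames(nm = unique(ix$scene_id)),
                          function(s) embedding_rows(emb, s, "^gold$"))
  out <- lapply(sel, function(i) {
    g <- gold_by_scene[[ix$scene_id[i]]]
    v <- emb$vectors[ix$row[i], ]
    data.frame(scene_id = ix$scene_id[i], role = ix$role[i],
               observer_id = ix$observer_id[i],
               score = mean(apply(g, 1L, cosine_similarity, v = v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
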