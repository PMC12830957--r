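# Resampling-based inference: hierarchical bootstrap over participants
# and images, one-tailed p-values, Cohen's d, and BH/BY FDR control.

#' Bootstrap configuration
#'
#' @param n_resamples Bootstrap resamples (study defaults: 100,000 for
#'   scalar statistics, 10,000 for map correlations).
#' @param resample_units Character vector of data columns to resample
#'   with replacement (e.g. `c("image_id", "observer_id")`).
#' @param tail Tested direction of the statistic: `"greater"` (H1:
#'   statistic > 0) or `"less"`. One-tailed throughout; the direction
#'   is declared here, never inferred from the data.
#' @param ci_level Confidence level for the percentile CI (default 0.68).
#' @param seed Integer seed.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_resamples = 10000L,
                             resample_units = c("image_id", "observer_id"),
                             tail = c("greater", "less"),
                             ci_level = 0.68, seed = 1L) {
  if (!is_count(n_resamples)) stopf("n_resamples must be a positive integer")
  if (length(resample_units) == 0L) stopf("resample_units must be nonempty")
  if (ci_level <= 0 || ci_level >= 1) stopf("ci_level must be in (0, 1)")
  list(n_resamples = as.integer(n_resamples), resample_units = resample_units,
       tail = match.arg(tail), ci_level = ci_level, seed = seed)
}

# One hierarchical resample: resample levels of each unit column with
# replacement, sequentially (images, then participants within the
# resampled design). idx_maps caches the row-index split per column.
resample_rows <- function(data, units, idx_maps) {
  rows <- seq_len(nrow(data))
  for (u in units) {
    lv <- idx_maps[[u]]
    grp <- lv$by[rows]
    split_rows <- split(rows, grp)
    sampled <- sample(names(split_rows), length(split_rows), replace = TRUE)
    rows <- unlist(split_rows[sampled], use.names = FALSE)
  }
  rows
}

#' Bootstrap a statistic with a one-tailed p-value
#'
#' Hierarchically resamples the configured unit columns with
#' replacement, recomputes the statistic on each resample, and reports
#' the point estimate, a percentile CI, and the one-tailed p-value: the
#' fraction of resamples on the null side of zero, floored at
#' `1/(n_resamples + 1)` so a p of exactly 0 is never reported.
#'
#' @param data A data.frame; `config$resample_units` must be columns.
#' @param statistic Function `data.frame -> scalar`.
#' @param config A [bootstrap_config()].
#' @return List: `estimate`, `ci` (length 2), `p`, `boot` (the resample
#'   distribution), `n_failed`.
#' @export
bootstrap_statistic <- function(data, statistic, config = bootstrap_config()) {
  for (u in config$resample_units) {
    if (!u %in% names(data)) stopf("resample unit '%s' is not a column", u)
    if (length(unique(data[[u]])) < 2L) {
      stopf("need >= 2 distinct '%s' units to resample", u)
    }
  }
  est <- statistic(data)
  idx_maps <- lapply(stats::setNames(nm = config$resample_units),
                     function(u) list(by = as.character(data[[u]])))
  B <- config$n_resamples
  boot <- numeric(B)
  n_failed <- 0L
  with_seed(config$seed, {
    for (b in seq_len(B)) {
      val <- NA_real_
      for (try in 1:3) {
        rows <- resample_rows(data, config$resample_units, idx_maps)
        val <- tryCatch(statistic(data[rows, , drop = FALSE]),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_failed <- n_failed + 1L
      }
      boot[b] <- val
    }
  })
  if (n_failed > 0.01 * B) {
    stopf("statistic failed on %d resamples (> 1%%)", n_failed)
  }
  boot_ok <- boot[is.finite(boot)]
  p_raw <- if (config$tail == "greater") mean(boot_ok <= 0) else mean(boot_ok >= 0)
  p <- max(p_raw, 1 / (B + 1))
  a <- (1 - config$ci_level) / 2
  ci <- unname(stats::quantile(boot_ok, c(a, 1 - a), names = FALSE))
  list(estimate = est, ci = ci, p = p, boot = boot_ok, n_failed = n_failed,
       tail = config$tail, n_resamples = B)
}

#' Cohen's d for two independent groups
#'
#' `(mean_a - mean_b)` over the pooled standard deviation with
#' `(n_a + n_b - 2)` degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors.
#' @return Scalar effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs >= 2 observations")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (sp2 <= 0) stopf("zero pooled SD: effect size undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' FDR configuration
#'
#' @param alpha Nominal false discovery rate (default 0.05).
#' @param method `"BH"` (independent / positively dependent
#'   comparisons) or `"BY"` (arbitrary dependence, e.g. successive
#'   cumulative-fixation comparisons).
#' @return An `fdr_config` list.
#' @export
fdr_config <- function(alpha = 0.05, method = c("BH", "BY")) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  list(alpha = alpha, method = match.arg(method))
}

#' Adjust p-values for the false discovery rate
#'
#' Step-up adjustment: `q_(i) = min over j >= i of min(1, p_(j) * m/j)`
#' for BH; BY additionally multiplies by `c(m) = sum_{j<=m} 1/j`.
#' Delegates to [stats::p.adjust()]; output order matches input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param config An [fdr_config()].
#' @return Data.frame with `p`, `q`, and `significant` (`q <= alpha`).
#' @export
fdr_adjust <- function(pvals, config = fdr_config()) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = config$method)
  data.frame(p = pvals, q = as.numeric(q), significant = q <= config$alpha)
}
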