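#' Constrained feature pools for the combination search
#'
#' The search space is constrained anatomically/physiologically: each
#' candidate combination takes exactly one prefrontal-cortex feature, one
#' visual-cortex feature and three systemic features. Task performance is
#' not part of any default pool (it has a low and insignificant impact on
#' classification and is not a systemic physiological parameter) but may be
#' added to `systemic`.
#'
#' @param pfc,vc,systemic character vectors of feature names; pools must be
#'   pairwise disjoint and `systemic` must have at least 3 entries.
#' @return an object of class `feature_pools`.
#' @examples
#' feature_pools()
#' @export
feature_pools <- function(pfc = spa_parameters("PFC"),
                          vc = spa_parameters("VC"),
                          systemic = spa_parameters("systemic")) {
  pools <- list(pfc = as.character(pfc), vc = as.character(vc),
                systemic = as.character(systemic))
  all_names <- unlist(pools)
  if (anyDuplicated(all_names))
    stopf("pools must be disjoint; duplicated: %s",
          paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  if (!length(pools$pfc) || !length(pools$vc))
    stopf("pfc and vc pools must be non-empty")
  if (length(pools$systemic) < 3)
    stopf("systemic pool must contain >= 3 features")
  structure(pools, class = "feature_pools")
}

#' @export
print.feature_pools <- function(x, ...) {
  cat(sprintf("<feature_pools> %d PFC x %d VC x C(%d systemic, 3) = %d combinations\n",
              length(x$pfc), length(x$vc), length(x$systemic),
              length(x$pfc) * length(x$vc) * choose(length(x$systemic), 3)))
  invisible(x)
}

#' Enumerate all constrained 5-feature combinations
#'
#' Produces every subset of one PFC + one VC + three systemic features, in
#' deterministic lexicographic order (pools sorted alphabetically). The
#' count is `|pfc| * |vc| * C(|systemic|, 3)`; with the default pools
#' (4, 4, 6) that is 320.
#'
#' @param pools a [feature_pools()].
#' @return character matrix with 5 columns (`pfc`, `vc`, `sys1..sys3`),
#'   one row per combination, no duplicates.
#' @examples
#' nrow(enumerate_combinations(feature_pools()))
#' @export
enumerate_combinations <- function(pools = feature_pools()) {
  if (!inherits(pools, "feature_pools"))
    stopf("pools must be a feature_pools object")
  pfc <- sort(pools$pfc); vc <- sort(pools$vc)
  sys_triples <- combn(sort(pools$systemic), 3)
  out <- matrix(NA_character_,
                nrow = length(pfc) * length(vc) * ncol(sys_triples),
                ncol = 5,
                dimnames = list(NULL, c("pfc", "vc", "sys1", "sys2", "sys3")))
  i <- 0L
  for (p in pfc) for (v in vc) for (j in seq_len(ncol(sys_triples))) {
    i <- i + 1L
    out[i, ] <- c(p, v, sys_triples[, j])
  }
  out
}

#' Score one 5-feature combination across conditions
#'
#' For each condition: restrict the normalized feature table to the
#' combination, project with PCA at the explained-variance threshold, run
#' k-means at every `k` in the range and record the best mean silhouette
#' and the `k` achieving it. A combination whose restricted columns are all
#' constant in some condition is recorded as failed (`NA` scores) rather
#' than erroring, so the exhaustive search stays total.
#'
#' @param tables named list of normalized [feature_table()]s, one per
#'   condition.
#' @param combo character vector of 5 feature names.
#' @param k_range candidate cluster numbers (default 2..9).
#' @param seed integer seed (k-means restarts are seeded per `k`).
#' @param variance_threshold PCA explained-variance threshold.
#' @param threshold silhouette cutoff defining `passes_threshold`.
#' @param nstart k-means restarts per `k` (default 10 for search speed).
#' @return an object of class `combination_score`: `features`,
#'   `per_condition` (best_silhouette and best_k per condition),
#'   `passes_threshold`, `rank_score` (mean of per-condition best
#'   silhouettes).
#' @export
score_combination <- function(tables, combo, k_range = 2:9, seed = 1,
                              variance_threshold = 0.8, threshold = 0.6,
                              nstart = 10) {
  if (!length(tables) || is.null(names(tables)))
    stopf("tables must be a named per-condition list")
  combo <- as.character(combo)
  per_condition <- lapply(tables, function(tab) {
    if (!inherits(tab, "feature_table")) stopf("tables must hold feature_table objects")
    missing <- setdiff(combo, tab$features)
    if (length(missing))
      stopf("combination feature(s) absent from table: %s",
            paste(missing, collapse = ", "))
    x <- tab$values[, combo, drop = FALSE]
    if (all(apply(x, 2, function(col) min(col) == max(col))))
      return(list(best_silhouette = NA_real_, best_k = NA_integer_))
    proj <- pca_project(x, variance_threshold)
    scores <- proj$scores
    dmat <- as.matrix(dist(scores))
    best_sil <- -Inf; best_k <- NA_integer_
    for (k in k_range) {
      res <- tryCatch(
        run_method(scores, "kmeans", k = k,
                   seed = substream_seed(seed, k),
                   params = list(nstart = nstart)),
        error = function(e) NULL)
      if (is.null(res)) next
      sil <- mean(.silhouette_from_dmat(dmat, res$labels))
      if (sil > best_sil) { best_sil <- sil; best_k <- as.integer(k) }
    }
    if (!is.finite(best_sil))
      return(list(best_silhouette = NA_real_, best_k = NA_integer_))
    list(best_silhouette = best_sil, best_k = best_k)
  })
  sils <- vapply(per_condition, `[[`, numeric(1), "best_silhouette")
  structure(
    list(features = combo, per_condition = per_condition,
         passes_threshold = all(!is.na(sils)) && all(sils > threshold),
         rank_score = if (any(is.na(sils))) NA_real_ else mean(sils),
         threshold = threshold),
    class = "combination_score"
  )
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("<combination_score> {%s}: %s | rank %.3f\n",
              paste(x$features, collapse = ", "),
              paste(vapply(names(x$per_condition), function(cd)
                sprintf("%s s=%.2f k=%s", cd,
                        x$per_condition[[cd]]$best_silhouette,
                        x$per_condition[[cd]]$best_k), character(1)),
                collapse = " | "),
              x$rank_score))
  invisible(x)
}

scores_to_frame <- function(scores, conditions) {
  do.call(rbind, lapply(scores, function(s) {
    row <- data.frame(features = paste(s$features, collapse = ", "),
                      stringsAsFactors = FALSE)
    for (cd in conditions) {
      row[[paste0("best_k_", cd)]] <- s$per_condition[[cd]]$best_k
      row[[paste0("silhouette_", cd)]] <-
        s$per_condition[[cd]]$best_silhouette
    }
    row$passes_threshold <- s$passes_threshold
    row$rank_score <- s$rank_score
    row
  }))
}

#' Select and rank the best common combinations
#'
#' Keeps the combinations whose best silhouette is strictly above the
#' threshold in every condition, ranks them by the mean of their
#' per-condition best silhouettes (descending; ties broken
#' lexicographically by feature names for determinism) and returns the top
#' rows — the best-common-combinations summary table.
#'
#' @param scores list of `combination_score` objects.
#' @param threshold silhouette cutoff (strict inequality), default 0.6.
#' @param top_n number of rows to report (all passing rows if fewer pass).
#' @return data frame with the features, per-condition best `k` and
#'   silhouette, and the rank score. Zero rows (with a warning) when no
#'   combination passes.
#' @export
select_common_combinations <- function(scores, threshold = 0.6, top_n = 5) {
  if (!length(scores)) stopf("scores must be non-empty")
  conditions <- names(scores[[1]]$per_condition)
  df <- scores_to_frame(scores, conditions)
  sil_cols <- paste0("silhouette_", conditions)
  pass <- rep(TRUE, nrow(df))
  for (cl in sil_cols) pass <- pass & !is.na(df[[cl]]) & df[[cl]] > threshold
  kept <- df[pass, , drop = FALSE]
  if (!nrow(kept)) {
    warnf("no combination exceeds silhouette %g in every condition",
          threshold)
    return(kept)
  }
  kept <- kept[order(-kept$rank_score, kept$features), , drop = FALSE]
  rownames(kept) <- NULL
  head(kept, top_n)
}

#' Exhaustive constrained combination search
#'
#' The end-to-end subset-selection stage: enumerate all constrained
#' combinations, score each per condition with k-means + silhouette over
#' the `k` range ([score_combination()]), then filter and rank the common
#' passers ([select_common_combinations()]).
#'
#' @param tables named list of normalized [feature_table()]s per condition.
#' @param pools a [feature_pools()].
#' @param k_range,seed,variance_threshold,nstart passed to
#'   [score_combination()]; each combination gets its own seed substream.
#' @param threshold,top_n passed to [select_common_combinations()].
#' @return list with `top` (the ranked summary data frame), `all_scores`
#'   (data frame over every combination), `best_features` (character
#'   vector of the top-ranked combination, or `NULL` if none passed) and
#'   `scores` (the raw `combination_score` list).
#' @export
search_features <- function(tables, pools = feature_pools(), k_range = 2:9,
                            threshold = 0.6, top_n = 5, seed = 1,
                            variance_threshold = 0.8, nstart = 10) {
  combos <- enumerate_combinations(pools)
  scores <- lapply(seq_len(nrow(combos)), function(i)
    score_combination(tables, combos[i, ], k_range = k_range,
                      seed = substream_seed(seed, i),
                      variance_threshold = variance_threshold,
                      threshold = threshold, nstart = nstart))
  top <- select_common_combinations(scores, threshold = threshold,
                                    top_n = top_n)
  best <- if (nrow(top)) strsplit(top$features[1], ", ", fixed = TRUE)[[1]]
          else NULL
  list(top = top,
       all_scores = scores_to_frame(scores, names(tables)),
       best_features = best, scores = scores)
}
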