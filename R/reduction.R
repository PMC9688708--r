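#' Min-max normalization of a feature table
#'
#' Maps every feature column onto `[0, 1]` by `(x - min) / (max - min)`,
#' bringing all features to a comparable scale while exactly preserving
#' within-column rank order. A constant column carries no information and
#' is mapped to all zeros with a warning rather than an error, so that
#' exhaustive combination searches stay total.
#'
#' @param table a [feature_table()] with at least 2 rows.
#' @return a [feature_table()] with provenance `"normalized"`.
#' @examples
#' ft <- generate_feature_table(cohort_spec(n_subjects = 8, seed = 1))
#' range(min_max_normalize(ft$blue$table)$values)
#' @export
min_max_normalize <- function(table) {
  if (!inherits(table, "feature_table")) stopf("table must be a feature_table")
  v <- table$values
  if (nrow(v) < 2) stopf("min-max normalization requires >= 2 rows")
  out <- apply(v, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  })
  const <- colnames(v)[apply(v, 2, function(x) min(x) == max(x))]
  if (length(const))
    warnf("constant feature column(s) normalized to 0: %s",
          paste(const, collapse = ", "))
  dimnames(out) <- dimnames(v)
  feature_table(out, condition = table$condition, provenance = "normalized")
}

#' PCA projection at an explained-variance threshold
#'
#' Mean-centers the columns (no further rescaling: min-max normalization is
#' the scaling step) and projects onto the smallest number of leading
#' principal components whose cumulative explained variance reaches the
#' threshold. Each loading vector's largest-magnitude element is made
#' positive so score plots are reproducible across runs and backends.
#'
#' @param x a [feature_table()] or numeric matrix (>= 2 rows).
#' @param variance_threshold fraction in (0, 1]; default 0.8, i.e. retain
#'   components explaining at least 80% of the variance.
#' @return an object of class `projected_data` with elements `scores`
#'   (subjects x retained components), `explained_variance_ratio` (all
#'   components), `n_components`, `component_loadings` (features x retained
#'   components, orthonormal columns) and `centering_means`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4, dimnames = list(1:10, letters[1:4]))
#' pca_project(m, 0.8)$n_components
#' @export
pca_project <- function(x, variance_threshold = 0.8) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1 ||
      variance_threshold <= 0 || variance_threshold > 1)
    stopf("variance_threshold must lie in (0, 1]")
  v <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (nrow(v) < 2 || ncol(v) < 1)
    stopf("PCA requires >= 2 rows and >= 1 column")
  fit <- prcomp(v, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  total <- sum(vars)
  if (total <= 0) stopf("input has zero total variance")
  ratio <- vars / total
  m <- which(cumsum(ratio) >= variance_threshold - 1e-12)[1]
  if (is.na(m)) m <- length(ratio)
  # sign convention: largest-|loading| element positive per component
  flip <- apply(fit$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  structure(
    list(scores = scores[, seq_len(m), drop = FALSE],
         explained_variance_ratio = unname(ratio),
         n_components = as.integer(m),
         component_loadings = rotation[, seq_len(m), drop = FALSE],
         centering_means = fit$center,
         variance_threshold = variance_threshold),
    class = "projected_data"
  )
}

#' @export
print.projected_data <- function(x, ...) {
  cat(sprintf(
    "<projected_data> %d x %d scores; %.1f%% variance retained (threshold %g)\n",
    nrow(x$scores), x$n_components,
    100 * sum(x$explained_variance_ratio[seq_len(x$n_components)]),
    x$variance_threshold))
  invisible(x)
}

#' @export
as.data.frame.projected_data <- function(x, ...) {
  data.frame(subject_id = rownames(x$scores), x$scores, check.names = FALSE,
             row.names = NULL)
}
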