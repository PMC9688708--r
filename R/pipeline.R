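#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: where the data come
#' from (simulation, a directory of recordings, or precomputed feature
#' tables), the feature pools of the combination search, the `k` range,
#' the silhouette and explained-variance thresholds, the clustering
#' methods to evaluate, and the master seed (which fans out to per-stage
#' substreams).
#'
#' @param input_mode `"simulate"`, `"timeseries_dir"` or
#'   `"feature_tables"`.
#' @param cohort a [cohort_spec()] (simulate mode).
#' @param input_dir directory of recordings (`timeseries_dir` mode) or of
#'   per-condition `features_<condition>.tsv` files (`feature_tables`
#'   mode).
#' @param pools a [feature_pools()].
#' @param k_range length-2 integer vector `(k_min, k_max)`, default (2, 9).
#' @param silhouette_threshold strict cutoff for a good clustering,
#'   default 0.6.
#' @param variance_threshold PCA explained-variance threshold, default 0.8.
#' @param methods subset of the six clustering methods to evaluate on the
#'   best combination.
#' @param seed master integer seed.
#' @param output_dir directory for the report artifacts, or `NULL` to skip
#'   writing.
#' @param top_n rows of the combination summary table.
#' @param baseline_window seconds of pre-task baseline used as the AUC
#'   reference level.
#' @param search_nstart k-means restarts per `k` inside the combination
#'   search.
#' @param exclude_subjects optional subject ids dropped after ingest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("simulate", "timeseries_dir",
                                           "feature_tables"),
                            cohort = cohort_spec(),
                            input_dir = NULL,
                            pools = feature_pools(),
                            k_range = c(2, 9),
                            silhouette_threshold = 0.6,
                            variance_threshold = 0.8,
                            methods = clustering_method_names(),
                            seed = 1,
                            output_dir = NULL,
                            top_n = 5,
                            baseline_window = 120,
                            search_nstart = 10,
                            exclude_subjects = character()) {
  input_mode <- match.arg(input_mode)
  if (input_mode != "simulate") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stopf("input_dir must be an existing directory in %s mode", input_mode)
  } else if (!inherits(cohort, "cohort_spec")) {
    stopf("simulate mode requires a cohort_spec")
  }
  if (length(k_range) != 2 || k_range[1] < 2 || k_range[2] < k_range[1])
    stopf("k_range must be (k_min, k_max) with 2 <= k_min <= k_max")
  methods <- match.arg(methods, clustering_method_names(),
                       several.ok = TRUE)
  if (silhouette_threshold < -1 || silhouette_threshold > 1)
    stopf("silhouette_threshold must lie in [-1, 1]")
  structure(
    list(input_mode = input_mode, cohort = cohort, input_dir = input_dir,
         pools = pools, k_range = as.integer(k_range),
         silhouette_threshold = silhouette_threshold,
         variance_threshold = variance_threshold, methods = methods,
         seed = as.integer(seed), output_dir = output_dir,
         top_n = top_n, baseline_window = baseline_window,
         search_nstart = search_nstart,
         exclude_subjects = as.character(exclude_subjects)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]. The `cohort` section
#' accepts `n_subjects`, `conditions`, `n_groups` (a per-condition map),
#' `separation`, `task_performance_mean`, `task_performance_sd` and
#' `seed`; group templates are built with [default_templates()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) {
    cs <- y$cohort
    conditions <- unlist(cs$conditions) %||% c("blue", "red")
    templates <- lapply(conditions, function(cond)
      default_templates(cond,
                        n_groups = cs$n_groups[[cond]],
                        separation = cs$separation %||% 1))
    names(templates) <- conditions
    cohort_spec(n_subjects = cs$n_subjects %||% 30,
                conditions = conditions,
                templates_per_condition = templates,
                task_performance_mean = cs$task_performance_mean %||% 58,
                task_performance_sd = cs$task_performance_sd %||% 12,
                seed = cs$seed %||% y$seed %||% 1)
  } else cohort_spec(seed = y$seed %||% 1)
  pools <- if (!is.null(y$pools)) {
    feature_pools(pfc = unlist(y$pools$pfc) %||% spa_parameters("PFC"),
                  vc = unlist(y$pools$vc) %||% spa_parameters("VC"),
                  systemic = unlist(y$pools$systemic) %||%
                    spa_parameters("systemic"))
  } else feature_pools()
  pipeline_config(
    input_mode = y$input_mode %||% "simulate",
    cohort = cohort,
    input_dir = y$input_dir,
    pools = pools,
    k_range = unlist(y$k_range) %||% c(2, 9),
    silhouette_threshold = y$silhouette_threshold %||% 0.6,
    variance_threshold = y$variance_threshold %||% 0.8,
    methods = unlist(y$methods) %||% clustering_method_names(),
    seed = y$seed %||% 1,
    output_dir = y$output_dir,
    top_n = y$top_n %||% 5,
    baseline_window = y$baseline_window %||% 120,
    search_nstart = y$search_nstart %||% 10,
    exclude_subjects = unlist(y$exclude_subjects) %||% character())
}

config_provenance <- function(config) {
  list(
    input_mode = config$input_mode,
    n_subjects = if (config$input_mode == "simulate")
      config$cohort$n_subjects else NA,
    conditions = if (config$input_mode == "simulate")
      config$cohort$conditions else NULL,
    k_range = config$k_range,
    silhouette_threshold = config$silhouette_threshold,
    variance_threshold = config$variance_threshold,
    methods = config$methods,
    seed = config$seed,
    top_n = config$top_n,
    baseline_window = config$baseline_window,
    search_nstart = config$search_nstart,
    pools = unclass(config$pools))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config_provenance(config), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: ingest or simulate -> task-phase AUC
#' feature tables -> min-max normalization -> exhaustive constrained
#' combination search -> for the best combination, PCA projection and a
#' validity grid (every configured method x three criteria, with
#' majority-vote consensus on `k` per condition) -> per-subject scores and
#' silhouettes, feature correlations, and (in simulate mode) recovery
#' metrics against the planted labels. Artifacts are written to
#' `config$output_dir` as delimited text plus a JSON provenance file; a
#' fixed config yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `spa_run_report`; see the elements
#'   `search_table`, `validity_grid`, `subject_tables`, `summary`,
#'   `correlations`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("config must be a pipeline_config")
  seed_search <- substream_seed(config$seed, 1)
  seed_cluster <- substream_seed(config$seed, 2)

  # stage 1: data
  data <- stage_error("ingest", switch(
    config$input_mode,
    simulate = {
      spec <- config$cohort
      spec$seed <- config$seed
      cohort_feature_tables(generate_cohort(spec),
                            baseline_window = config$baseline_window)
    },
    timeseries_dir =
      cohort_feature_tables(read_timeseries_dir(config$input_dir),
                            baseline_window = config$baseline_window),
    feature_tables = {
      files <- sort(list.files(config$input_dir,
                               pattern = "^features_.*\\.tsv$",
                               full.names = TRUE))
      files <- grep("_normalized\\.tsv$", files, invert = TRUE,
                    value = TRUE)
      if (!length(files))
        stopf("%s contains no features_<condition>.tsv files",
              config$input_dir)
      out <- lapply(files, function(f) {
        tab <- read_feature_table(f)
        list(table = tab, labels = NULL)
      })
      names(out) <- vapply(out, function(e) e$table$condition, character(1))
      ids <- lapply(out, function(e) e$table$subjects)
      common <- Reduce(intersect, ids)
      for (cond in names(out)) {
        extra <- setdiff(ids[[cond]], common)
        if (length(extra))
          stopf("subject(s) %s present in condition '%s' but not in all conditions",
                paste(extra, collapse = ", "), cond)
      }
      out
    }))
  if (length(config$exclude_subjects)) {
    data <- lapply(data, function(e) {
      keep <- !(e$table$subjects %in% config$exclude_subjects)
      e$table <- feature_table(e$table$values[keep, , drop = FALSE],
                               e$table$condition, e$table$provenance)
      if (!is.null(e$labels)) e$labels <- e$labels[keep]
      e
    })
  }
  conditions <- names(data)
  raw_tables <- lapply(data, `[[`, "table")
  planted <- lapply(data, `[[`, "labels")

  # stage 2: normalization
  norm_tables <- stage_error("normalize",
                             lapply(raw_tables, min_max_normalize))

  # stage 3: constrained combination search
  k_range <- seq(config$k_range[1], config$k_range[2])
  search <- stage_error("search",
    search_features(norm_tables, pools = config$pools, k_range = k_range,
                    threshold = config$silhouette_threshold,
                    top_n = config$top_n, seed = seed_search,
                    variance_threshold = config$variance_threshold,
                    nstart = config$search_nstart))
  best <- search$best_features
  if (is.null(best)) {
    warnf("no combination passed the silhouette threshold; validity grid skipped")
    report <- structure(
      list(search_table = search$top, all_scores = search$all_scores,
           best_features = NULL, validity_grid = NULL,
           subject_tables = NULL, summary = NULL, correlations = NULL,
           config = config,
           provenance = list(config = config_provenance(config),
                             config_hash = config_hash(config),
                             package_version =
                               as.character(utils::packageVersion("spaclust")))),
      class = "spa_run_report")
    return(report)
  }

  # stage 4: validity grid on the best combination
  projections <- stage_error("project", lapply(norm_tables, function(tab)
    pca_project(tab$values[, best, drop = FALSE],
                config$variance_threshold)))
  validity <- stage_error("validity_grid", lapply(conditions, function(cond) {
    reps <- lapply(config$methods, function(m)
      validity_report(projections[[cond]]$scores, method = m,
                      k_range = k_range, seed = seed_cluster,
                      silhouette_threshold = config$silhouette_threshold))
    names(reps) <- config$methods
    reps
  }))
  names(validity) <- conditions
  validity_grid <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(config$methods, function(m) {
      vr <- validity[[cond]][[m]]
      data.frame(condition = cond, method = m,
                 silhouette_k = vr$optimal_k_per_criterion[["silhouette"]],
                 calinski_harabasz_k =
                   vr$optimal_k_per_criterion[["calinski_harabasz"]],
                 davies_bouldin_k =
                   vr$optimal_k_per_criterion[["davies_bouldin"]],
                 consensus_k = vr$consensus_k,
                 mean_silhouette =
                   mean(vr$per_sample_silhouette, na.rm = TRUE),
                 fraction_above = vr$fraction_above,
                 stringsAsFactors = FALSE)
    }))
  }))

  # stage 5: per-subject detail for the reference hard method (k-means,
  # or the first configured method if k-means is not among them)
  ref_method <- if ("kmeans" %in% config$methods) "kmeans"
                else config$methods[1]
  subject_tables <- lapply(conditions, function(cond) {
    vr <- validity[[cond]][[ref_method]]
    proj <- projections[[cond]]
    df <- data.frame(subject_id = rownames(proj$scores),
                     proj$scores, check.names = FALSE, row.names = NULL)
    df$cluster <- vr$consensus_result$labels
    df$silhouette <- vr$per_sample_silhouette
    if (!is.null(planted[[cond]]) && !all(is.na(planted[[cond]])))
      df$planted_label <- unname(planted[[cond]][df$subject_id])
    df
  })
  names(subject_tables) <- conditions
  summary_df <- do.call(rbind, lapply(conditions, function(cond) {
    vr <- validity[[cond]][[ref_method]]
    ari <- if (!is.null(planted[[cond]]) && !all(is.na(planted[[cond]]))) {
      adjusted_rand_index(vr$consensus_result$labels,
                          unname(planted[[cond]]))
    } else NA_real_
    data.frame(condition = cond, method = ref_method,
               consensus_k = vr$consensus_k,
               mean_silhouette = mean(vr$per_sample_silhouette,
                                      na.rm = TRUE),
               fraction_above = vr$fraction_above,
               n_components = projections[[cond]]$n_components,
               variance_retained = sum(
                 projections[[cond]]$explained_variance_ratio[
                   seq_len(projections[[cond]]$n_components)]),
               ari_vs_planted = ari,
               stringsAsFactors = FALSE)
  }))

  # stage 6: correlations between the cerebrovascular and systemic members
  # of the best combination, on the raw AUC scale
  cerebro <- intersect(best, c(config$pools$pfc, config$pools$vc))
  systemic <- setdiff(best, cerebro)
  correlations <- if (length(cerebro) && length(systemic)) {
    do.call(rbind, lapply(conditions, function(cond)
      cbind(condition = cond,
            feature_correlations(raw_tables[[cond]], cerebro, systemic))))
  } else NULL

  report <- structure(
    list(search_table = search$top, all_scores = search$all_scores,
         best_features = best, validity = validity,
         validity_grid = validity_grid, projections = projections,
         subject_tables = subject_tables, summary = summary_df,
         correlations = correlations, raw_tables = raw_tables,
         norm_tables = norm_tables, planted = planted, config = config,
         provenance = list(
           config = config_provenance(config),
           config_hash = config_hash(config),
           seeds = list(master = config$seed, search = seed_search,
                        cluster = seed_cluster),
           n_combinations = nrow(search$all_scores),
           n_passing = sum(search$all_scores$passes_threshold,
                           na.rm = TRUE),
           package_version =
             as.character(utils::packageVersion("spaclust")))),
    class = "spa_run_report")
  if (!is.null(config$output_dir)) write_run_report(report)
  report
}

write_run_report <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(report$search_table, file.path(dir, "search_table.tsv"))
  if (!is.null(report$validity_grid))
    write_tsv_file(report$validity_grid,
                   file.path(dir, "validity_grid.tsv"))
  if (!is.null(report$subject_tables))
    for (cond in names(report$subject_tables))
      write_tsv_file(report$subject_tables[[cond]],
                     file.path(dir, sprintf("subjects_%s.tsv", cond)))
  if (!is.null(report$summary))
    write_tsv_file(report$summary, file.path(dir, "summary.tsv"))
  if (!is.null(report$correlations))
    write_tsv_file(report$correlations,
                   file.path(dir, "correlations.tsv"))
  for (cond in names(report$raw_tables)) {
    write_feature_table(report$raw_tables[[cond]],
                        file.path(dir, sprintf("features_%s.tsv", cond)))
    write_feature_table(report$norm_tables[[cond]],
                        file.path(dir,
                                  sprintf("features_%s_normalized.tsv",
                                          cond)))
  }
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.spa_run_report <- function(x, ...) {
  cat("<spa_run_report>\n")
  if (!is.null(x$best_features))
    cat("  best combination:", paste(x$best_features, collapse = ", "),
        "\n")
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf(
        "  %s: consensus k = %d, mean silhouette %.2f, %d%% subjects > %.2g%s\n",
        x$summary$condition[i], x$summary$consensus_k[i],
        x$summary$mean_silhouette[i],
        round(100 * x$summary$fraction_above[i]),
        x$config$silhouette_threshold,
        if (!is.na(x$summary$ari_vs_planted[i]))
          sprintf(", ARI vs planted %.2f", x$summary$ari_vs_planted[i])
        else ""))
  } else {
    cat("  no combination passed the silhouette threshold\n")
  }
  invisible(x)
}

#' Plot the per-subject scores of a pipeline run
#'
#' Scatter of the first two PCA score dimensions per condition, colored by
#' the consensus clustering, with per-subject silhouette bars alongside.
#'
#' @param x an `spa_run_report`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.spa_run_report <- function(x, ...) {
  if (is.null(x$subject_tables)) {
    warnf("nothing to plot: no combination passed the threshold")
    return(invisible(x))
  }
  conds <- names(x$subject_tables)
  old <- graphics::par(mfrow = c(length(conds), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cond in conds) {
    df <- x$subject_tables[[cond]]
    pc2 <- if ("PC2" %in% names(df)) df$PC2 else rep(0, nrow(df))
    graphics::plot(df$PC1, pc2, col = df$cluster + 2, pch = 19,
                   xlab = "PC1", ylab = "PC2",
                   main = sprintf("%s: consensus clusters", cond))
    graphics::text(df$PC1, pc2, df$subject_id, pos = 3, cex = 0.6)
    ord <- order(df$cluster, -df$silhouette)
    graphics::barplot(df$silhouette[ord], col = df$cluster[ord] + 2,
                      names.arg = df$subject_id[ord], las = 2,
                      cex.names = 0.6, ylim = c(-0.2, 1),
                      main = sprintf("%s: silhouettes", cond))
    graphics::abline(h = x$config$silhouette_threshold, lty = 2)
  }
  invisible(x)
}
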