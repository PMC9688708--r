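#' One physiological channel of one subject and condition
#'
#' A uniformly sampled signal for a single named parameter, annotated with
#' the protocol phase boundaries (baseline start, task start, task end,
#' recovery end, in seconds).
#'
#' @param subject_id,condition labels.
#' @param parameter one of [spa_parameters()].
#' @param sampling_rate Hz, > 0.
#' @param samples numeric vector; must span the annotated phases.
#' @param phase_bounds numeric length-4 vector, strictly increasing.
#' @return an object of class `time_series_record` with a `time` element
#'   (seconds, starting at `phase_bounds[1]`).
#' @export
time_series_record <- function(subject_id, condition, parameter,
                               sampling_rate, samples, phase_bounds) {
  if (!parameter %in% spa_parameters())
    stopf("unknown parameter '%s'", parameter)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be > 0")
  phase_bounds <- as.numeric(phase_bounds)
  if (length(phase_bounds) != 4L || any(diff(phase_bounds) <= 0))
    stopf("phase_bounds must be 4 strictly increasing times")
  names(phase_bounds) <- c("baseline_start", "task_start", "task_end",
                           "recovery_end")
  time <- phase_bounds[[1]] + (seq_along(samples) - 1L) / sampling_rate
  if (time[length(time)] < phase_bounds[[4]] - 1e-9)
    stopf("samples for %s/%s do not span the recovery end",
          subject_id, parameter)
  structure(
    list(subject_id = as.character(subject_id),
         condition = as.character(condition),
         parameter = parameter, sampling_rate = sampling_rate,
         samples = as.numeric(samples), time = as.numeric(time),
         phase_bounds = phase_bounds),
    class = "time_series_record"
  )
}

#' @export
print.time_series_record <- function(x, ...) {
  cat(sprintf("<time_series_record> %s | %s | %s: %d samples @ %g Hz\n",
              x$subject_id, x$condition, x$parameter, length(x$samples),
              x$sampling_rate))
  invisible(x)
}

#' Subjects-by-features table
#'
#' Container for the per-condition feature matrix: one row per subject,
#' one column per feature (the 14 task-phase AUC values plus task
#' performance, although any feature set is accepted).
#'
#' @param values numeric matrix with subject rownames and feature colnames;
#'   no missing entries.
#' @param condition condition label.
#' @param provenance `"raw_auc"` or `"normalized"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, condition,
                          provenance = c("raw_auc", "normalized")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have subject rownames and feature colnames")
  if (anyDuplicated(colnames(values))) stopf("feature names must be unique")
  if (anyDuplicated(rownames(values))) stopf("subject ids must be unique")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("missing/non-finite entry at subject %s, feature %s",
          rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  structure(
    list(condition = as.character(condition),
         subjects = rownames(values), features = colnames(values),
         values = values, provenance = provenance),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d subjects x %d features (%s)\n",
              x$condition, nrow(x$values), ncol(x$values), x$provenance))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(subject_id = x$subjects, x$values, check.names = FALSE,
             row.names = NULL)
}

#' Pre-task baseline level of a record
#'
#' Arithmetic mean over the final `window` seconds of the baseline phase
#' (a steady-state reference window), used as the reference level that AUC
#' changes are computed against.
#'
#' @param record a [time_series_record()].
#' @param window seconds; must be positive and no longer than the baseline
#'   phase.
#' @return scalar, in the record's native units.
#' @export
baseline_level <- function(record, window = 120) {
  pb <- record$phase_bounds
  base_dur <- pb[["task_start"]] - pb[["baseline_start"]]
  if (!is.numeric(window) || window <= 0)
    stopf("baseline window must be a positive duration")
  if (window > base_dur)
    stopf("baseline window (%gs) exceeds the baseline phase (%gs)",
          window, base_dur)
  idx <- record$time >= pb[["task_start"]] - window &
    record$time <= pb[["task_start"]]
  if (!any(idx)) stopf("baseline window contains no samples")
  mean(record$samples[idx])
}

#' Task-phase area under the curve
#'
#' Sign-preserving trapezoidal integral of the baseline-referenced signal
#' over the task phase; negative deflections yield negative AUC.
#'
#' @param record a [time_series_record()].
#' @param baseline reference level subtracted from every sample (e.g.
#'   [baseline_level()]).
#' @return scalar in parameter units x seconds.
#' @export
auc_task_phase <- function(record, baseline = 0) {
  pb <- record$phase_bounds
  idx <- record$time >= pb[["task_start"]] & record$time <= pb[["task_end"]]
  if (sum(idx) < 2L)
    stopf("task phase of %s/%s has fewer than 2 samples",
          record$subject_id, record$parameter)
  x <- record$samples[idx]
  if (any(!is.finite(x)))
    stopf("non-finite task-phase samples in subject %s, parameter %s",
          record$subject_id, record$parameter)
  pracma::trapz(record$time[idx], x - baseline)
}

#' Build the per-condition feature table from records
#'
#' Computes the task-phase AUC of every parameter for every subject
#' (baseline-referenced via [baseline_level()]) and appends the scalar task
#' performance, yielding the 15-feature subject table.
#'
#' @param records list of [time_series_record()]s for one condition (any
#'   order); every subject must have all 14 parameters.
#' @param task_performance named numeric vector (names = subject ids).
#' @param condition condition label; defaults to the records' label.
#' @param baseline_window seconds, passed to [baseline_level()].
#' @return a [feature_table()] with provenance `"raw_auc"`, rows ordered by
#'   subject id so row order is stable across conditions of one cohort.
#' @export
build_feature_table <- function(records, task_performance,
                                condition = NULL, baseline_window = 120) {
  if (!length(records)) stopf("no records supplied")
  flat <- list()
  for (r in records) {
    if (inherits(r, "time_series_record")) flat <- c(flat, list(r))
    else flat <- c(flat, r)  # per-subject sublists
  }
  ok <- vapply(flat, inherits, logical(1), "time_series_record")
  if (!all(ok)) stopf("records must be time_series_record objects")
  condition <- condition %||% flat[[1]]$condition
  params <- spa_parameters()
  subj <- sort(unique(vapply(flat, `[[`, character(1), "subject_id")))
  key <- paste(vapply(flat, `[[`, character(1), "subject_id"),
               vapply(flat, `[[`, character(1), "parameter"), sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate (subject, parameter) records")
  lookup <- stats::setNames(seq_along(flat), key)
  missing <- list()
  for (s in subj) for (p in params)
    if (is.na(lookup[paste(s, p, sep = "\r")]))
      missing <- c(missing, sprintf("(%s, %s)", s, p))
  if (length(missing))
    stopf("missing channel(s): %s", paste(missing, collapse = ", "))
  tp_missing <- setdiff(subj, names(task_performance))
  if (length(tp_missing))
    stopf("missing task performance for subject(s): %s",
          paste(tp_missing, collapse = ", "))
  values <- vapply(params, function(p) {
    vapply(subj, function(s) {
      r <- flat[[lookup[[paste(s, p, sep = "\r")]]]]
      auc_task_phase(r, baseline_level(r, baseline_window))
    }, numeric(1))
  }, numeric(length(subj)))
  values <- cbind(values, as.numeric(task_performance[subj]))
  dimnames(values) <- list(subj, c(params, task_performance_feature()))
  feature_table(values, condition = condition, provenance = "raw_auc")
}

#' Feature tables for every condition of a simulated cohort
#'
#' Convenience wrapper running [build_feature_table()] per condition of a
#' [generate_cohort()] result.
#'
#' @param cohort an `spa_cohort`.
#' @param baseline_window seconds, passed to [baseline_level()].
#' @return named list per condition with `table` and planted `labels`.
#' @export
cohort_feature_tables <- function(cohort, baseline_window = 120) {
  if (!inherits(cohort, "spa_cohort")) stopf("cohort must be an spa_cohort")
  out <- lapply(names(cohort$conditions), function(cond) {
    co <- cohort$conditions[[cond]]
    list(table = build_feature_table(co$records, co$task_performance,
                                     condition = cond,
                                     baseline_window = baseline_window),
         labels = co$labels)
  })
  names(out) <- names(cohort$conditions)
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("correlation requires >= 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("non-finite values in correlation input")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined for zero-variance input")
  cor(x, y, method = "pearson")
}

#' Pairwise feature correlations
#'
#' Pearson correlations (with two-sided p-values) between two sets of
#' columns of a feature table, e.g. the cerebrovascular versus the systemic
#' members of a selected combination.
#'
#' @param table a [feature_table()].
#' @param features_a,features_b character vectors of column names.
#' @return data frame with columns `feature_a`, `feature_b`, `r`, `p`.
#' @export
feature_correlations <- function(table, features_a, features_b) {
  if (!inherits(table, "feature_table")) stopf("table must be a feature_table")
  missing <- setdiff(c(features_a, features_b), table$features)
  if (length(missing))
    stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
  grid <- expand.grid(feature_a = features_a, feature_b = features_b,
                      stringsAsFactors = FALSE)
  res <- t(apply(grid, 1, function(fp) {
    ct <- cor.test(table$values[, fp[[1]]], table$values[, fp[[2]]],
                   method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
  cbind(grid, as.data.frame(res))
}
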