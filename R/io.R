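# Delimited-text I/O. Feature tables and recordings are plain TSV with a
# JSON sidecar carrying the metadata; numbers are written with 17
# significant digits so a write-then-read round trip is exact.

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_file <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a feature table as delimited text
#'
#' One TSV per condition: a `subject_id` column followed by one column per
#' feature, plus a JSON sidecar (`<path>.json`) recording condition,
#' provenance and feature order.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table")) stopf("table must be a feature_table")
  write_tsv_file(as.data.frame(table), path)
  jsonlite::write_json(
    list(condition = table$condition, provenance = table$provenance,
         features = table$features),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Validates the schema (header starting with `subject_id`, fully numeric
#' cells, no missing entries) and reports violations with file and line.
#'
#' @param path TSV path; the JSON sidecar is used when present.
#' @param condition,provenance fallbacks when no sidecar exists.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, condition = NULL,
                               provenance = "raw_auc") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0) stopf("%s: empty file", path)
  lines <- readLines(path)
  if (length(lines) < 2) stopf("%s: no data rows", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "subject_id")
    stopf("%s: first column must be 'subject_id', got '%s'",
          path, names(df)[1])
  if (ncol(df) < 2) stopf("%s: no feature columns", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("%s: non-numeric cell '%s' at line %d, column '%s'",
          path, vals[bad[1], bad[2]], bad[1] + 1L,
          colnames(df)[bad[2] + 1L])
  }
  dimnames(num) <- list(df$subject_id, names(df)[-1])
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list()
  feature_table(num,
                condition = condition %||% meta$condition %||% "unknown",
                provenance = meta$provenance %||% provenance)
}

#' Write a simulated cohort as per-subject delimited text
#'
#' One TSV per subject and condition (`<subject>_<condition>.tsv`) with a
#' `time_s` column and one column per parameter, plus a JSON sidecar with
#' sampling rate, phase boundaries, task performance and the planted group
#' label.
#'
#' @param cohort an `spa_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "spa_cohort")) stopf("cohort must be an spa_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(cohort$conditions)) {
    co <- cohort$conditions[[cond]]
    for (id in names(co$records)) {
      recs <- co$records[[id]]
      df <- data.frame(time_s = recs[[1]]$time, check.names = FALSE)
      for (r in recs) df[[r$parameter]] <- r$samples
      stem <- file.path(dir, sprintf("%s_%s", id, cond))
      write_tsv_file(df, paste0(stem, ".tsv"))
      jsonlite::write_json(
        list(subject_id = id, condition = cond,
             sampling_rate = recs[[1]]$sampling_rate,
             phase_bounds = as.list(recs[[1]]$phase_bounds),
             task_performance = unname(co$task_performance[[id]]),
             planted_label = unname(co$labels[[id]])),
        paste0(stem, ".tsv.json"), auto_unbox = TRUE)
    }
  }
  invisible(dir)
}

#' Read a directory of per-subject recordings
#'
#' Ingests the format written by [write_cohort()]: per subject/condition a
#' TSV (`time_s` + one column per parameter) with a JSON sidecar. Subjects
#' must be present in every condition.
#'
#' @param dir directory containing `*.tsv` + `*.tsv.json` pairs.
#' @return an `spa_cohort`-like object (without a generating spec):
#'   per-condition `records`, `task_performance` and `labels` (planted
#'   labels from the sidecars; `NA` if absent).
#' @export
read_timeseries_dir <- function(dir) {
  if (!dir.exists(dir)) stopf("no such directory: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stopf("%s contains no .tsv recordings", dir)
  entries <- lapply(files, function(f) {
    sc <- paste0(f, ".json")
    if (!file.exists(sc)) stopf("%s: missing metadata sidecar %s", f, sc)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (field in c("subject_id", "condition", "sampling_rate",
                    "phase_bounds"))
      if (is.null(meta[[field]]))
        stopf("%s: sidecar lacks field '%s'", sc, field)
    if (file.size(f) == 0) stopf("%s: empty file", f)
    df <- tryCatch(read.delim(f, check.names = FALSE),
                   error = function(e) stopf("%s: %s", f, conditionMessage(e)))
    if (names(df)[1] != "time_s")
      stopf("%s: first column must be 'time_s'", f)
    params <- setdiff(names(df), "time_s")
    bad <- setdiff(params, spa_parameters())
    if (length(bad))
      stopf("%s: unknown parameter column(s): %s", f,
            paste(bad, collapse = ", "))
    num_ok <- vapply(df, is.numeric, logical(1))
    if (!all(num_ok))
      stopf("%s: non-numeric cells in column '%s'", f,
            names(df)[!num_ok][1])
    pb <- unlist(meta$phase_bounds)
    records <- lapply(params, function(p)
      time_series_record(meta$subject_id, meta$condition, p,
                         meta$sampling_rate, df[[p]], pb))
    names(records) <- params
    list(meta = meta, records = records)
  })
  conds <- unique(vapply(entries, function(e) e$meta$condition, character(1)))
  by_cond <- lapply(conds, function(cond) {
    sel <- entries[vapply(entries, function(e)
      identical(e$meta$condition, cond), logical(1))]
    ids <- vapply(sel, function(e) e$meta$subject_id, character(1))
    ord <- order(ids)
    sel <- sel[ord]; ids <- ids[ord]
    list(records = stats::setNames(lapply(sel, `[[`, "records"), ids),
         task_performance = stats::setNames(vapply(sel, function(e)
           as.numeric(e$meta$task_performance %||% NA_real_), numeric(1)),
           ids),
         labels = stats::setNames(vapply(sel, function(e)
           as.integer(e$meta$planted_label %||% NA_integer_), integer(1)),
           ids))
  })
  names(by_cond) <- conds
  all_ids <- lapply(by_cond, function(co) names(co$records))
  common <- Reduce(intersect, all_ids)
  for (cond in conds) {
    extra <- setdiff(all_ids[[cond]], common)
    if (length(extra))
      stopf("subject(s) %s present in condition '%s' but not in all conditions",
            paste(extra, collapse = ", "), cond)
  }
  structure(list(spec = NULL, conditions = by_cond), class = "spa_cohort")
}
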