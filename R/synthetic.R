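#' Simulate one subject's multichannel recording
#'
#' Draws one record per time-varying parameter under the signal model
#' baseline level + group response + linear drift + noise, where the group
#' response is amplitude x saturating exponential onset (time constant
#' `onset_time_constant`) during the task phase and an exponential return
#' toward baseline during recovery. The subject's realized response
#' amplitude per parameter is drawn around the template amplitude with the
#' template's between-subject `amplitude_sd`.
#'
#' @param template a [group_template()].
#' @param protocol a [protocol_spec()].
#' @param subject_id,condition labels stamped on the records.
#' @param task_performance_mean,task_performance_sd rounded Gaussian,
#'   clipped at 0.
#' @param ar lag-1 autocorrelation of the noise (0 = white, the default).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return list with `records` (named list of [time_series_record()]s, one
#'   per parameter) and `task_performance` (scalar count).
#' @examples
#' s <- generate_subject(default_templates("blue")[[1]], seed = 1)
#' names(s$records)[1:3]
#' @export
generate_subject <- function(template, protocol = protocol_spec(),
                             subject_id = "S01", condition = "blue",
                             task_performance_mean = 58,
                             task_performance_sd = 12,
                             ar = 0, seed = NULL) {
  if (!inherits(template, "group_template"))
    stopf("template must be a group_template")
  params <- spa_parameters()
  missing <- setdiff(params, names(template$response_amplitude))
  if (length(missing))
    stopf("template is missing parameter(s): %s",
          paste(missing, collapse = ", "))
  run <- function() {
    pb <- phase_bounds(protocol)
    dt <- 1 / protocol$sampling_rate
    t <- seq(0, pb[["recovery_end"]], by = dt)
    tau <- template$onset_time_constant
    in_task <- t >= pb[["task_start"]] & t <= pb[["task_end"]]
    in_rec <- t > pb[["task_end"]]
    shape <- numeric(length(t))
    shape[in_task] <- 1 - exp(-(t[in_task] - pb[["task_start"]]) / tau)
    end_level <- 1 - exp(-protocol$task_duration / tau)
    shape[in_rec] <- end_level * exp(-(t[in_rec] - pb[["task_end"]]) / tau)
    records <- lapply(params, function(p) {
      amp <- rnorm(1, template$response_amplitude[[p]],
                   template$amplitude_sd[[p]])
      slope <- rnorm(1, 0, template$drift_sd[[p]]) / 60  # units per second
      noise <- rnorm(length(t), 0, template$noise_sd[[p]])
      if (ar != 0)
        noise <- as.numeric(stats::filter(noise, ar, method = "recursive"))
      x <- template$baseline[[p]] + amp * shape + slope * t + noise
      time_series_record(subject_id = subject_id, condition = condition,
                         parameter = p,
                         sampling_rate = protocol$sampling_rate,
                         samples = x, phase_bounds = pb)
    })
    names(records) <- params
    tp <- max(0, round(rnorm(1, task_performance_mean, task_performance_sd)))
    list(records = records, task_performance = tp)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Substream offsets: one block per condition so that adding subjects or
# conditions never reshuffles earlier subjects' draws.
.cond_offset <- function(ci) ci * 1000000

# Each subject draws its group independently from the mixing proportions
# in its own label substream, so group sizes follow the proportions under a
# multinomial law while early subjects stay fixed when the cohort grows.
.draw_labels <- function(spec, cond, ci) {
  tpl <- spec$templates_per_condition[[cond]]
  pr <- spec$group_proportions_per_condition[[cond]]
  vapply(seq_len(spec$n_subjects), function(i)
    with_substream(spec$seed, .cond_offset(ci) + 500000 + i,
                   sample.int(length(tpl), 1, prob = pr)),
    integer(1))
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate a full two-condition cohort of time series
#'
#' Every subject appears in every condition; within each condition subjects
#' are assigned to a planted group by a multinomial draw from the seeded
#' generator, then simulated with [generate_subject()] from that group's
#' template. Per-subject substreams are derived from the master seed by
#' counter offset, so enlarging the cohort does not reshuffle earlier
#' subjects.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `spa_cohort`: a list with `spec` and
#'   `conditions`, where each condition holds `records` (per-subject lists
#'   of [time_series_record()]s), `task_performance` and planted `labels`
#'   (integer group indices named by subject). The realized number of
#'   groups per condition is attached as attribute `realized_groups` on the
#'   label vector.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 6, seed = 42))
#' coh$conditions$blue$labels
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  ids <- subject_ids(spec$n_subjects)
  conditions <- lapply(seq_along(spec$conditions), function(ci) {
    cond <- spec$conditions[[ci]]
    tpl <- spec$templates_per_condition[[cond]]
    labels <- .draw_labels(spec, cond, ci)
    subjects <- lapply(seq_len(spec$n_subjects), function(i) {
      with_substream(spec$seed, .cond_offset(ci) + i,
        generate_subject(tpl[[labels[i]]], spec$protocol,
                         subject_id = ids[i], condition = cond,
                         task_performance_mean = spec$task_performance_mean,
                         task_performance_sd = spec$task_performance_sd))
    })
    names(subjects) <- ids
    labels <- stats::setNames(labels, ids)
    attr(labels, "realized_groups") <- length(unique(labels))
    list(records = lapply(subjects, `[[`, "records"),
         task_performance = vapply(subjects, `[[`, numeric(1),
                                   "task_performance"),
         labels = labels)
  })
  names(conditions) <- spec$conditions
  structure(list(spec = spec, conditions = conditions),
            class = "spa_cohort")
}

#' @export
print.spa_cohort <- function(x, ...) {
  n <- length(x$conditions[[1]]$records)
  cat(sprintf("<spa_cohort> %d subjects x {%s}; realized groups: %s\n",
              n, paste(names(x$conditions), collapse = ", "),
              paste(vapply(x$conditions, function(co)
                attr(co$labels, "realized_groups"), integer(1)),
                collapse = "/")))
  invisible(x)
}

#' Simulate feature tables directly (fast mode)
#'
#' Skips the time-series stage and draws the AUC-level features from a
#' Gaussian mixture whose component means are the template amplitudes times
#' the task duration. Group labels use the same substreams as
#' [generate_cohort()], so the planted partitions of the two modes
#' coincide for a given spec.
#'
#' @param spec a [cohort_spec()].
#' @param separation non-negative scalar scaling each component mean's
#'   deviation from the across-group mean feature value; 0 collapses all
#'   groups onto a single distribution, 1 keeps the template amplitudes as
#'   specified.
#' @return named list (one entry per condition) with `table` (a
#'   [feature_table()] with 14 AUC features + task performance, provenance
#'   `"raw_auc"`) and planted `labels`.
#' @examples
#' ft <- generate_feature_table(cohort_spec(n_subjects = 10, seed = 3))
#' dim(ft$blue$table$values)
#' @export
generate_feature_table <- function(spec, separation = 1) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  if (!is.numeric(separation) || length(separation) != 1 || separation < 0)
    stopf("separation must be a non-negative scalar")
  params <- spa_parameters()
  T <- spec$protocol$task_duration
  ids <- subject_ids(spec$n_subjects)
  out <- lapply(seq_along(spec$conditions), function(ci) {
    cond <- spec$conditions[[ci]]
    tpl <- spec$templates_per_condition[[cond]]
    labels <- .draw_labels(spec, cond, ci)
    # component means: amplitude x task duration, deviations from the
    # across-group mean scaled by `separation`
    mu <- vapply(tpl, function(g)
      g$response_amplitude[params] * T, numeric(length(params)))
    mu <- rowMeans(mu) + separation * (mu - rowMeans(mu))
    # within-group SD on the AUC scale: between-subject amplitude spread
    # integrated over the task plus accumulated sample noise
    sds <- vapply(tpl, function(g)
      sqrt((g$amplitude_sd[params] * T)^2 + g$noise_sd[params]^2 * T),
      numeric(length(params)))
    rows <- t(vapply(seq_len(spec$n_subjects), function(i) {
      g <- labels[i]
      with_substream(spec$seed, .cond_offset(ci) + i, {
        auc <- rnorm(length(params), mu[, g], sds[, g])
        tp <- max(0, round(rnorm(1, spec$task_performance_mean,
                                 spec$task_performance_sd)))
        c(auc, tp)
      })
    }, numeric(length(params) + 1L)))
    dimnames(rows) <- list(ids, c(params, task_performance_feature()))
    labels <- stats::setNames(labels, ids)
    attr(labels, "realized_groups") <- length(unique(labels))
    list(table = feature_table(rows, condition = cond,
                               provenance = "raw_auc"),
         labels = labels)
  })
  names(out) <- spec$conditions
  out
}
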