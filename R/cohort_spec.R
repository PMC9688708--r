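#' Experimental protocol specification
#'
#' Phase durations and sampling rate of the recording protocol: a resting
#' baseline in darkness, the colored-light-exposure task phase, and a
#' post-task recovery phase. The default (480 s baseline, 540 s task, 900 s
#' recovery, 1 Hz) is the 8 min / 9 min / 15 min protocol the package
#' emulates.
#'
#' @param baseline_duration seconds, > 0.
#' @param task_duration seconds, > 0.
#' @param recovery_duration seconds, > 0.
#' @param sampling_rate Hz, > 0.
#' @return an object of class `protocol_spec`.
#' @examples
#' protocol_spec()
#' @export
protocol_spec <- function(baseline_duration = 480, task_duration = 540,
                          recovery_duration = 900, sampling_rate = 1) {
  for (v in c(baseline_duration, task_duration, recovery_duration,
              sampling_rate)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("protocol durations and sampling rate must be positive scalars")
  }
  structure(
    list(baseline_duration = baseline_duration,
         task_duration = task_duration,
         recovery_duration = recovery_duration,
         sampling_rate = sampling_rate),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol_spec> baseline %gs | task %gs | recovery %gs @ %g Hz\n",
    x$baseline_duration, x$task_duration, x$recovery_duration,
    x$sampling_rate))
  invisible(x)
}

phase_bounds <- function(protocol) {
  c(baseline_start = 0,
    task_start = protocol$baseline_duration,
    task_end = protocol$baseline_duration + protocol$task_duration,
    recovery_end = protocol$baseline_duration + protocol$task_duration +
      protocol$recovery_duration)
}

#' Group reactivity template
#'
#' Encodes one planted subject group as a set of task-phase response
#' amplitudes (in each parameter's native unit), an onset time constant for
#' the saturating response ramp, and noise characteristics. Any field not
#' supplied falls back to the per-parameter simulation defaults of
#' [parameter_profiles()].
#'
#' @param group_id label for the group.
#' @param response_amplitude named numeric vector; entries override the
#'   default task-phase amplitude for the named parameters. After merging
#'   with defaults all 14 time-varying parameters must be covered.
#' @param onset_time_constant seconds, > 0; time constant of the saturating
#'   exponential response onset (and of the recovery decay).
#' @param noise_sd,drift_sd,amplitude_sd,baseline optional named numeric
#'   overrides of the per-parameter defaults (drift in units/minute;
#'   amplitude_sd is the between-subject SD of the response amplitude).
#' @return an object of class `group_template` whose elements are full
#'   14-parameter vectors.
#' @examples
#' group_template("high-SC", response_amplitude = c(SC = 11.4))
#' @export
group_template <- function(group_id, response_amplitude = numeric(),
                           onset_time_constant = 30,
                           noise_sd = numeric(), drift_sd = numeric(),
                           amplitude_sd = numeric(), baseline = numeric()) {
  if (!is.numeric(onset_time_constant) || onset_time_constant <= 0)
    stopf("onset_time_constant must be > 0")
  prof <- parameter_profiles()
  merge_field <- function(defaults, override, field) {
    out <- stats::setNames(defaults, prof$parameter)
    if (length(override)) {
      bad <- setdiff(names(override), prof$parameter)
      if (length(bad))
        stopf("unknown parameter(s) in %s: %s", field,
              paste(bad, collapse = ", "))
      out[names(override)] <- override
    }
    out
  }
  amp   <- merge_field(prof$amplitude, response_amplitude,
                       "response_amplitude")
  nsd   <- merge_field(prof$noise_sd, noise_sd, "noise_sd")
  dsd   <- merge_field(prof$drift_sd, drift_sd, "drift_sd")
  asd   <- merge_field(prof$amplitude_sd, amplitude_sd, "amplitude_sd")
  base  <- merge_field(prof$baseline, baseline, "baseline")
  if (any(!is.finite(amp)))
    stopf("template '%s' does not cover all parameters", group_id)
  if (any(nsd < 0) || any(asd < 0) || any(dsd < 0))
    stopf("noise_sd, drift_sd and amplitude_sd must be >= 0")
  structure(
    list(group_id = as.character(group_id), response_amplitude = amp,
         onset_time_constant = onset_time_constant, noise_sd = nsd,
         drift_sd = dsd, amplitude_sd = asd, baseline = base),
    class = "group_template"
  )
}

# Anchored group-discriminating amplitudes for the canonical cohorts:
# three reactivity groups under blue light, five under red. Values are in
# native units and loosely anchored to the skin-conductance and [O2Hb]-VC
# response ranges reported for this paradigm (e.g. one group with small SC
# responses around 1 uS versus one with very strong responses above 11 uS).
# The group mean vectors are constructed to span two latent directions
# (equiangular layouts in a 2-D latent plane mapped through fixed feature
# loadings), emulating the observed structure where two principal
# components carry >80% of the feature variance while groups stay
# well-separated in the retained score space.
canonical_amplitudes <- function(condition) {
  if (condition == "blue") {
    list(
      `HHb-PFC` = c(-0.050, -0.826, 0.126),
      `O2Hb-VC` = c(0.950, -0.472, -1.078),
      PETCO2    = c(-1.100, -1.125, 3.725),
      SC        = c(0.800, 11.198, 6.002),
      SpO2      = c(0.450, -1.379, 0.179)
    )
  } else {
    list(
      `HHb-PFC` = c(-0.050, -0.711, -0.735, -0.089, 0.335),
      `O2Hb-VC` = c(0.950, 0.488, -0.925, -1.336, -0.178),
      PETCO2    = c(-1.100, -2.657, 0.149, 3.440, 2.669),
      SC        = c(0.800, 7.246, 11.970, 8.444, 1.540),
      SpO2      = c(0.450, -0.890, -1.345, -0.287, 0.822)
    )
  }
}

#' Default group templates for a condition
#'
#' Builds the planted reactivity groups used by the synthetic cohort
#' generator: 3 groups for blue light, 5 for red. Groups differ only in the
#' five group-discriminating features (`HHb-PFC`, `O2Hb-VC`, `PETCO2`,
#' `SC`, `SpO2`); all other parameters share a common response. At
#' `separation = 1` the nearest-group amplitude gap on every discriminating
#' feature is at least 6 within-group SDs, i.e. the planted partition is
#' well-separated.
#'
#' @param condition `"blue"` or `"red"` (any other label gets generic
#'   evenly spaced groups).
#' @param n_groups number of groups; defaults to 3 for blue and 5 for red.
#' @param separation non-negative scalar scaling each group amplitude's
#'   deviation from the across-group mean; 0 collapses all groups onto one
#'   distribution, 1 is the canonical separation.
#' @param informative character vector of features carrying group structure.
#' @return list of [group_template()] objects.
#' @examples
#' length(default_templates("red"))
#' @export
default_templates <- function(condition = "blue", n_groups = NULL,
                              separation = 1,
                              informative = informative_features()) {
  if (!is.numeric(separation) || separation < 0)
    stopf("separation must be >= 0")
  if (is.null(n_groups))
    n_groups <- if (identical(condition, "red")) 5L else 3L
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L) stopf("n_groups must be >= 1")
  prof <- parameter_profiles()
  canonical <- if (condition %in% c("blue", "red")) {
    canonical_amplitudes(condition)
  } else {
    canonical_amplitudes("blue")
  }
  amps <- lapply(informative, function(f) {
    a <- canonical[[f]]
    if (is.null(a) || length(a) < n_groups) {
      # generic grid: groups 8 within-group SDs apart, centred on the
      # parameter's common amplitude
      s <- prof[f, "amplitude_sd"]
      a <- prof[f, "amplitude"] +
        (seq_len(n_groups) - (n_groups + 1) / 2) * 8 * s
    }
    a <- a[seq_len(n_groups)]
    mean(a) + separation * (a - mean(a))
  })
  names(amps) <- informative
  lapply(seq_len(n_groups), function(g) {
    group_template(
      group_id = sprintf("%s-g%d", condition, g),
      response_amplitude = vapply(amps, `[[`, numeric(1), g)
    )
  })
}

#' Synthetic cohort specification
#'
#' Describes a two-condition cohort with planted group structure: how many
#' subjects, which conditions, the group templates and mixing proportions
#' per condition, the task-performance distribution, and the master seed.
#' Defaults reproduce the emulated study conditions: 30 subjects, blue and
#' red light, 3 planted groups under blue and 5 under red, and a task
#' performance of 58 +/- 12 correct nouns.
#'
#' @param n_subjects number of subjects (each appears in every condition).
#' @param conditions character vector of condition labels.
#' @param templates_per_condition named list (one entry per condition) of
#'   lists of [group_template()] objects.
#' @param group_proportions_per_condition named list of simplex weight
#'   vectors; defaults to equal proportions.
#' @param task_performance_mean,task_performance_sd rounded-Gaussian
#'   parameters of the correct-noun count (clipped at 0).
#' @param seed master seed; all randomness derives from it via per-subject
#'   substreams.
#' @param protocol a [protocol_spec()].
#' @return an object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_subjects = 12, seed = 7)
#' @export
cohort_spec <- function(n_subjects = 30,
                        conditions = c("blue", "red"),
                        templates_per_condition = NULL,
                        group_proportions_per_condition = NULL,
                        task_performance_mean = 58,
                        task_performance_sd = 12,
                        seed = 1,
                        protocol = protocol_spec()) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stopf("n_subjects must be >= 1")
  n_subjects <- as.integer(n_subjects)
  conditions <- as.character(conditions)
  if (!length(conditions) || anyDuplicated(conditions))
    stopf("conditions must be a non-empty set of unique labels")
  if (is.null(templates_per_condition)) {
    templates_per_condition <- lapply(conditions, default_templates)
    names(templates_per_condition) <- conditions
  }
  if (!setequal(names(templates_per_condition), conditions))
    stopf("templates_per_condition must name exactly the conditions")
  for (cond in conditions) {
    tpl <- templates_per_condition[[cond]]
    if (!length(tpl)) stopf("condition '%s' needs >= 1 template", cond)
    ok <- vapply(tpl, inherits, logical(1), "group_template")
    if (!all(ok)) stopf("templates for '%s' must be group_template objects",
                        cond)
    if (n_subjects < length(tpl))
      stopf("n_subjects (%d) < number of groups (%d) in condition '%s'",
            n_subjects, length(tpl), cond)
  }
  if (is.null(group_proportions_per_condition)) {
    group_proportions_per_condition <- lapply(
      templates_per_condition,
      function(tpl) rep(1 / length(tpl), length(tpl)))
  }
  for (cond in conditions) {
    pr <- group_proportions_per_condition[[cond]]
    if (length(pr) != length(templates_per_condition[[cond]]))
      stopf("proportions for '%s' must match its number of templates", cond)
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stopf("proportions for '%s' must be non-negative and sum to 1", cond)
  }
  if (task_performance_sd < 0) stopf("task_performance_sd must be >= 0")
  structure(
    list(n_subjects = n_subjects, conditions = conditions,
         templates_per_condition = templates_per_condition,
         group_proportions_per_condition = group_proportions_per_condition,
         task_performance_mean = task_performance_mean,
         task_performance_sd = task_performance_sd,
         seed = as.integer(seed), protocol = protocol),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects x {%s}; groups: %s; seed %d\n",
              x$n_subjects, paste(x$conditions, collapse = ", "),
              paste(vapply(x$templates_per_condition, length, integer(1)),
                    collapse = "/"),
              x$seed))
  invisible(x)
}
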