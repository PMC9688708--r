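#' Parameter vocabulary of the SPA-fNIRS feature set
#'
#' The 14 time-varying physiological parameters measured concurrently:
#' hemoglobin species and tissue oxygenation at two cortical sites
#' (prefrontal cortex, PFC; visual cortex, VC) plus six systemic
#' parameters. Together with the scalar task performance they form the
#' 15-feature vocabulary used throughout the package.
#'
#' @param site optional filter: `"PFC"`, `"VC"` or `"systemic"`.
#' @return character vector of parameter names.
#' @examples
#' spa_parameters()
#' spa_parameters("systemic")
#' @export
spa_parameters <- function(site = NULL) {
  pfc <- c("O2Hb-PFC", "HHb-PFC", "tHb-PFC", "StO2-PFC")
  vc  <- c("O2Hb-VC", "HHb-VC", "tHb-VC", "StO2-VC")
  sys <- c("HR", "MAP", "SpO2", "RR", "PETCO2", "SC")
  if (is.null(site)) return(c(pfc, vc, sys))
  switch(match.arg(site, c("PFC", "VC", "systemic")),
         PFC = pfc, VC = vc, systemic = sys)
}

#' Name of the scalar task-performance feature
#' @return a string.
#' @export
task_performance_feature <- function() "task_performance"

# Per-parameter simulation defaults. Units: hemoglobin species uM, StO2 and
# SpO2 %, HR bpm, MAP and PETCO2 mmHg, RR breaths/min, SC uS.
#   baseline      resting level
#   amplitude     task-phase response shared by all groups unless a template
#                 overrides it (the group-discriminating parameters do)
#   amplitude_sd  between-subject SD of the response amplitude within a group
#   noise_sd      per-sample measurement noise SD
#   drift_sd      SD of the random linear drift slope, units per minute
parameter_profiles <- function() {
  p <- data.frame(
    parameter = spa_parameters(),
    unit = c(rep(c("uM", "uM", "uM", "%"), 2),
             "bpm", "mmHg", "%", "breaths/min", "mmHg", "uS"),
    baseline     = c(35, 15, 50, 65, 35, 15, 50, 65, 70, 85, 97, 15, 38, 5),
    amplitude    = c(0.8, 0, 0.5, 0.8, 0, -0.2, 0.3, 0.5, 4, 5, 0, 1.5, 0, 0),
    amplitude_sd = c(0.5, 0.05, 0.5, 0.6, 0.12, 0.3, 0.5, 0.6,
                     2.5, 3, 0.08, 1, 0.25, 0.4),
    noise_sd     = c(0.3, 0.15, 0.35, 0.2, 0.3, 0.15, 0.35, 0.2,
                     1.5, 1.5, 0.3, 0.8, 0.4, 0.1),
    drift_sd     = c(0.01, 0.005, 0.01, 0.01, 0.01, 0.005, 0.01, 0.01,
                     0.05, 0.05, 0.005, 0.02, 0.01, 0.02),
    stringsAsFactors = FALSE
  )
  rownames(p) <- p$parameter
  p
}

# The five features through which group structure is planted by default:
# the ones that drive subject classification in this paradigm.
informative_features <- function() {
  c("HHb-PFC", "O2Hb-VC", "PETCO2", "SC", "SpO2")
}
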