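#' Define a simulation scenario
#'
#' A scenario combines a volume status (euvolemia, or hypovolemia as a 20
#' percent blood-volume reduction matching the experimental withdrawal),
#' reflex activity (on = ventricular-fibrillation-like arrest with intact
#' autonomic arcs; off = pentobarbital-like arrest with reflexes
#' inactivated), the arrest time (t = 0 by convention) and the horizon.
#'
#' @param volume_status `"euvolemia"` or `"hypovolemia_20pct"`.
#' @param reflexes `"on"` or `"off"`.
#' @param arrest_time Arrest time (s); `Inf` for a no-arrest run.
#' @param horizon_post_arrest Simulation end (s after arrest); `NULL` takes
#'   the config default (>= 600 s for full post-arrest analysis).
#' @param baseline_duration Settling time before the recorded baseline (s).
#' @param valve_mode_post_arrest `NULL` (config default), `"open"` (valves
#'   ignored after arrest, free redistribution — the MCFP idealization),
#'   `"diode"` (one-way valves stay one-way) or `"sealed_cardiac"` (no flow
#'   through the arrested heart; other valves stay one-way).
#' @param label Trace label; defaults to a descriptive tag.
#' @param check_steady Verify a settled baseline before arrest.
#' @return A `zf_scenario` list.
#' @export
scenario_config <- function(volume_status = c("euvolemia", "hypovolemia_20pct"),
                            reflexes = c("on", "off"),
                            arrest_time = 0,
                            horizon_post_arrest = NULL,
                            baseline_duration = NULL,
                            valve_mode_post_arrest = NULL,
                            label = NULL,
                            check_steady = TRUE) {
  volume_status <- match.arg(volume_status)
  reflexes <- match.arg(reflexes)
  if (!is.null(valve_mode_post_arrest)) {
    valve_mode_post_arrest <- match.arg(valve_mode_post_arrest,
                                        c("open", "diode", "sealed_cardiac"))
  }
  if (!is.null(horizon_post_arrest) && horizon_post_arrest < 0) {
    abort("horizon_post_arrest must be >= 0")
  }
  label <- label %||% paste0(
    if (reflexes == "on") "reflex_on" else "reflex_off", "_",
    if (volume_status == "euvolemia") "eu" else "hypo")
  structure(
    list(volume_status = volume_status, reflexes = reflexes,
         arrest_time = arrest_time, horizon_post_arrest = horizon_post_arrest,
         baseline_duration = baseline_duration,
         valve_mode_post_arrest = valve_mode_post_arrest,
         label = label, check_steady = check_steady),
    class = "zf_scenario"
  )
}

#' Apply a volume status to a model state
#'
#' Hypovolemia scales every compartment volume by 0.80 (proportional
#' withdrawal, reducing total volume by exactly 20 percent); euvolemia
#' leaves the state unchanged. Must be applied before baseline
#' stabilization, and only once.
#'
#' @param state A `zf_state` from [model_state()].
#' @param status `"euvolemia"` or `"hypovolemia_20pct"`.
#' @return The updated state.
#' @export
apply_volume_status <- function(state, status = c("euvolemia", "hypovolemia_20pct")) {
  status <- match.arg(status)
  if (isTRUE(state$volume_status_applied)) {
    abort("volume status already applied to this state", class = "zf_scenario_error")
  }
  if (status == "hypovolemia_20pct") state$V <- 0.8 * state$V
  state$volume_status_applied <- TRUE
  state
}

#' Induce circulatory arrest in a model state
#'
#' Sets heart rate and respiratory rate to zero and flags the arrest, which
#' removes cardiac activation (the chambers fall to their arrest elastance)
#' and holds intrathoracic pressure at zero thereafter. With
#' `controller_mode = "active"` the reflex controller keeps running (the
#' ventricular-fibrillation condition); with `"inactive"` it is pinned at
#' base (the pentobarbital condition).
#'
#' @param state A `zf_state`.
#' @param controller_mode `"active"` or `"inactive"`.
#' @return The arrested state.
#' @export
induce_arrest <- function(state, controller_mode = c("active", "inactive")) {
  controller_mode <- match.arg(controller_mode)
  state$HR <- 0
  state$RR <- 0
  state$arrest <- TRUE
  state$controller_mode <- controller_mode
  state
}

#' The four study scenarios
#'
#' Euvolemia and 20 percent hypovolemia, each with reflexes on
#' (ventricular-fibrillation-like) and off (pentobarbital-like).
#'
#' @param horizon_post_arrest Optional horizon override (s).
#' @return Named list of four `zf_scenario` objects.
#' @export
study_scenarios <- function(horizon_post_arrest = NULL) {
  list(
    vf_eu = scenario_config("euvolemia", "on", horizon_post_arrest = horizon_post_arrest,
                            label = "vf_eu"),
    vf_hypo = scenario_config("hypovolemia_20pct", "on",
                              horizon_post_arrest = horizon_post_arrest,
                              label = "vf_hypo"),
    pento_eu = scenario_config("euvolemia", "off",
                               horizon_post_arrest = horizon_post_arrest,
                               label = "pento_eu"),
    pento_hypo = scenario_config("hypovolemia_20pct", "off",
                                 horizon_post_arrest = horizon_post_arrest,
                                 label = "pento_hypo")
  )
}

#' Run the full set of simulation scenarios
#'
#' Runs each scenario on the given model, filters each trace to mean
#' signals and extracts the four analysis time points.
#'
#' @param model A `zf_model`; defaults to the packaged human configuration.
#' @param scenarios A list of `zf_scenario` objects.
#' @return List with `traces` (one tibble, all scenarios stacked, labelled)
#'   and `summary` (time-point values per scenario and channel).
#' @export
run_study <- function(model = build_default_model(),
                      scenarios = study_scenarios()) {
  traces <- purrr::map(scenarios, ~ simulate(model, .x))
  summaries <- purrr::imap_dfr(traces, function(tr, nm) {
    dplyr::mutate(extract_timepoints(lowpass_mean(tr)), label = nm,
                  .before = 1)
  })
  list(traces = dplyr::bind_rows(traces), summary = summaries)
}
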