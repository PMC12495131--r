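#' Run a closed-loop simulation
#'
#' Integrates the closed-loop network from a settled baseline, applies the
#' volume status before stabilization, induces arrest at `t = 0` (heart
#' rate, respiratory rate and cardiac activation set to zero; intrathoracic
#' pressure held at zero thereafter), and integrates to the post-arrest
#' horizon. Arterial pressure is sampled at the abdominal-aorta node,
#' central venous pressure at the right atrium, and cardiac output as the
#' main pulmonary-artery flow, at the configured sampling rate.
#'
#' With reflexes enabled the controller (see [reflex]) runs throughout,
#' including after arrest (with pulse pressure zero); with reflexes off the
#' effectors stay at base for the whole run.
#'
#' @param model A `zf_model` from [build_default_model()].
#' @param scenario A `zf_scenario` from [scenario_config()].
#' @return A tibble (`time_s`, `abp_mmhg`, `cvp_mmhg`, `co_l_min`, `label`)
#'   with attributes `fs`, `scenario`, and `diagnostics` (volume drift,
#'   effector traces, final state).
#' @examples
#' \donttest{
#' mod <- build_default_model()
#' tr <- simulate(mod, scenario_config(reflexes = "off"))
#' }
#' @export
simulate <- function(model, scenario = scenario_config()) {
  stopifnot(inherits(model, "zf_model"), inherits(scenario, "zf_scenario"))
  comp <- dplyr::arrange(model$compartments, .data$id)
  conn <- model$connections
  g <- model$global

  ea <- arrest_elastance_values(comp, g$arrest_elastance %||% "diastolic")
  ea[is.na(ea)] <- 0
  valve_code <- c(none = 0L, cardiac = 1L, microvascular = 2L, venous = 2L)
  vu_w <- model$reflex$vu_weights %||% rep(0, nrow(comp))

  topo <- list(
    is_cardiac = as.integer(comp$kind == "cardiac"),
    C = ifelse(is.na(comp$C), 1, comp$C),
    Emin = ifelse(is.na(comp$E_min), 0, comp$E_min),
    Emax = ifelse(is.na(comp$E_max), 0, comp$E_max),
    V0 = comp$V_unstressed, act_delay = comp$act_delay,
    thoracic = as.integer(comp$thoracic),
    vu_w = vu_w, E_arrest = ea,
    edge_from = conn$from, edge_to = conn$to, edge_R = conn$R,
    edge_valve = unname(valve_code[conn$valve]),
    edge_reflex = as.integer(conn$reflex_resistance),
    ctrl_a_node = as.integer(g$aortic_arch_index %||% 0L),
    ctrl_v_node = as.integer(g$right_atrium_index %||% 15L),
    meas_abp_node = as.integer(g$abp_index %||% 0L),
    meas_cvp_node = as.integer(g$right_atrium_index %||% 15L),
    co_edge = co_edge_index(model)
  )

  V_total <- g$total_blood_volume
  if (scenario$volume_status == "hypovolemia_20pct") V_total <- 0.8 * V_total
  record_from <- g$record_from %||% -60
  settle <- scenario$baseline_duration %||% g$settle_s %||% 60
  horizon <- scenario$horizon_post_arrest %||% g$horizon_post_arrest %||% 600
  vmode <- scenario$valve_mode_post_arrest %||% g$valve_mode_post_arrest %||% "sealed_cardiac"
  vmode_code <- c(open = 0L, diode = 1L, sealed_cardiac = 2L)[[vmode]]

  pars <- list(
    V_init = initial_volumes(model, V_total),
    dt = g$dt, t0 = record_from - settle, t_end = horizon,
    record_from = record_from, fs = g$fs,
    HR0 = g$heart_rate, RR0 = g$resp_rate,
    pit_mean = g$p_it_mean, pit_amp = g$p_it_amp,
    sys_k = g$systolic_k %||% 0.3,
    arrest_time = scenario$arrest_time,
    valve_mode_post = vmode_code
  )

  ctrl <- NULL
  if (scenario$reflexes == "on") {
    rf <- model$reflex
    if (is.null(rf)) abort("scenario has reflexes on but the model has no reflex block")
    tick_every <- as.integer(round(1 / (rf$tick_hz * g$dt)))
    ctrl <- list(
      window_n = rf$window_n, tick_every = tick_every,
      set_a = rf$setpoints$arterial, set_p = rf$setpoints$pulse,
      set_v = rf$setpoints$venous,
      lim_abr = rf$limits$abr, lim_cpr = rf$limits$cpr,
      arc_source = match(rf$arcs$source, c("abp", "pp", "cvp")) - 1L,
      arc_every = as.integer(pmax(1, round(rf$tick_hz / rf$arcs$rate_hz))),
      kernels = rf$arcs$kernel,
      g_hr = rf$arcs$g_hr, g_contract = rf$arcs$g_contract,
      g_resist = rf$arcs$g_resist, g_vu = rf$arcs$g_vu
    )
  }

  res <- simulate_cpp(topo, pars, ctrl)
  if (nzchar(res$error)) {
    abort(paste0("integration failure: ", res$error, "; state dump: V = [",
                 paste(signif(res$V_final, 6), collapse = ", "), "]"),
          class = "zf_integration_error")
  }

  tr <- tibble::tibble(
    time_s = res$time, abp_mmhg = res$abp, cvp_mmhg = res$cvp,
    co_l_min = res$co, label = scenario$label
  )

  if (isTRUE(scenario$check_steady)) {
    w1 <- dplyr::filter(tr, .data$time_s >= -20, .data$time_s < -10)
    w2 <- dplyr::filter(tr, .data$time_s >= -10, .data$time_s < 0)
    drift <- abs(mean(w2$abp_mmhg) - mean(w1$abp_mmhg))
    if (!is.finite(drift) || drift > 2) {
      abort(paste0(
        "baseline did not reach a periodic steady state (arterial drift ",
        signif(drift, 3), " mmHg over the last 20 s); review model ",
        "parameters or extend baseline_duration"), class = "zf_steady_error")
    }
  }

  attr(tr, "fs") <- g$fs
  attr(tr, "scenario") <- scenario
  attr(tr, "diagnostics") <- list(
    sumV_start = res$sumV_start, max_drift = res$max_drift, minV = res$minV,
    V_final = res$V_final, P_final = res$P_final,
    effectors = tibble::tibble(time_s = res$time, hr = res$hr,
                               contract = res$contract,
                               resist_scale = res$resist_scale,
                               dvu = res$dvu)
  )
  class(tr) <- c("zf_trace", class(tr))
  tr
}

co_edge_index <- function(model) {
  ce <- model$global$co_edge
  idx <- which(model$connections$from == ce$from & model$connections$to == ce$to)
  if (length(idx) != 1) abort("co_edge not found in connection table")
  idx - 1L
}

#' Sampling frequency of a trace
#'
#' @param trace A trace tibble with a `time_s` column.
#' @return Sampling frequency in Hz.
#' @export
trace_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (!is.null(fs)) return(fs)
  1 / median(diff(trace$time_s))
}
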