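#' Pressure of a single compartment
#'
#' Passive compartments follow the linear Windkessel law
#' `P = (V - V_unstressed) / C + P_ext`; cardiac compartments follow the
#' elastance law `P = E_now * (V - V_unstressed) + P_ext`. Pressures below
#' the external pressure are permitted (no nonlinear collapse law).
#'
#' @param spec One row of a compartment table (list or one-row data frame).
#' @param V Volume (mL), `>= 0`.
#' @param E_now Instantaneous elastance (mmHg/mL) for cardiac compartments.
#' @param P_ext External (intrathoracic) pressure, mmHg.
#' @return Pressure in mmHg.
#' @examples
#' compartment_pressure(list(kind = "venous", C = 2, V_unstressed = 100), V = 150)
#' @export
compartment_pressure <- function(spec, V, E_now = NULL, P_ext = 0) {
  spec <- as.list(spec)
  stopifnot(V >= 0)
  if (identical(spec$kind, "cardiac")) {
    E_now * (V - spec$V_unstressed) + P_ext
  } else {
    (V - spec$V_unstressed) / spec$C + P_ext
  }
}

#' Time-varying cardiac elastance
#'
#' Smooth periodic activation between the diastolic floor `E_min` and the
#' systolic peak `E_max`: a raised-half-sine (Hann) pulse over the systolic
#' fraction of the beat, with systolic duration `systolic_k * sqrt(T)` for
#' cycle length `T = 60/HR`. During arrest the activation is removed and the
#' chamber sits at its arrest elastance (`E_min` by default), making it an
#' ordinary passive reservoir.
#'
#' @param spec Cardiac compartment row (needs `E_min`, `E_max`, `act_delay`).
#' @param cardiac_phase Beat phase in `[0, 1)`.
#' @param HR Heart rate, beats/min (sets the systolic duration).
#' @param arrest Arrest flag.
#' @param systolic_k Systolic-duration coefficient (s^1/2), default 0.3.
#' @param arrest_elastance `"diastolic"` or a numeric elastance floor.
#' @return Elastance in mmHg/mL.
#' @export
cardiac_elastance <- function(spec, cardiac_phase, HR = 72, arrest = FALSE,
                              systolic_k = 0.3, arrest_elastance = "diastolic") {
  spec <- as.list(spec)
  stopifnot(cardiac_phase >= 0, cardiac_phase < 1)
  if (isTRUE(arrest)) {
    if (identical(arrest_elastance, "diastolic")) return(spec$E_min)
    return(as.numeric(arrest_elastance))
  }
  T_cycle <- 60 / HR
  Ts <- systolic_k * sqrt(T_cycle)
  u <- (cardiac_phase - (spec$act_delay %||% 0)) %% 1
  ts <- u * T_cycle
  act <- if (ts < Ts) 0.5 * (1 - cos(2 * pi * ts / Ts)) else 0
  spec$E_min + (spec$E_max - spec$E_min) * act
}

#' Flows across all connections
#'
#' Ohmic flow `Q = (P_from - P_to) / R` on plain edges; on valved edges the
#' ideal-diode law `Q = max(0, P_from - P_to) / R`.
#'
#' @param model A `zf_model`.
#' @param pressures Per-compartment pressures (mmHg), in id order.
#' @param valves_active Whether one-way valves rectify flow (default TRUE).
#' @return The connection tibble with a `Q` column (mL/s).
#' @export
flows <- function(model, pressures, valves_active = TRUE) {
  conn <- model$connections
  dP <- pressures[conn$from + 1L] - pressures[conn$to + 1L]
  q <- dP / conn$R
  if (valves_active) {
    q[conn$valve != "none" & dP < 0] <- 0
  }
  dplyr::mutate(conn, Q = q)
}

#' Per-compartment pressures for a model state
#' @noRd
state_pressures <- function(model, state, P_it = 0) {
  comp <- model$compartments
  k <- model$global$systolic_k %||% 0.3
  ae <- model$global$arrest_elastance %||% "diastolic"
  purrr::map_dbl(seq_len(nrow(comp)), function(i) {
    spec <- comp[i, ]
    pe <- if (spec$thoracic) P_it else 0
    if (spec$kind == "cardiac") {
      E <- cardiac_elastance(spec, state$cardiac_phase, HR = max(state$HR, 1e-9),
                             arrest = state$arrest, systolic_k = k,
                             arrest_elastance = ae)
      compartment_pressure(spec, state$V[i], E_now = E, P_ext = pe)
    } else {
      compartment_pressure(spec, state$V[i], P_ext = pe)
    }
  })
}

#' Advance the model state by one explicit step
#'
#' Reference (pure-R) fixed-step integrator used for small-instance checks;
#' production simulations use the compiled loop in [simulate()]. Volumes are
#' advanced by the net flow balance `dV_i/dt = sum(Q_in) - sum(Q_out)`, the
#' cardiac phase by `dt * HR / 60` (mod 1) and the respiratory phase by
#' `dt * RR / 60` (mod 1). Total volume is conserved exactly by
#' construction.
#'
#' @param model A `zf_model`.
#' @param state A `zf_state`.
#' @param dt Step (s).
#' @param P_it Intrathoracic pressure applied to thoracic compartments, mmHg.
#' @param valves_active Whether valves rectify.
#' @return The advanced `zf_state`.
#' @export
step <- function(model, state, dt, P_it = 0, valves_active = TRUE) {
  p <- state_pressures(model, state, P_it)
  fl <- flows(model, p, valves_active = valves_active)
  dV <- numeric(length(state$V))
  for (j in seq_len(nrow(fl))) {
    q <- fl$Q[j] * dt
    dV[fl$from[j] + 1L] <- dV[fl$from[j] + 1L] - q
    dV[fl$to[j] + 1L] <- dV[fl$to[j] + 1L] + q
  }
  V_new <- state$V + dV
  if (any(!is.finite(V_new)) || any(V_new < 0)) {
    bad <- which(!is.finite(V_new) | V_new < 0)
    abort(paste0(
      "integration failure: non-finite or negative volume in compartment(s) ",
      paste(bad - 1L, collapse = ", "), " at t = ", signif(state$t, 6),
      "; state dump: V = [", paste(signif(state$V, 6), collapse = ", "), "]"
    ), class = "zf_integration_error")
  }
  state$V <- V_new
  state$t <- state$t + dt
  if (!state$arrest) {
    state$cardiac_phase <- (state$cardiac_phase + dt * state$HR / 60) %% 1
    state$resp_phase <- (state$resp_phase + dt * state$RR / 60) %% 1
  }
  state
}
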