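#' Read a model configuration file
#'
#' Model configurations are YAML files holding one record per compartment
#' (resistive/capacitive parameters, unstressed volume, intrathoracic flag),
#' the directed connection table (with optional one-way valves), a global
#' block (total blood volume, integrator step, sampling rate, heart and
#' respiratory rate, intrathoracic pressure waveform) and the reflex
#' controller block. Two configurations ship with the package: a human
#' default (`calibration = "human"`) and a pig-calibrated scaling of it
#' (`calibration = "pig"`, see [derive_pig_config()]).
#'
#' @param path Path to a YAML configuration; overrides `calibration`.
#' @param calibration One of `"human"` or `"pig"`, selecting a packaged file.
#' @return A named list mirroring the YAML structure.
#' @export
read_model_config <- function(path = NULL, calibration = c("human", "pig")) {
  if (is.null(path)) {
    calibration <- match.arg(calibration)
    path <- system.file("extdata", paste0("model_", calibration, ".yaml"),
                        package = "zeroflow", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' Build and validate the closed-loop model topology
#'
#' Turns a configuration list (see [read_model_config()]) into a validated
#' model topology: a compartment table, a directed connection table forming a
#' single closed loop with branching systemic beds, and the global settings.
#' Compartment 0 is the aortic arch (the arterial afferent site of the
#' baroreflex) and compartment 15 the right atrium (the venous afferent
#' site); arterial pressure is reported at the abdominal aorta and cardiac
#' output as the flow through the main pulmonary artery.
#'
#' Invariants enforced: every resistance positive; positive compliance for
#' passive compartments; `E_max >= E_min >= 0` for cardiac compartments;
#' non-negative unstressed volumes; strongly connected topology.
#'
#' @param config A configuration list, or `NULL` for the packaged human
#'   default.
#' @return An object of class `zf_model`: a list with `compartments` and
#'   `connections` tibbles plus the global fields.
#' @examples
#' mod <- build_default_model()
#' nrow(mod$compartments) # 21
#' @export
build_default_model <- function(config = NULL) {
  if (is.null(config)) config <- read_model_config()
  comp <- purrr::map_dfr(config$compartments, function(x) {
    tibble::tibble(
      id = as.integer(x$id), name = x$name, kind = x$kind,
      C = x$C %||% NA_real_,
      E_min = x$E_min %||% NA_real_, E_max = x$E_max %||% NA_real_,
      V_unstressed = x$V_unstressed,
      thoracic = isTRUE(x$thoracic),
      venous_tone = isTRUE(x$venous_tone),
      act_delay = x$act_delay %||% 0,
      init_like = x$init_like %||% NA_character_
    )
  })
  conn <- purrr::map_dfr(config$connections, function(x) {
    tibble::tibble(
      from = as.integer(x$from), to = as.integer(x$to), R = x$R,
      valve = x$valve %||% "none",
      reflex_resistance = isTRUE(x$reflex_resistance)
    )
  })
  glob <- config[setdiff(names(config), c("compartments", "connections", "reflex"))]
  model <- structure(
    list(compartments = comp, connections = conn,
         reflex = parse_reflex_config(config$reflex, comp),
         global = glob),
    class = "zf_model"
  )
  validate_model(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_model <- function(model) {
  comp <- model$compartments
  conn <- model$connections
  n <- nrow(comp)
  if (!identical(sort(comp$id), 0:(n - 1L))) {
    abort("compartment ids must be a complete 0-based index (missing compartment)")
  }
  comp <- dplyr::arrange(comp, .data$id)
  bad_kind <- setdiff(comp$kind, c("arterial", "venous", "cardiac", "pulmonary"))
  if (length(bad_kind)) abort(paste0("unknown compartment kind: ", bad_kind[1]))
  passive <- comp$kind != "cardiac"
  if (any(is.na(comp$C[passive]) | comp$C[passive] <= 0)) {
    i <- comp$id[passive][which(is.na(comp$C[passive]) | comp$C[passive] <= 0)[1]]
    abort(paste0("compartment ", i, ": compliance C must be > 0 for passive compartments"))
  }
  cardiac <- !passive
  ok_e <- !is.na(comp$E_min[cardiac]) & !is.na(comp$E_max[cardiac]) &
    comp$E_min[cardiac] >= 0 & comp$E_max[cardiac] >= comp$E_min[cardiac]
  if (any(!ok_e)) {
    i <- comp$id[cardiac][which(!ok_e)[1]]
    abort(paste0("compartment ", i, ": need E_max >= E_min >= 0 for cardiac compartments"))
  }
  if (any(comp$V_unstressed < 0)) {
    abort(paste0("compartment ", comp$id[comp$V_unstressed < 0][1],
                 ": V_unstressed must be >= 0"))
  }
  if (any(conn$R <= 0 | !is.finite(conn$R))) {
    j <- which(conn$R <= 0 | !is.finite(conn$R))[1]
    abort(paste0("connection ", conn$from[j], "->", conn$to[j], ": R must be > 0"))
  }
  if (any(conn$from < 0 | conn$from >= n | conn$to < 0 | conn$to >= n)) {
    abort("connection endpoint out of range")
  }
  if (!is_strongly_connected(conn, n)) {
    abort("topology is not strongly connected (disconnected topology)")
  }
  vt <- model$global$total_blood_volume
  if (is.null(vt) || vt <= 0) abort("total_blood_volume must be > 0")
  model$compartments <- comp
  model
}

is_strongly_connected <- function(conn, n) {
  reach <- function(adj) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v + 1L]]
      new <- nb[!seen[nb + 1L]]
      seen[new + 1L] <- TRUE
      queue <- c(queue, new)
    }
    all(seen)
  }
  fwd <- split(conn$to, factor(conn$from, levels = 0:(n - 1L)))
  bwd <- split(conn$from, factor(conn$to, levels = 0:(n - 1L)))
  reach(purrr::map(fwd, as.integer)) && reach(purrr::map(bwd, as.integer))
}

#' Effective compliance of each compartment at zero flow
#'
#' Passive compartments contribute their compliance `C`; cardiac compartments
#' contribute the inverse of their arrest elastance (the diastolic `E_min` by
#' default, or a numeric floor configured via `arrest_elastance`).
#' @noRd
effective_compliance <- function(model) {
  comp <- model$compartments
  ae <- model$global$arrest_elastance %||% "diastolic"
  ifelse(comp$kind == "cardiac",
         1 / arrest_elastance_values(comp, ae),
         comp$C)
}

arrest_elastance_values <- function(comp, arrest_elastance) {
  if (identical(arrest_elastance, "diastolic")) {
    ifelse(comp$kind == "cardiac", comp$E_min, NA_real_)
  } else {
    rep(as.numeric(arrest_elastance), nrow(comp))
  }
}

#' Mean circulatory filling pressure of the model (closed form)
#'
#' The pressure every compartment assumes at the zero-flow equilibrium with
#' volume freely redistributed and external pressures zero:
#' `(V_total - sum(V_unstressed)) / sum(C_effective)`, where cardiac
#' compartments enter with compliance `1 / E_arrest`. This is the model's
#' analytic mean circulatory filling pressure (MCFP) and serves as an
#' independent oracle for reflex-off simulations.
#'
#' @param model A `zf_model`.
#' @param V_total Total blood volume (mL); defaults to the configured value.
#' @return MCFP in mmHg.
#' @examples
#' mcfp(build_default_model())
#' @export
mcfp <- function(model, V_total = NULL) {
  V_total <- V_total %||% model$global$total_blood_volume
  (V_total - sum(model$compartments$V_unstressed)) /
    sum(effective_compliance(model))
}

#' Initial volume assignment
#'
#' Distributes the total blood volume over compartments from per-kind
#' starting pressures, then rescales stressed volumes so the sum matches
#' `V_total` exactly.
#' @noRd
initial_volumes <- function(model, V_total = NULL) {
  V_total <- V_total %||% model$global$total_blood_volume
  comp <- model$compartments
  ip <- model$global$init_pressures
  p <- unlist(ip)[init_pressure_kind(comp)]
  # target pressures are observed (atmosphere-referenced); thoracic
  # compartments sit inside the baseline intrathoracic pressure
  p_int <- p - (model$global$p_it_mean %||% 0) * comp$thoracic
  ceff <- ifelse(comp$kind == "cardiac", 1 / comp$E_min, comp$C)
  stressed <- ceff * p_int
  lambda <- (V_total - sum(comp$V_unstressed)) / sum(stressed)
  comp$V_unstressed + lambda * stressed
}

# Kind used to pick a compartment's starting pressure: atria (and any other
# compartment tagged init_like) borrow their upstream bed's value.
init_pressure_kind <- function(comp) {
  ifelse(is.na(comp$init_like), comp$kind, comp$init_like)
}

#' Initial model state
#'
#' @param model A `zf_model`.
#' @param V_total Optional total blood volume override (mL).
#' @return A `zf_state` list: time, per-compartment volumes, cardiac and
#'   respiratory phases, heart and respiratory rates.
#' @export
model_state <- function(model, V_total = NULL) {
  structure(
    list(t = 0, V = initial_volumes(model, V_total),
         cardiac_phase = 0, resp_phase = 0,
         HR = model$global$heart_rate, RR = model$global$resp_rate,
         arrest = FALSE, volume_status_applied = FALSE),
    class = "zf_state"
  )
}

#' Write a model configuration back to YAML
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}
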