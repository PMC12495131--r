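#' Derive the pig-calibrated model configuration
#'
#' Scales the human default to a pig of the given weight and tunes it so
#' the controller-on baseline matches the target hemodynamics (defaults:
#' the VF-euvolemia baseline of the anchor table — MAP 53 mmHg, CVP 11
#' mmHg). The derivation is the documented calibration procedure behind
#' the packaged `model_pig.yaml`:
#'
#' 1. allometric scaling — total blood volume set to
#'    `blood_volume_per_kg * weight_kg`; every compliance and unstressed
#'    volume scaled by the volume ratio, every resistance by its inverse
#'    (pressures and time constants preserved, flows scaled);
#' 2. rate settings — pig baseline heart and respiratory rate;
#' 3. set points moved to the targets (arterial = target MAP, venous =
#'    target CVP) so the controller trims around the pig operating point;
#' 4. damped fixed-point adjustment from short baseline simulations: total
#'    blood volume closes the CVP gap (through its effect on the filling
#'    state), the microvascular resistances close the MAP gap, a
#'    contractility scale on the systolic elastances closes the CO gap
#'    (anesthetized piglets run a depressed pump function), and the
#'    pulse-pressure set point is moved to the measured baseline pulse
#'    pressure. Unstressed-volume reflex gains are rescaled with volume.
#'
#' @param weight_kg Animal weight (kg).
#' @param target_map,target_cvp Baseline targets (mmHg).
#' @param target_co Baseline cardiac output target (L/min).
#' @param heart_rate,resp_rate Baseline rates (1/min).
#' @param blood_volume_per_kg Blood volume density (mL/kg).
#' @param n_iter Adjustment iterations.
#' @param base_config Starting configuration (human default).
#' @param verbose Print per-iteration measurements.
#' @return The calibrated configuration list (write with
#'   [write_model_config()]).
#' @export
derive_pig_config <- function(weight_kg = 41.5, target_map = 53,
                              target_cvp = 11, target_co = 3,
                              heart_rate = 100,
                              resp_rate = 20, blood_volume_per_kg = 75,
                              n_iter = 8, base_config = read_model_config(),
                              verbose = FALSE) {
  cfg <- base_config
  v_target <- blood_volume_per_kg * weight_kg
  s <- v_target / cfg$total_blood_volume
  cfg$name <- "pig_calibrated"
  cfg$total_blood_volume <- v_target
  cfg$heart_rate <- heart_rate
  cfg$resp_rate <- resp_rate
  cfg$init_pressures <- list(arterial = target_map, venous = target_cvp,
                             pulmonary = 14, cardiac = 10)
  cfg$compartments <- lapply(cfg$compartments, function(x) {
    if (!is.null(x$C)) x$C <- x$C * s
    x$V_unstressed <- x$V_unstressed * s
    if (!is.null(x$E_min)) x$E_min <- x$E_min / s
    if (!is.null(x$E_max)) x$E_max <- x$E_max / s
    x
  })
  cfg$connections <- lapply(cfg$connections, function(x) {
    x$R <- x$R / s
    x
  })
  cfg$reflex$setpoints$arterial <- target_map
  cfg$reflex$setpoints$venous <- target_cvp
  cfg$reflex$arcs <- lapply(cfg$reflex$arcs, function(a) {
    if (!is.null(a$g_vu)) a$g_vu <- a$g_vu * s
    a
  })

  baseline_measure <- function(cfg) {
    model <- build_default_model(cfg)
    sc <- scenario_config(reflexes = "on", arrest_time = 1e6,
                          horizon_post_arrest = 0, baseline_duration = 120,
                          check_steady = FALSE, label = "cal")
    tr <- simulate(model, sc)
    w <- dplyr::filter(tr, .data$time_s >= -20)
    beat <- dplyr::filter(tr, .data$time_s >= -3)
    list(map = mean(w$abp_mmhg), cvp = mean(w$cvp_mmhg),
         co = mean(w$co_l_min), pp = diff(range(beat$abp_mmhg)))
  }

  damp <- 0.5
  for (k in seq_len(n_iter)) {
    m <- baseline_measure(cfg)
    if (verbose) {
      message(sprintf("iter %d: MAP %.1f CVP %.1f CO %.2f PP %.1f V %.0f",
                      k, m$map, m$cvp, m$co, m$pp, cfg$total_blood_volume))
    }
    r_fac <- ((target_map - m$cvp) / max(m$map - m$cvp, 1))^damp
    r_fac <- min(max(r_fac, 0.4), 2.5)
    cfg$connections <- lapply(cfg$connections, function(x) {
      if (!is.null(x$valve) && identical(x$valve, "microvascular")) x$R <- x$R * r_fac
      x
    })
    e_fac <- (target_co / max(m$co, 0.1))^damp
    e_fac <- min(max(e_fac, 0.5), 1.5)
    cfg$compartments <- lapply(cfg$compartments, function(x) {
      if (!is.null(x$E_max)) {
        x$E_max <- max(x$E_max * e_fac, 1.05 * x$E_min)
      }
      x
    })
    ceff <- sum(effective_compliance(build_default_model(cfg)))
    dv <- 0.35 * (target_cvp - m$cvp) * ceff
    cfg$total_blood_volume <- cfg$total_blood_volume + dv
    cfg$reflex$setpoints$pulse <- round(m$pp, 1)
    ip_old <- cfg$init_pressures
    cfg$init_pressures <- rebalance_init_pressures(
      cfg, 0.5 * ip_old$arterial + 0.5 * m$map,
      0.5 * ip_old$venous + 0.5 * m$cvp)
  }
  if (verbose) {
    m <- baseline_measure(cfg)
    message(sprintf("final: MAP %.1f CVP %.1f CO %.2f PP %.1f V %.0f",
                    m$map, m$cvp, m$co, m$pp, cfg$total_blood_volume))
  }
  cfg
}

# Make the initial volume assignment self-consistent with the measured
# baseline: arterial and venous starting pressures pinned to the measured
# MAP and CVP (so the controller warm-start sees near-zero afferent errors)
# and the cardiopulmonary starting pressures scaled to absorb the residual
# stressed volume.
rebalance_init_pressures <- function(cfg, map_meas, cvp_meas) {
  model <- build_default_model(cfg)
  comp <- model$compartments
  ceff <- ifelse(comp$kind == "cardiac", 1 / comp$E_min, comp$C)
  kind_eff <- init_pressure_kind(comp)
  pit <- (cfg$p_it_mean %||% 0) * comp$thoracic
  ip <- cfg$init_pressures
  is_cp <- kind_eff %in% c("pulmonary", "cardiac")
  p_fixed <- ifelse(kind_eff == "arterial", map_meas, cvp_meas)
  s_fixed <- sum((ceff * (p_fixed - pit))[!is_cp])
  p0_cp <- unlist(ip)[kind_eff[is_cp]]
  target <- cfg$total_blood_volume - sum(comp$V_unstressed)
  # solve for the cardiopulmonary scale x: s_fixed + sum(ceff*(x*p0 - pit)) = target
  x <- (target - s_fixed + sum((ceff * pit)[is_cp])) / sum(ceff[is_cp] * p0_cp)
  x <- max(x, 0.2)
  list(arterial = map_meas, venous = cvp_meas,
       pulmonary = ip$pulmonary * x, cardiac = ip$cardiac * x)
}
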