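# Shared fixtures: models are built once per test run and cached.

zf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = zf_cache)) assign(key, force(expr), envir = zf_cache)
  get(key, envir = zf_cache)
}

human_model <- function() cached("human", build_default_model())

pig_model <- function() {
  cached("pig", build_default_model(read_model_config(calibration = "pig")))
}

# Three passive compartments in a closed resistive ring, distinct starting
# pressures; relaxes to a common equilibrium. Used for small-instance
# integrator checks against an independent stiff-ODE reference.
toy_ring_config <- function(C = c(1, 2, 4), V0 = c(10, 20, 30),
                            R = c(1, 2, 3), p0 = c(30, 10, 5),
                            V_total = NULL) {
  stressed <- sum(C * p0)
  list(
    name = "toy_ring",
    total_blood_volume = V_total %||% (sum(V0) + stressed),
    dt = 0.001, fs = 100, heart_rate = 0, resp_rate = 0,
    p_it_mean = 0, p_it_amp = 0, systolic_k = 0.3,
    arrest_elastance = "diastolic",
    valve_mode_post_arrest = "open",
    settle_s = 0, record_from = 0, horizon_post_arrest = 30,
    aortic_arch_index = 0, right_atrium_index = 2, abp_index = 0,
    co_edge = list(from = 0, to = 1),
    init_pressures = list(arterial = p0[1], venous = p0[2], pulmonary = p0[3],
                          cardiac = 1),
    compartments = list(
      list(id = 0, name = "a", kind = "arterial", C = C[1], V_unstressed = V0[1]),
      list(id = 1, name = "b", kind = "venous", C = C[2], V_unstressed = V0[2]),
      list(id = 2, name = "c", kind = "pulmonary", C = C[3], V_unstressed = V0[3])
    ),
    connections = list(
      list(from = 0, to = 1, R = R[1]),
      list(from = 1, to = 2, R = R[2]),
      list(from = 2, to = 0, R = R[3])
    )
  )
}

toy_ring_model <- function(...) build_default_model(toy_ring_config(...))

toy_ring_scenario <- function(horizon = 30) {
  scenario_config(reflexes = "off", arrest_time = -1e9,
                  horizon_post_arrest = horizon, baseline_duration = 0,
                  valve_mode_post_arrest = "open", check_steady = FALSE,
                  label = "toy")
}

# A short arrest scenario to keep simulation-heavy unit tests fast.
short_scenario <- function(reflexes = "off", ...) {
  scenario_config(reflexes = reflexes, baseline_duration = 20,
                  horizon_post_arrest = 40, check_steady = FALSE, ...)
}

# Small reflex config with short kernels for direct controller-step tests.
test_reflex_config <- function() {
  raw <- list(
    enabled = TRUE, window_n = 10L, tick_hz = 10,
    setpoints = list(arterial = 95, pulse = 35, venous = 3),
    limits = list(abr = 18, cpr = 5),
    arcs = list(
      list(name = "fast_hr", source = "abp", class = "abr",
           delay = 0, peak = 0.2, end = 0.5, rate_hz = 10, g_hr = -1),
      list(name = "symp_r", source = "abp", class = "abr",
           delay = 0.1, peak = 0.5, end = 2, rate_hz = 10, g_resist = -0.05,
           g_vu = 20),
      list(name = "cpr_v", source = "cvp", class = "cpr",
           delay = 0.1, peak = 0.5, end = 2, rate_hz = 10, g_resist = -0.04,
           g_vu = 30)
    )
  )
  comp <- human_model()$compartments
  zeroflow:::parse_reflex_config(raw, comp)
}

# Reproducible local RNG without touching the global stream elsewhere.
with_seed <- function(seed, code) withr::with_seed(seed, code)
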