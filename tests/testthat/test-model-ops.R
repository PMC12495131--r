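test_that("compartment pressure follows the linear Windkessel/elastance laws", {
  passive <- list(kind = "venous", C = 2, V_unstressed = 100)
  expect_equal(compartment_pressure(passive, V = 100), 0)
  expect_equal(compartment_pressure(passive, V = 150), 25)
  cardiac <- list(kind = "cardiac", V_unstressed = 0)
  expect_equal(compartment_pressure(cardiac, V = 120, E_now = 0.1, P_ext = -4), 8)
  # pressures below external pressure are permitted (no collapse law)
  expect_lt(compartment_pressure(passive, V = 50, P_ext = 0), 0)
})

test_that("cardiac elastance spans E_min to E_max over the activation", {
  spec <- list(kind = "cardiac", E_min = 0.1, E_max = 2.5, act_delay = 0)
  # late diastole: activation over (systole ended)
  expect_equal(cardiac_elastance(spec, 0.9, HR = 60), 0.1)
  # activation peak: ts = Ts/2; HR 60 -> T = 1 s, Ts = 0.3 s -> phase 0.15
  expect_equal(cardiac_elastance(spec, 0.15, HR = 60), 2.5)
  # arrest removes activation entirely
  expect_equal(cardiac_elastance(spec, 0.15, HR = 60, arrest = TRUE), 0.1)
  expect_equal(cardiac_elastance(spec, 0.15, HR = 60, arrest = TRUE,
                                 arrest_elastance = 1e-3), 1e-3)
  # smooth and bounded over the whole cycle
  e <- vapply(seq(0, 0.999, by = 0.001), cardiac_elastance, numeric(1),
              spec = spec, HR = 72)
  expect_true(all(e >= 0.1 - 1e-12 & e <= 2.5 + 1e-12))
})

test_that("flows follow the Ohm analogy with ideal diodes on valved edges", {
  mod <- toy_ring_model()
  p <- c(10, 10, 10)
  expect_true(all(flows(mod, p)$Q == 0))
  p <- c(20, 10, 10)
  fl <- flows(mod, p)
  expect_equal(fl$Q[fl$from == 0], 10 / fl$R[fl$from == 0])
  # valved edge blocks retrograde flow
  mod$connections$valve[1] <- "microvascular"
  fl <- flows(mod, c(5, 10, 10))
  expect_equal(fl$Q[1], 0)
  fl_open <- flows(mod, c(5, 10, 10), valves_active = FALSE)
  expect_lt(fl_open$Q[1], 0)
})

test_that("step conserves volume and fixes equal-pressure states", {
  mod <- toy_ring_model()
  st <- model_state(mod)
  st2 <- step(mod, st, dt = 0.001)
  expect_equal(sum(st2$V), sum(st$V), tolerance = 1e-12)
  # equal pressures: fixed point
  st$V <- mod$compartments$V_unstressed + mod$compartments$C * 12
  st_eq <- step(mod, st, dt = 0.001)
  expect_equal(st_eq$V, st$V, tolerance = 1e-12)
})

test_that("step aborts with a state dump on negative volume", {
  mod <- toy_ring_model()
  st <- model_state(mod)
  st$V <- c(0.0001, st$V[2], st$V[3])
  # huge outflow from a nearly empty compartment drives V negative
  expect_error(step(mod, st, dt = 50), class = "zf_integration_error")
})

test_that("fixed-step integration matches an independent stiff-ODE solution", {
  skip_if_not_installed("deSolve")
  cfg <- toy_ring_config()
  mod <- build_default_model(cfg)
  tr <- simulate(mod, toy_ring_scenario(horizon = 20))

  comp <- mod$compartments
  rhs <- function(t, V, parms) {
    P <- (V - comp$V_unstressed) / comp$C
    conn <- mod$connections
    q <- (P[conn$from + 1] - P[conn$to + 1]) / conn$R
    dV <- numeric(3)
    for (j in seq_len(nrow(conn))) {
      dV[conn$from[j] + 1] <- dV[conn$from[j] + 1] - q[j]
      dV[conn$to[j] + 1] <- dV[conn$to[j] + 1] + q[j]
    }
    list(dV)
  }
  V0 <- zeroflow:::initial_volumes(mod)
  sol <- deSolve::lsoda(V0, times = seq(0, 20, by = 0.01), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  P_ref <- (sol[, 2] - comp$V_unstressed[1]) / comp$C[1]
  P_sim <- approx(tr$time_s, tr$abp_mmhg, xout = sol[, 1])$y
  expect_lt(max(abs(P_sim - P_ref), na.rm = TRUE), 0.1)
})

test_that("halving the step changes toy-ring pressures negligibly", {
  cfg <- toy_ring_config()
  tr1 <- simulate(build_default_model(cfg), toy_ring_scenario(horizon = 10))
  cfg$dt <- cfg$dt / 2
  tr2 <- simulate(build_default_model(cfg), toy_ring_scenario(horizon = 10))
  expect_lt(max(abs(tr1$abp_mmhg - tr2$abp_mmhg)), 0.05)
})
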