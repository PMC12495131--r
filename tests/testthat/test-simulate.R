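test_that("simulation conserves volume to integrator tolerance", {
  mod <- human_model()
  tr <- simulate(mod, short_scenario("off"))
  d <- attr(tr, "diagnostics")
  expect_lt(d$max_drift / d$sumV_start, 1e-6)
  expect_gte(d$minV, 0)
})

test_that("baseline is pulsatile with forward output before arrest", {
  mod <- human_model()
  tr <- cached("human_short_off", simulate(mod, short_scenario("off")))
  base <- dplyr::filter(tr, time_s >= -10, time_s < 0)
  expect_gt(mean(base$co_l_min), 2)
  expect_gt(diff(range(base$abp_mmhg)), 10)  # pulse pressure
})

test_that("simulations are deterministic", {
  mod <- human_model()
  tr1 <- simulate(mod, short_scenario("on"))
  tr2 <- simulate(mod, short_scenario("on"))
  expect_identical(tr1$abp_mmhg, tr2$abp_mmhg)
  expect_identical(tr1$cvp_mmhg, tr2$cvp_mmhg)
})

test_that("reflex-off arrest converges to the analytic zero-flow equilibrium", {
  # valves ignored after arrest: every compartment relaxes to the MCFP
  mod <- human_model()
  sc <- scenario_config(reflexes = "off", valve_mode_post_arrest = "open",
                        horizon_post_arrest = 1500, check_steady = FALSE)
  tr <- cached("human_open_long", simulate(mod, sc))
  late <- dplyr::filter(tr, time_s >= 1490)
  expect_equal(mean(late$abp_mmhg), mcfp(mod), tolerance = 0.1 / mcfp(mod))
  expect_equal(mean(late$cvp_mmhg), mcfp(mod), tolerance = 0.1 / mcfp(mod))
  p_final <- attr(tr, "diagnostics")$P_final
  expect_lt(max(abs(p_final - mcfp(mod))), 0.1)
})

test_that("reflex-off arrest equilibrates ABP and CVP onto a common plateau", {
  mod <- human_model()
  tr <- cached("human_def_off",
               simulate(mod, scenario_config(reflexes = "off",
                                             check_steady = FALSE)))
  f <- lowpass_mean(tr)
  gap <- abs(f$abp_mmhg - f$cvp_mmhg)
  t_idx <- f$time_s
  expect_lt(max(gap[t_idx > 60 & t_idx < 600]), 0.5)
  # plateau is flat
  late <- dplyr::filter(f, time_s > 100, time_s < 600)
  expect_lt(diff(range(late$abp_mmhg)), 0.5)
})

test_that("reflex-on arrest sustains a retrograde veno-arterial gradient", {
  mod <- human_model()
  tr <- cached("human_def_on",
               simulate(mod, scenario_config(reflexes = "on",
                                             check_steady = FALSE)))
  f <- lowpass_mean(tr)
  w600 <- dplyr::filter(f, abs(time_s - 600) <= 1)
  expect_gt(mean(w600$cvp_mmhg), mean(w600$abp_mmhg))
})

test_that("an unsettled baseline raises the steady-state error", {
  cfg <- read_model_config()
  cfg$init_pressures$arterial <- 20
  cfg$init_pressures$venous <- 30  # overfilled veins drain slowly into the loop
  cfg$record_from <- -25
  mod <- build_default_model(cfg)
  expect_error(
    simulate(mod, scenario_config(reflexes = "off", baseline_duration = 0,
                                  horizon_post_arrest = 0)),
    class = "zf_steady_error"
  )
})

test_that("trace carries sampling-rate metadata", {
  mod <- toy_ring_model()
  tr <- simulate(mod, toy_ring_scenario(horizon = 5))
  expect_equal(trace_fs(tr), 100)
  expect_equal(median(diff(tr$time_s)), 1 / 100)
})
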